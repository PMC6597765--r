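test_that("derivatives match the printed right-hand sides", {
  p <- within_host_params()
  expect_equal(within_host_derivatives(c(W = 1, M = 0, I = 1), p),
               c(1 - 1e-4, 0, 0.8 * (1 / 1001)))
  expect_equal(within_host_derivatives(c(0, 0, 1), p), c(0, 0, 0))
  p0 <- update_params(p, rm = 1)
  expect_equal(within_host_derivatives(c(1, 1, 0), p0), c(1, 1, 0))
  expect_error(within_host_derivatives(c(-1, 0, 1), p), "negative state")
})

test_that("transmission rate is log10 of weighted density, clamped at zero", {
  p <- within_host_params()
  expect_equal(transmission_rate(10, 0, p), 1)
  expect_equal(transmission_rate(1, 0, p), 0)
  expect_equal(transmission_rate(0.5, 0, p), 0)  # clamped
  expect_equal(transmission_rate(0, 0, p), 0)
  # host-infectivity boost applies only when the mutant is present
  px <- update_params(p, x = 9)
  expect_equal(transmission_rate(10, 0, px, mutant_present = TRUE), 2)
  expect_equal(transmission_rate(10, 0, px, mutant_present = FALSE), 1)
  # selfish transmissibility weights only the mutant
  pz <- update_params(p, z = 5)
  expect_equal(transmission_rate(0, 2, pz), 1)
  expect_error(transmission_rate(-1, 0, p), "nonnegative")
})

test_that("pathology is the virulence-weighted density", {
  expect_equal(pathology(5, 0, v = 3), 5)
  expect_equal(pathology(0, 10, v = 0.5), 5)
  expect_equal(pathology(1, 1, v = 1), 2)
  expect_error(pathology(-1, 0, 1), "nonnegative")
})

test_that("mutant fraction is z-weighted and bounded", {
  expect_equal(mutant_fraction(3, 0, z = 2), 0)
  expect_equal(mutant_fraction(1, 1, z = 1), 0.5)
  expect_equal(mutant_fraction(1, 1, z = 3), 0.75)
  expect_error(mutant_fraction(0, 0, z = 1), "positive")
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(within_host_params(rw = -1), "nonnegative")
  expect_error(within_host_params(phi = 1, omega = 2), "phi > omega")
  expect_error(within_host_params(z = 0), "'z'")
  expect_error(within_host_params(bottlenecks = 0), "positive integers")
  expect_error(update_params(within_host_params(), nope = 1), "unknown")
})

test_that("a non-replicating inoculum is cleared, not grown", {
  p <- update_params(within_host_params(), rw = 0, t_max = 1e4)
  sim <- simulate_infection(p, dense_n = 201)
  expect_identical(sim$outcome$end_cause, "clearance")
  expect_true(all(diff(sim$trajectory$W) <= 1e-12))
  expect_equal(total_transmission(sim), 0)
})

test_that("default infections terminate by threshold, with valid state", {
  sim <- simulate_infection(within_host_params(), dense_n = 401)
  expect_true(sim$outcome$end_cause %in% c("pathology", "clearance"))
  tr <- sim$trajectory
  expect_true(all(tr$W >= 0 & tr$M >= 0 & tr$I >= 0))
  expect_true(all(tr$lambda >= 0))
  expect_true(all(diff(tr$Lambda_cum) >= -1e-9))
  expect_gt(total_transmission(sim), 0)
  # raising the pathology ceiling lets the immune response clear the infection
  sim2 <- simulate_infection(update_params(within_host_params(), phi = 1e12),
                             dense_n = 0)
  expect_identical(sim2$outcome$end_cause, "clearance")
  expect_error(simulate_infection(within_host_params(w0 = 0, m0 = 0)),
               "w0 \\+ m0")
})

test_that("a mutant-only infection has theta identically one", {
  p <- within_host_params(w0 = 0, m0 = 1, rm = 1.2, phi = 1e12)
  sim <- simulate_infection(p, dense_n = 101)
  expect_true(all(abs(sim$trajectory$theta - 1) < 1e-12))
  bc <- cotransmission_probs(sim, 5)
  expect_equal(unname(bc["c"]), 0)
  expect_equal(unname(bc["b"]), 1)
})

test_that("auxiliary-state integrals agree with trapezoid quadrature", {
  sim <- simulate_infection(neutral_coinfection(), dense_n = 2001)
  tr <- sim$trajectory
  lam_quad <- trapz(tr$t, tr$lambda)
  expect_lt(abs(total_transmission(sim) - lam_quad) / lam_quad, 1e-3)
  for (n in c(2L, 10L)) {
    c_quad <- trapz(tr$t, (1 - tr$theta^n - (1 - tr$theta)^n) * tr$lambda) /
      lam_quad
    b_quad <- trapz(tr$t, tr$theta^n * tr$lambda) / ((1 - c_quad) * lam_quad)
    bc <- cotransmission_probs(sim, n)
    expect_lt(abs(bc["c"] - c_quad), 1e-3)
    expect_lt(abs(bc["b"] - b_quad), 1e-3)
  }
})

test_that("neutral co-infections obey the closed-form co-transmission law", {
  sim <- simulate_infection(neutral_coinfection(), dense_n = 0)
  for (n in c(1L, 2L, 5L, 10L)) {
    bc <- cotransmission_probs(sim, n)
    expect_lt(abs(bc["c"] - (1 - 0.5^(n - 1))), 1e-3)
    expect_lt(abs(bc["b"] - 0.5), 1e-3)
  }
})

test_that("a bottleneck of one particle never co-transmits", {
  # asymmetric co-infection: theta far from 1/2, still c = 0 exactly at n = 1
  p <- within_host_params(w0 = 0.8, m0 = 0.2, rm = 1.3, z = 2, phi = 1e10,
                          bottlenecks = c(1L, 3L))
  sim <- simulate_infection(p, dense_n = 0)
  expect_identical(unname(cotransmission_probs(sim, 1)["c"]), 0)
  expect_gt(cotransmission_probs(sim, 3)["c"], 0)
})

test_that("transmission-type masses sum to the total transmission", {
  p <- within_host_params(w0 = 0.5, m0 = 0.5, rm = 1.2, phi = 1e10)
  sim <- simulate_infection(p, dense_n = 0)
  Lam <- total_transmission(sim)
  for (n in p$bottlenecks[p$bottlenecks > 1L]) {
    bc <- cotransmission_probs(sim, n)
    mass <- bc["c"] * Lam + (1 - bc["c"]) * bc["b"] * Lam +
      (1 - bc["c"]) * (1 - bc["b"]) * Lam
    expect_equal(unname(mass), Lam, tolerance = 1e-12)
  }
})

test_that("swapping strain labels mirrors b and preserves total transmission", {
  a <- simulate_infection(
    within_host_params(w0 = 0.5, m0 = 0.5, rw = 1, rm = 1.3, phi = 1e10),
    dense_n = 0)
  b <- simulate_infection(
    within_host_params(w0 = 0.5, m0 = 0.5, rw = 1.3, rm = 1, phi = 1e10),
    dense_n = 0)
  expect_equal(total_transmission(a), total_transmission(b),
               tolerance = 1e-6)
  for (n in c(2L, 5L, 10L)) {
    ba <- cotransmission_probs(a, n)
    bb <- cotransmission_probs(b, n)
    expect_equal(unname(ba["c"]), unname(bb["c"]), tolerance = 1e-5)
    expect_equal(unname(ba["b"]), 1 - unname(bb["b"]), tolerance = 1e-5)
  }
})

test_that("dominance is the normalized excess transmission of a co-infection", {
  expect_equal(dominance(10, 20, 20), 1)
  expect_equal(dominance(10, 20, 10), 0)
  expect_equal(dominance(10, 20, 15), 0.5)
  expect_error(dominance(10, 10, 12), "neutral")
})

test_that("cotransmission accessor rejects unrequested bottlenecks", {
  sim <- simulate_infection(neutral_coinfection(bottlenecks = c(1L, 2L)),
                            dense_n = 0)
  expect_error(cotransmission_probs(sim, 7), "not requested")
})
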