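test_that("co-infection offspring means partition Rc", {
  expect_equal(offspring_means(branching_params(Rw = 0.7, Rm = 2, d = 1))[["Rc"]], 2)
  expect_equal(offspring_means(branching_params(Rw = 0.7, Rm = 2, d = 0))[["Rc"]], 0.7)
  m <- offspring_means(branching_params(Rw = 1, Rm = 1, d = 0.5,
                                        c = 0.5, b = 0.5))
  expect_equal(unname(m[c("Rcc", "Rcm", "Rcw")]), c(0.5, 0.25, 0.25))
  # underdominance can drive the interpolated mean negative; it is clamped
  mneg <- offspring_means(branching_params(Rw = 0.2, Rm = 3, d = -2))
  expect_equal(mneg[["Rc"]], 0)
  # partition identity over random parameter draws
  set.seed(11)
  for (i in 1:25) {
    bp <- branching_params(Rw = runif(1), Rm = runif(1, 1, 4),
                           d = runif(1, -0.5, 1.5), c = runif(1),
                           b = runif(1), mu1 = runif(1), mu2 = runif(1))
    m <- offspring_means(bp)
    expect_equal(m[["Rcw"]] + m[["Rcm"]] + m[["Rcc"]], m[["Rc"]])
  }
})

test_that("the offspring PGF is a proper, monotone generating function", {
  set.seed(21)
  for (i in 1:20) {
    bp <- branching_params(Rw = runif(1), Rm = runif(1, 1, 4),
                           d = runif(1), c = runif(1), b = runif(1),
                           mu1 = runif(1), mu2 = runif(1))
    expect_equal(unname(offspring_pgf(c(1, 1, 1), bp)), c(1, 1, 1))
    s1 <- runif(3); s2 <- pmin(s1 + runif(3, 0, 1 - s1), 1)
    f1 <- offspring_pgf(s1, bp); f2 <- offspring_pgf(s2, bp)
    expect_true(all(f2 - f1 >= -1e-12))
    expect_true(all(f1 >= 0 & f1 <= 1))
  }
  # without mutation, the wild-type component is the Poisson PGF
  bp0 <- branching_params(Rw = 0.8, mu1 = 0, mu2 = 0)
  s <- c(0.3, 0.9, 0.1)
  expect_equal(unname(offspring_pgf(s, bp0)["fW"]), exp(0.8 * (0.3 - 1)))
  expect_error(offspring_pgf(c(0.5, 1.2, 0.5), branching_params()),
               "unit cube")
})

test_that("a zero-offspring process goes extinct in one step", {
  sol <- extinction_probability(branching_params(Rw = 0, Rm = 0, d = 0))
  expect_equal(unname(sol$q), c(1, 1, 1))
  mc <- simulate_chains(branching_params(Rw = 0, Rm = 0, d = 0),
                        n_chains = 50, seed = 1)
  expect_equal(mc$estimate, 0)
  expect_equal(mc$n_extinct, 50)
})

test_that("mutant-only emergence matches the scalar Poisson fixed point", {
  bp <- branching_params(Rw = 0.75, Rm = 1.5, d = 1, mu1 = 0, mu2 = 0)
  sol <- extinction_probability(bp)
  expect_lt(abs(sol$q[["qM"]] - poisson_extinction(1.5)), 1e-6)
  expect_true(sol$converged)
})

test_that("emergence is impossible without a supercritical escape route", {
  # no mutation path: subcritical and critical wild-types die out surely
  for (Rw in c(0.25, 0.75, 1)) {
    expect_equal(emergence_probability(branching_params(Rw = Rw, mu1 = 0)), 0)
  }
  # critical Poisson branching is almost surely finite
  expect_equal(emergence_probability(
    branching_params(Rm = 1, mu2 = 0, d = 1), start_type = "M"), 0)
  # ...but a supercritical mutant reachable by mutation rescues the chain
  expect_gt(emergence_probability(
    branching_params(Rw = 0.75, Rm = 1.5, d = 1, mu1 = 0.01)), 0)
})

test_that("functional iteration from zero rises monotonically to the fixed point", {
  set.seed(31)
  for (i in 1:10) {
    bp <- branching_params(Rw = runif(1), Rm = runif(1, 1, 4),
                           d = runif(1), c = runif(1), b = runif(1),
                           mu1 = runif(1, 0, 0.2), mu2 = runif(1, 0, 0.2))
    q <- c(0, 0, 0)
    for (k in 1:200) {
      qn <- unname(offspring_pgf(q, bp))
      expect_true(all(qn >= q - 1e-14) && all(qn <= 1))
      q <- qn
    }
    sol <- extinction_probability(bp)
    expect_true(all(unname(sol$q) >= q - 1e-6))
  }
})

test_that("analytic emergence agrees with the Monte-Carlo chain oracle", {
  bp <- branching_params(Rw = 0.75, Rm = 1.5, d = 1, b = 0.5, c = 0.5,
                         mu1 = 0.01, mu2 = 0.01)
  an <- emergence_probability(bp)
  mc <- simulate_chains(bp, "W", n_chains = 20000, seed = 99)
  expect_lt(abs(an - mc$estimate), 3 * max(mc$se, 1e-4))
  # from one mutant, the closed-form Poisson value
  bpm <- branching_params(Rm = 1.5, mu2 = 0)
  anm <- 1 - poisson_extinction(1.5)
  mcm <- simulate_chains(bpm, "M", n_chains = 20000, seed = 100)
  expect_lt(abs(anm - mcm$estimate), 3 * mcm$se)
})

test_that("chain simulation is reproducible and reports censoring", {
  bp <- branching_params(Rw = 0.9, Rm = 1.1, d = 0.5, mu1 = 0.05, mu2 = 0.05)
  a <- simulate_chains(bp, "W", n_chains = 500, seed = 7)
  b <- simulate_chains(bp, "W", n_chains = 500, seed = 7)
  expect_identical(a, b)
  expect_equal(a$n_emerged + a$n_extinct + a$n_censored, a$n_chains)
  expect_gte(a$censored_fraction, 0)
})
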