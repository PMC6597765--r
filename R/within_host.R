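#' Right-hand side of the two-strain within-host ODE system
#'
#' Evaluates the instantaneous rates of change of wild-type density W, mutant
#' density M and immune response I:
#' \code{dW = rw*W - k*W*I}, \code{dM = rm*M - k*M*I},
#' \code{dI = s*I*(W+M)/(A+W+M)}.
#'
#' @param state Numeric vector \code{c(W, M, I)} of nonnegative densities.
#' @param params A \code{\link{within_host_params}} object.
#' @return Numeric vector \code{c(dW, dM, dI)}.
#' @examples
#' within_host_derivatives(c(W = 1, M = 0, I = 1), within_host_params())
#' @export
within_host_derivatives <- function(state, params) {
  stopifnot(inherits(params, "within_host_params"))
  if (length(state) < 3L || anyNA(state))
    stop("state must be c(W, M, I)", call. = FALSE)
  W <- state[[1]]; M <- state[[2]]; I <- state[[3]]
  if (W < 0 || M < 0 || I < 0)
    stop("negative state passed to within_host_derivatives; ",
         "this signals integrator misuse", call. = FALSE)
  c(params$rw * W - params$k * W * I,
    params$rm * M - params$k * M * I,
    params$s * I * (W + M) / (params$A + W + M))
}

#' Instantaneous transmission rate
#'
#' The transmission rate is a saturating function of weighted pathogen
#' density, \code{lambda = log10((1 + x*deltaM) * (W + z*M))}, clamped at
#' zero (densities below one unit contribute no transmission). The
#' host-infectivity boost \code{x} applies only when the infection contains
#' the mutant (\code{mutant_present}); it is fixed per infection because ODE
#' densities never reach exactly zero.
#'
#' @param W,M Wild-type and mutant densities (nonnegative).
#' @param params A \code{\link{within_host_params}} object (uses \code{x},
#'   \code{z}).
#' @param mutant_present Logical: does this infection contain the mutant?
#' @return Nonnegative transmission rate.
#' @examples
#' transmission_rate(10, 0, within_host_params())  # log10(10) = 1
#' @export
transmission_rate <- function(W, M, params, mutant_present = any(M > 0)) {
  stopifnot(inherits(params, "within_host_params"))
  if (any(W < 0) || any(M < 0))
    stop("densities must be nonnegative", call. = FALSE)
  delta <- as.numeric(mutant_present)
  arg <- (1 + params$x * delta) * (W + params$z * M)
  lam <- rep(0, length(arg))
  pos <- arg > 0
  lam[pos] <- pmax(0, log10(arg[pos]))
  lam
}

#' Pathology level
#'
#' Pathology is a virulence-weighted linear function of pathogen density,
#' \code{alpha = W + v*M}. The infection is lethal (and transmission ceases)
#' when it exceeds the threshold \code{phi}.
#'
#' @param W,M Wild-type and mutant densities (nonnegative).
#' @param v Relative virulence of the mutant.
#' @return Pathology level \code{W + v*M}.
#' @examples
#' pathology(0, 10, v = 0.5)  # 5
#' @export
pathology <- function(W, M, v) {
  if (any(W < 0) || any(M < 0))
    stop("densities must be nonnegative", call. = FALSE)
  W + v * M
}

#' Transmissibility-weighted mutant fraction
#'
#' The probability that a single transmitted particle is the mutant,
#' \code{theta = z*M / (W + z*M)}. With a bottleneck of n particles the number
#' of mutant particles transmitted is Binomial(n, theta).
#'
#' @param W,M Wild-type and mutant densities.
#' @param z Relative transmissibility of the mutant.
#' @return Mutant fraction in [0, 1].
#' @examples
#' mutant_fraction(1, 1, z = 3)  # 0.75
#' @export
mutant_fraction <- function(W, M, z) {
  denom <- W + z * M
  if (any(denom <= 0))
    stop("W + z*M must be positive (both strains extinct?)", call. = FALSE)
  z * M / denom
}

# deSolve right-hand side: state = (W, M, I, Lambda, Ic_1..Ic_K, Ib_1..Ib_K)
# where Ic_n accumulates the co-transmission integrand
# (1 - theta^n - (1-theta)^n) * lambda and Ib_n accumulates theta^n * lambda.
wh_rhs <- function(t, y, parms) {
  W <- max(y[1L], 0); M <- max(y[2L], 0); I <- max(y[3L], 0)
  p <- parms$p
  dW <- p$rw * W - p$k * W * I
  dM <- p$rm * M - p$k * M * I
  dI <- p$s * I * (W + M) / (p$A + W + M)
  arg <- (1 + p$x * parms$deltaM) * (W + p$z * M)
  lam <- if (arg > 1) log10(arg) else 0
  denom <- W + p$z * M
  theta <- if (denom > 0) p$z * M / denom else 0
  ns <- parms$ns
  dIc <- (1 - theta^ns - (1 - theta)^ns) * lam
  dIb <- theta^ns * lam
  list(c(dW, dM, dI, lam, dIc, dIb))
}

# Root functions. Phase A: pathology, arming crossing, decay-to-clearance.
# Phase B (armed): pathology, true clearance crossing.
wh_root_a <- function(t, y, parms) {
  W <- max(y[1L], 0); M <- max(y[2L], 0)
  p <- parms$p
  c(W + p$v * M - p$phi,
    W + M - parms$arm_level,
    W + M - parms$decay_level)
}
wh_root_b <- function(t, y, parms) {
  W <- max(y[1L], 0); M <- max(y[2L], 0)
  p <- parms$p
  c(W + p$v * M - p$phi,
    W + M - p$omega)
}

#' Simulate a within-host infection
#'
#' Integrates the two-strain ODE system with event detection and returns the
#' trajectory together with an outcome summary. Total transmission
#' \eqn{\Lambda = \int_0^\tau \lambda(t)\,dt} and, for each requested
#' bottleneck size n, the co-transmission integrals are accumulated as
#' auxiliary ODE states, so the integrals are located exactly at the
#' terminating event.
#'
#' Termination: the infection ends at the first of (i) pathology
#' \code{W + v*M} reaching \code{phi} ("pathology"), (ii) combined density
#' \code{W + M} falling to \code{omega} ("clearance"), or (iii) the horizon
#' \code{t_max} ("horizon", with a warning). Because the inoculum may start
#' at the clearance threshold, the clearance event is armed only once
#' combined density first exceeds 10 * omega; an infection that decays from
#' the start (never arming) is detected as cleared when density halves.
#'
#' @param params A \code{\link{within_host_params}} object with
#'   \code{w0 + m0 > 0}.
#' @param dense_n Number of equally spaced trajectory points returned over
#'   \code{[0, tau]} (a second integration pass; the outcome quantities come
#'   from the event-located first pass). Set to 0 to skip the dense pass.
#' @param rtol,atol Integrator tolerances (lsodar, stiff-capable).
#' @return A list of class \code{infection_sim} with elements
#'   \describe{
#'     \item{trajectory}{data.frame \code{t, W, M, I, lambda, alpha, theta,
#'       Lambda_cum} (dense pass; \code{NULL} if \code{dense_n = 0}).}
#'     \item{outcome}{list of class \code{infection_outcome}: \code{tau},
#'       \code{total_transmission}, \code{end_cause}, and \code{bottleneck}, a
#'       data.frame with columns \code{n, b, c} (b is \code{NA} for
#'       single-strain infections where it is degenerate only when c = 1).}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- simulate_infection(within_host_params(phi = 1e12))
#' sim$outcome$end_cause
#' @export
simulate_infection <- function(params, dense_n = 1001L,
                               rtol = 1e-8, atol = 1e-10) {
  validate_within_host_params(params)
  if (params$w0 + params$m0 <= 0)
    stop("w0 + m0 must be positive", call. = FALSE)
  ns <- params$bottlenecks
  K <- length(ns)
  y0 <- c(params$w0, params$m0, params$i0, 0, numeric(2L * K))
  parms <- list(p = params, deltaM = as.numeric(params$m0 > 0), ns = ns,
                arm_level = 10 * params$omega,
                decay_level = 0.5 * min(params$omega, params$w0 + params$m0))

  run <- function(y, t0, t1, rootfun) {
    out <- tryCatch(
      deSolve::ode(y, c(t0, t1), wh_rhs, parms, method = "lsodar",
                   rootfun = rootfun, rtol = rtol, atol = atol,
                   maxsteps = 1e5),
      warning = function(w) stop("integrator failure: ", conditionMessage(w),
                                 call. = FALSE))
    if (anyNA(out) || any(!is.finite(out)))
      stop("non-finite state during integration", call. = FALSE)
    out
  }

  armed <- (params$w0 + params$m0) >= parms$arm_level
  t_end <- NA_real_; cause <- "horizon"
  if (!armed) {
    outA <- run(y0, 0, params$t_max, wh_root_a)
    troot <- attr(outA, "troot")
    iroot <- attr(outA, "iroot")
    last <- outA[nrow(outA), -1L]
    if (length(troot)) {
      if (iroot[1L] == 1L) {
        t_end <- troot; cause <- "pathology"
      } else if (iroot[3L] == 1L) {
        t_end <- troot; cause <- "clearance"
      } else {
        armed <- TRUE
        y0b <- pmax(last, 0); t0b <- troot
      }
    }
    if (armed) {
      outB <- run(y0b, t0b, params$t_max, wh_root_b)
      troot <- attr(outB, "troot")
      iroot <- attr(outB, "iroot")
      last <- outB[nrow(outB), -1L]
      if (length(troot)) {
        t_end <- troot
        cause <- if (iroot[1L] == 1L) "pathology" else "clearance"
      }
    }
  } else {
    outB <- run(y0, 0, params$t_max, wh_root_b)
    troot <- attr(outB, "troot")
    iroot <- attr(outB, "iroot")
    last <- outB[nrow(outB), -1L]
    if (length(troot)) {
      t_end <- troot
      cause <- if (iroot[1L] == 1L) "pathology" else "clearance"
    }
  }
  if (is.na(t_end)) {
    t_end <- params$t_max
    warning("infection did not terminate before t_max; end_cause = horizon",
            call. = FALSE)
  }

  Lambda <- last[[4L]]
  Ic <- last[4L + seq_len(K)]
  Ib <- last[4L + K + seq_len(K)]
  cvals <- if (Lambda > 0) pmin(pmax(Ic / Lambda, 0), 1) else rep(0, K)
  cvals[ns == 1L] <- 0  # exact: integrand vanishes pointwise for n = 1
  bvals <- ifelse(1 - cvals > 0 & Lambda > 0,
                  pmin(pmax(Ib / ((1 - cvals) * Lambda), 0), 1), NA_real_)
  outcome <- structure(
    list(tau = t_end, total_transmission = Lambda, end_cause = cause,
         bottleneck = data.frame(n = ns, b = as.numeric(bvals),
                                 c = as.numeric(cvals))),
    class = "infection_outcome")

  traj <- NULL
  if (dense_n > 0) {
    tgrid <- seq(0, t_end, length.out = max(dense_n, 2L))
    dd <- tryCatch(
      deSolve::ode(y0, tgrid, wh_rhs, parms, method = "lsodar",
                   rtol = rtol, atol = atol, maxsteps = 1e5),
      warning = function(w) stop("integrator failure: ", conditionMessage(w),
                                 call. = FALSE))
    W <- pmax(dd[, 2L], 0); M <- pmax(dd[, 3L], 0); I <- pmax(dd[, 4L], 0)
    lam <- transmission_rate(W, M, params,
                             mutant_present = params$m0 > 0)
    denom <- W + params$z * M
    theta <- ifelse(denom > 0, params$z * M / denom, NA_real_)
    traj <- data.frame(t = dd[, 1L], W = W, M = M, I = I,
                       lambda = lam,
                       alpha = pathology(W, M, params$v),
                       theta = theta,
                       Lambda_cum = dd[, 5L])
  }

  structure(list(trajectory = traj, outcome = outcome, params = params),
            class = "infection_sim")
}

#' @export
print.infection_outcome <- function(x, ...) {
  cat(sprintf("Infection outcome: tau = %.4g, Lambda = %.6g, end = %s\n",
              x$tau, x$total_transmission, x$end_cause))
  print(x$bottleneck, row.names = FALSE)
  invisible(x)
}

#' @export
print.infection_sim <- function(x, ...) {
  print(x$outcome)
  if (!is.null(x$trajectory))
    cat(sprintf("Trajectory: %d points over [0, %.4g]\n",
                nrow(x$trajectory), x$outcome$tau))
  invisible(x)
}

#' Total transmission of a simulated infection
#'
#' Returns \eqn{\Lambda = \int_0^\tau \lambda(t)\,dt}, accumulated as an
#' auxiliary ODE state during integration (equal, within tolerance, to
#' quadrature of lambda over the returned trajectory).
#'
#' @param sim An \code{infection_sim} from \code{\link{simulate_infection}}.
#' @return Nonnegative total transmission.
#' @export
total_transmission <- function(sim) {
  stopifnot(inherits(sim, "infection_sim"))
  sim$outcome$total_transmission
}

#' Co-transmission probabilities for a bottleneck size
#'
#' For a co-infection with transmissibility-weighted mutant fraction
#' \eqn{\theta(t)} and bottleneck n, the probability that a transmission
#' event carries both strains is
#' \deqn{c = \frac{1}{\Lambda_c}\int_0^\tau (1-\theta^n-(1-\theta)^n)
#'   \lambda\,dt}
#' and the probability that a single-strain event carries the mutant is
#' \deqn{b = \frac{1}{(1-c)\Lambda_c}\int_0^\tau \theta^n \lambda\,dt.}
#'
#' @param sim An \code{infection_sim} whose parameters requested bottleneck
#'   size \code{n}.
#' @param n Bottleneck size (one of \code{sim$params$bottlenecks}).
#' @return Named numeric vector \code{c(b = , c = )}.
#' @export
cotransmission_probs <- function(sim, n) {
  stopifnot(inherits(sim, "infection_sim"))
  tab <- sim$outcome$bottleneck
  i <- match(as.integer(n), tab$n)
  if (is.na(i))
    stop("bottleneck n = ", n, " was not requested in params", call. = FALSE)
  if (sim$outcome$total_transmission <= 0)
    stop("total transmission is zero; b and c undefined", call. = FALSE)
  if (is.na(tab$b[i]) && tab$c[i] < 1)
    stop("b undefined for this trajectory", call. = FALSE)
  if (tab$c[i] >= 1)
    stop("c = 1: no single-strain events, b undefined", call. = FALSE)
  c(b = tab$b[i], c = tab$c[i])
}

#' Dominance of a mutant strain
#'
#' Dominance measures how closely the total transmission of a co-infection
#' matches that of the mutant alone:
#' \deqn{d = (\Lambda_c - \Lambda_w) / (\Lambda_m - \Lambda_w).}
#' Values outside [0, 1] indicate under- or overdominance.
#'
#' @param lambda_w Total transmission of a wild-type-only infection.
#' @param lambda_m Total transmission of a mutant-only infection.
#' @param lambda_c Total transmission of the co-infection.
#' @return Dominance d (finite; errors when \code{lambda_m == lambda_w}).
#' @examples
#' dominance(10, 20, 15)  # 0.5
#' @export
dominance <- function(lambda_w, lambda_m, lambda_c) {
  if (any(lambda_m == lambda_w))
    stop("dominance undefined for a neutral mutant (lambda_m == lambda_w)",
         call. = FALSE)
  (lambda_c - lambda_w) / (lambda_m - lambda_w)
}
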