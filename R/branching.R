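#' Branching-process parameters
#'
#' Parameters of the three-type (wild-type W, mutant M, co-infection C)
#' discrete-generation branching process of evolutionary emergence. A
#' wild-type infection mutates with probability \code{mu1} (re-classifying it
#' as a co-infection) and otherwise leaves Poisson(\code{Rw}) wild-type
#' progeny; a mutant infection reverts with probability \code{mu2} and
#' otherwise leaves Poisson(\code{Rm}) mutant progeny; a co-infection leaves
#' Poisson progeny of all three types with means given by
#' \code{\link{offspring_means}}. The co-infection reproduction number is
#' \code{Rc = d*Rm + (1-d)*Rw}, clamped at zero for underdominant
#' combinations.
#'
#' @param Rw Basic reproduction number of the wild-type (>= 0).
#' @param Rm Basic reproduction number of the mutant (>= 0).
#' @param d Dominance of the mutant in co-infections (may lie outside [0, 1]).
#' @param c Probability that a transmission event from a co-infection carries
#'   both strains (another co-infection), in [0, 1].
#' @param b Probability that a single-strain transmission event from a
#'   co-infection carries the mutant, in [0, 1].
#' @param mu1 Wild-type to mutant mutation probability, in [0, 1].
#' @param mu2 Mutant to wild-type reversion probability, in [0, 1].
#' @return An object of class \code{branching_params}.
#' @examples
#' branching_params(Rw = 0.75, Rm = 1.5, d = 1)
#' @export
branching_params <- function(Rw = 0.75, Rm = 1.5, d = 0.5,
                             c = 0.5, b = 0.5, mu1 = 0.01, mu2 = 0.01) {
  p <- list(Rw = Rw, Rm = Rm, d = d, c = c, b = b, mu1 = mu1, mu2 = mu2)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  if (Rw < 0 || Rm < 0) stop("Rw and Rm must be >= 0", call. = FALSE)
  for (nm in c("c", "b", "mu1", "mu2"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  class(p) <- "branching_params"
  p
}

#' @export
print.branching_params <- function(x, ...) {
  m <- offspring_means(x)
  cat(sprintf(
    "Branching-process parameters: Rw = %g, Rm = %g, d = %g\n", x$Rw, x$Rm,
    x$d))
  cat(sprintf("  c = %g, b = %g, mu1 = %g, mu2 = %g\n",
              x$c, x$b, x$mu1, x$mu2))
  cat(sprintf("  derived: Rc = %g (Rcw = %g, Rcm = %g, Rcc = %g)\n",
              m["Rc"], m["Rcw"], m["Rcm"], m["Rcc"]))
  invisible(x)
}

#' Offspring means of a co-infection
#'
#' A co-infection with reproduction number \code{Rc = max(0, d*Rm + (1-d)*Rw)}
#' produces co-infection, mutant-only and wild-type-only progeny with Poisson
#' means \code{Rcc = c*Rc}, \code{Rcm = (1-c)*b*Rc} and
#' \code{Rcw = (1-c)*(1-b)*Rc}; the three components sum to \code{Rc}.
#'
#' @param params A \code{\link{branching_params}} object.
#' @return Named numeric vector \code{c(Rc, Rcw, Rcm, Rcc)}.
#' @examples
#' offspring_means(branching_params(d = 1))  # Rc = Rm
#' @export
offspring_means <- function(params) {
  stopifnot(inherits(params, "branching_params"))
  Rc <- max(0, params$d * params$Rm + (1 - params$d) * params$Rw)
  c(Rc = Rc,
    Rcw = (1 - params$c) * (1 - params$b) * Rc,
    Rcm = (1 - params$c) * params$b * Rc,
    Rcc = params$c * Rc)
}

#' Probability generating function of the three-type offspring distribution
#'
#' Evaluates the multi-type PGF at \code{s = (sW, sM, sC)}. Mutation and
#' reversion re-classify an infection as a co-infection before it reproduces,
#' so a mutated wild-type reproduces exactly as a co-infection:
#' \deqn{f_C(s) = \exp(R_{cw}(s_W-1) + R_{cm}(s_M-1) + R_{cc}(s_C-1))}
#' \deqn{f_W(s) = (1-\mu_1)\exp(R_w(s_W-1)) + \mu_1 f_C(s)}
#' \deqn{f_M(s) = (1-\mu_2)\exp(R_m(s_M-1)) + \mu_2 f_C(s)}
#'
#' @param s Numeric triple \code{(sW, sM, sC)}, each in [0, 1].
#' @param params A \code{\link{branching_params}} object.
#' @return Numeric triple \code{(fW, fM, fC)}, each in [0, 1].
#' @examples
#' offspring_pgf(c(1, 1, 1), branching_params())  # (1, 1, 1)
#' @export
offspring_pgf <- function(s, params) {
  stopifnot(inherits(params, "branching_params"))
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("s must be a triple in the unit cube", call. = FALSE)
  m <- offspring_means(params)
  fC <- exp(m[["Rcw"]] * (s[1L] - 1) + m[["Rcm"]] * (s[2L] - 1) +
              m[["Rcc"]] * (s[3L] - 1))
  fW <- (1 - params$mu1) * exp(params$Rw * (s[1L] - 1)) + params$mu1 * fC
  fM <- (1 - params$mu2) * exp(params$Rm * (s[2L] - 1)) + params$mu2 * fC
  c(fW = fW, fM = fM, fC = fC)
}

# Mean offspring matrix: entry [i, j] is the expected number of type-j
# progeny of one type-i infection (types W, M, C; mutation/reversion
# re-classification folded in).
mean_matrix <- function(params, m = offspring_means(params)) {
  rbind(
    W = c((1 - params$mu1) * params$Rw + params$mu1 * m[["Rcw"]],
          params$mu1 * m[["Rcm"]], params$mu1 * m[["Rcc"]]),
    M = c(params$mu2 * m[["Rcw"]],
          (1 - params$mu2) * params$Rm + params$mu2 * m[["Rcm"]],
          params$mu2 * m[["Rcc"]]),
    C = c(m[["Rcw"]], m[["Rcm"]], m[["Rcc"]]))
}

# For each start type, is extinction certain (all reachable types form a
# system with spectral radius <= 1)?
extinction_certain <- function(params, m = offspring_means(params)) {
  A <- mean_matrix(params, m)
  adj <- A > 0
  vapply(1:3, function(i) {
    reach <- rep(FALSE, 3L); reach[i] <- TRUE
    repeat {
      new <- reach | (colSums(adj[reach, , drop = FALSE]) > 0)
      if (identical(new, reach)) break
      reach <- new
    }
    rho <- max(Mod(eigen(A[reach, reach, drop = FALSE],
                         only.values = TRUE)$values))
    rho <= 1
  }, logical(1))
}

# PGF map without the unit-cube check (hot path; Newton iterates may sit a
# rounding error outside [0,1])
pgf_map <- function(s, params, m) {
  fC <- exp(m[["Rcw"]] * (s[1L] - 1) + m[["Rcm"]] * (s[2L] - 1) +
              m[["Rcc"]] * (s[3L] - 1))
  c((1 - params$mu1) * exp(params$Rw * (s[1L] - 1)) + params$mu1 * fC,
    (1 - params$mu2) * exp(params$Rm * (s[2L] - 1)) + params$mu2 * fC,
    fC)
}

#' Extinction probabilities of the three-type branching process
#'
#' Computes the minimal fixed point q = f(q) of the multi-type PGF map, i.e.
#' the probabilities that a process started from a single wild-type, mutant
#' or co-infection eventually dies out. Functional iteration from the zero
#' vector converges monotonically to the minimal fixed point; after a burn-in
#' it is polished by a damped Newton step on q - f(q) (numerical Jacobian) so
#' that near-critical parameter sets, where plain iteration converges only
#' like O(1/n), still reach tight residuals. Emergence probabilities are the
#' complements 1 - q.
#'
#' @param params A \code{\link{branching_params}} object.
#' @param tol Convergence tolerance on the sup-norm residual ||q - f(q)||.
#' @param max_iter Iteration cap for the fallback plain iteration.
#' @return An object of class \code{extinction_solution}: list with
#'   \code{q} (named triple \code{qW, qM, qC}), \code{emergence} (named
#'   triple \code{1 - q}), \code{iterations}, \code{converged},
#'   \code{residual}.
#' @examples
#' extinction_probability(branching_params(Rw = 0.75, Rm = 1.5, d = 1))
#' @export
extinction_probability <- function(params, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(params, "branching_params"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  m <- offspring_means(params)
  f <- function(q) pgf_map(q, params, m)
  resid <- function(q) max(abs(q - f(q)))

  # extinction is certain from type i iff every type reachable from i forms a
  # (sub)critical system: spectral radius of the restricted mean matrix <= 1.
  # Deciding this exactly avoids the O(sqrt(eps)) limit of root-finding at a
  # critical point, where q - f(q) has a double root at q = 1.
  certain <- extinction_certain(params, m)
  if (any(certain)) {
    # pin certain components at their exact value 1 and solve the rest
    raw_f <- f
    f <- function(q) { r <- raw_f(q); r[certain] <- 1; r }
  }

  q <- ifelse(certain, 1, 0)
  burn <- 1000L
  it <- 0L
  for (i in seq_len(burn)) {
    qn <- f(q)
    it <- it + 1L
    if (max(abs(qn - q)) < tol) { q <- qn; break }
    q <- qn
  }

  if (resid(q) >= tol) {
    # Newton polish on g(q) = q - f(q); monotone burn-in has placed q below
    # and near the minimal fixed point
    # stop on step size, not residual: at a (near-)critical point q - f(q)
    # has a double root at the fixed point, so the residual goes tiny while q
    # is still O(sqrt(residual)) away
    h <- 1e-7
    for (i in seq_len(200L)) {
      g0 <- q - f(q)
      if (max(abs(g0)) == 0) break
      J <- diag(3)
      for (j in 1:3) {
        qh <- q; qh[j] <- qh[j] + h
        J[, j] <- J[, j] - (f(qh) - f(q)) / h
      }
      step <- tryCatch(solve(J, g0), error = function(e) NULL)
      if (is.null(step)) break
      qn <- pmin(pmax(q - step, 0), 1)
      it <- it + 1L
      if (resid(qn) > resid(q)) break  # not improving; fall back
      q <- qn
      if (max(abs(step)) < tol / 4) break
    }
  }

  if (resid(q) >= tol) {
    while (it < max_iter) {
      qn <- f(q)
      it <- it + 1L
      if (max(abs(qn - q)) < tol) { q <- qn; break }
      q <- qn
    }
  }

  q[certain] <- 1
  r <- resid(q)  # resid sees the pinned map
  converged <- r < max(tol, 1e-10)
  if (!converged)
    warning("extinction fixed point not converged (residual ",
            format(r, digits = 3), ")", call. = FALSE)
  q <- pmin(pmax(q, 0), 1)
  structure(list(q = c(qW = q[1L], qM = q[2L], qC = q[3L]),
                 emergence = c(W = 1 - q[1L], M = 1 - q[2L], C = 1 - q[3L]),
                 iterations = it, converged = converged, residual = r,
                 params = params),
            class = "extinction_solution")
}

#' @export
print.extinction_solution <- function(x, ...) {
  cat("Extinction probabilities (qW, qM, qC):",
      sprintf("%.6f", x$q), "\n")
  cat("Emergence (1 - q):            ", sprintf("%.6f", x$emergence), "\n")
  cat(sprintf("  %d iterations, residual %.2e, converged: %s\n",
              x$iterations, x$residual, x$converged))
  invisible(x)
}

#' Probability of evolutionary emergence
#'
#' The probability that an infection chain started from a single infection of
#' the given type does not go extinct, P(emergence) = 1 - P(extinction).
#'
#' @param params A \code{\link{branching_params}} object.
#' @param start_type One of \code{"W"} (wild-type, the default), \code{"M"}
#'   (mutant) or \code{"C"} (co-infection).
#' @param ... Passed to \code{\link{extinction_probability}}.
#' @return Emergence probability in [0, 1].
#' @examples
#' emergence_probability(branching_params(Rw = 0.75, Rm = 1.5, d = 1))
#' @export
emergence_probability <- function(params, start_type = c("W", "M", "C"),
                                  ...) {
  start_type <- match.arg(start_type)
  sol <- extinction_probability(params, ...)
  unname(sol$emergence[start_type])
}

#' Monte-Carlo simulation of infection chains
#'
#' Simulates the three-type branching process generation by generation:
#' each wild-type infection mutates with probability \code{mu1} (becoming a
#' co-infection for reproduction), each mutant reverts with probability
#' \code{mu2}, and progeny counts are Poisson draws with the appropriate
#' means. A chain is declared emerged when the total number of concurrent
#' infections reaches \code{emergence_cap}, extinct when it hits zero, and
#' censored at \code{gen_cap} generations (censored chains are counted as
#' emerged; the censoring fraction is reported so the bias is bounded).
#' Serves as an independent stochastic check on
#' \code{\link{extinction_probability}}.
#'
#' @param params A \code{\link{branching_params}} object.
#' @param start_type Initial infection type, \code{"W"}, \code{"M"} or
#'   \code{"C"}.
#' @param n_chains Number of independent chains.
#' @param seed RNG seed (chains are reproducible given the seed).
#' @param emergence_cap Population size at which a chain counts as emerged.
#' @param gen_cap Generation cap.
#' @return List with \code{estimate} (emerged fraction), \code{se} (binomial
#'   standard error), \code{n_emerged}, \code{n_extinct}, \code{n_censored},
#'   \code{censored_fraction}, \code{n_chains}.
#' @examples
#' simulate_chains(branching_params(Rw = 0, Rm = 0), n_chains = 10, seed = 1)
#' @export
simulate_chains <- function(params, start_type = c("W", "M", "C"),
                            n_chains = 1000L, seed = NULL,
                            emergence_cap = 1000L, gen_cap = 200L) {
  stopifnot(inherits(params, "branching_params"))
  start_type <- match.arg(start_type)
  n_chains <- as.integer(n_chains)
  if (n_chains < 1L || emergence_cap < 1L || gen_cap < 1L)
    stop("n_chains and caps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- offspring_means(params)

  nW <- rep.int(if (start_type == "W") 1L else 0L, n_chains)
  nM <- rep.int(if (start_type == "M") 1L else 0L, n_chains)
  nC <- rep.int(if (start_type == "C") 1L else 0L, n_chains)
  status <- rep.int(0L, n_chains)  # 0 active, 1 emerged, 2 extinct, 3 censored
  active <- seq_len(n_chains)

  for (g in seq_len(gen_cap)) {
    if (!length(active)) break
    aW <- nW[active]; aM <- nM[active]; aC <- nC[active]
    mut <- stats::rbinom(length(active), aW, params$mu1)
    rev <- stats::rbinom(length(active), aM, params$mu2)
    co <- aC + mut + rev
    newW <- stats::rpois(length(active), (aW - mut) * params$Rw) +
      stats::rpois(length(active), co * m[["Rcw"]])
    newM <- stats::rpois(length(active), (aM - rev) * params$Rm) +
      stats::rpois(length(active), co * m[["Rcm"]])
    newC <- stats::rpois(length(active), co * m[["Rcc"]])
    nW[active] <- newW; nM[active] <- newM; nC[active] <- newC
    tot <- newW + newM + newC
    status[active[tot == 0L]] <- 2L
    status[active[tot >= emergence_cap]] <- 1L
    active <- active[tot > 0L & tot < emergence_cap]
  }
  status[active] <- 3L

  n_emerged <- sum(status == 1L)
  n_extinct <- sum(status == 2L)
  n_censored <- sum(status == 3L)
  est <- (n_emerged + n_censored) / n_chains
  list(estimate = est,
       se = sqrt(est * (1 - est) / n_chains),
       n_emerged = n_emerged, n_extinct = n_extinct,
       n_censored = n_censored,
       censored_fraction = n_censored / n_chains,
       n_chains = n_chains)
}
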