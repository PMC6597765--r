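#' Parameter ranges for global sensitivity analysis
#'
#' Lower/upper bounds for each branching-process parameter, used for Latin
#' hypercube sampling. Defaults: Rw in [0, 1] (a maladapted wild-type),
#' Rm in [1, 4], d in [0, 1] (set \code{extended_d = TRUE} for [-0.5, 1.5],
#' covering under- and overdominance), and c, b, mu1, mu2 in [0, 1].
#'
#' @param Rw,Rm,d,c,b,mu1,mu2 Length-2 numeric ranges \code{c(low, high)}.
#' @param extended_d Use the extended dominance range [-0.5, 1.5].
#' @return An object of class \code{param_ranges}: a named list of
#'   \code{c(low, high)} pairs.
#' @examples
#' param_ranges()
#' @export
param_ranges <- function(Rw = base::c(0, 1), Rm = base::c(1, 4),
                         d = if (extended_d) base::c(-0.5, 1.5)
                             else base::c(0, 1),
                         c = base::c(0, 1), b = base::c(0, 1),
                         mu1 = base::c(0, 1), mu2 = base::c(0, 1),
                         extended_d = FALSE) {
  r <- list(Rw = Rw, Rm = Rm, d = d, c = c, b = b, mu1 = mu1, mu2 = mu2)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v) || v[1L] > v[2L])
      stop("range for '", nm, "' must be c(low, high) with low <= high",
           call. = FALSE)
  }
  structure(r, class = "param_ranges")
}

#' Latin hypercube sample over parameter ranges
#'
#' Divides each parameter range into N equal-width strata and draws exactly
#' one uniform sample per stratum, with independent random pairing across
#' parameters (stratification via \code{lhs::randomLHS}).
#'
#' @param ranges A \code{\link{param_ranges}} object (or any named list of
#'   \code{c(low, high)} pairs).
#' @param N Number of samples (>= 2).
#' @param seed RNG seed; the design is reproducible given the seed.
#' @return An object of class \code{lhs_design}: a data.frame with N rows and
#'   one column per parameter, with attributes \code{seed} and \code{ranges}.
#' @examples
#' head(lhs_sample(param_ranges(), N = 10, seed = 1))
#' @export
lhs_sample <- function(ranges, N = 500L, seed = NULL) {
  if (!inherits(ranges, "param_ranges") &&
      !(is.list(ranges) && all(lengths(ranges) == 2L)))
    stop("'ranges' must be a param_ranges object or named list of pairs",
         call. = FALSE)
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- length(ranges)
  u <- lhs::randomLHS(N, k)
  out <- as.data.frame(u)
  names(out) <- names(ranges)
  for (j in seq_len(k)) {
    lo <- ranges[[j]][1L]; hi <- ranges[[j]][2L]
    if (lo == hi) {
      warning("degenerate range for '", names(ranges)[j],
              "': constant column", call. = FALSE)
      out[[j]] <- rep(lo, N)
    } else {
      out[[j]] <- lo + (hi - lo) * u[, j]
    }
  }
  structure(out, class = c("lhs_design", "data.frame"),
            seed = seed, ranges = ranges)
}

#' Partial rank correlation coefficients
#'
#' For each design parameter, the PRCC is the Pearson correlation between (i)
#' the residuals of the parameter's ranks regressed on the ranks of all other
#' parameters, and (ii) the residuals of the response's ranks regressed on
#' the same; i.e. the monotone association between parameter and response
#' after factoring out the other parameters. Ties receive average ranks.
#'
#' @param design An \code{\link{lhs_sample}} design (or data.frame of
#'   parameter columns).
#' @param response Numeric response vector of length \code{nrow(design)}.
#' @return Named numeric vector of PRCCs in [-1, 1].
#' @examples
#' des <- lhs_sample(param_ranges(), N = 50, seed = 1)
#' prcc(des, des$d + 0.01 * seq_len(50))
#' @export
prcc <- function(design, response) {
  X <- as.data.frame(design)
  if (length(response) != nrow(X))
    stop("response length must equal the number of design rows",
         call. = FALSE)
  if (anyNA(response) || anyNA(X))
    stop("missing values in design or response", call. = FALSE)
  if (stats::var(response) == 0)
    stop("constant response: PRCC undefined", call. = FALSE)
  R <- vapply(X, rank, numeric(nrow(X)), ties.method = "average")
  ry <- rank(response, ties.method = "average")
  k <- ncol(R)
  out <- numeric(k)
  names(out) <- colnames(R)
  for (j in seq_len(k)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    # shared projection for both residual vectors
    qz <- qr(Z)
    e1 <- qr.resid(qz, R[, j])
    e2 <- qr.resid(qz, ry)
    out[j] <- if (stats::sd(e1) == 0 || stats::sd(e2) == 0) NA_real_
              else stats::cor(e1, e2)
  }
  out
}

#' Bootstrap confidence intervals for PRCCs
#'
#' Resamples design rows (with their responses) with replacement B times,
#' recomputes all PRCCs per replicate, and returns percentile 2.5%/97.5%
#' intervals.
#'
#' @param design An \code{\link{lhs_sample}} design.
#' @param response Numeric response vector.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed RNG seed for the resampling.
#' @param level Confidence level (default 0.95).
#' @return A data.frame of class \code{prcc_result} with columns
#'   \code{parameter, prcc, ci_low, ci_high} and attributes \code{N},
#'   \code{B}, \code{level}.
#' @export
bootstrap_prcc_ci <- function(design, response, B = 500L, seed = NULL,
                              level = 0.95) {
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  X <- as.data.frame(design)
  point <- prcc(X, response)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  reps <- matrix(NA_real_, B, length(point))
  for (bb in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[bb, ] <- tryCatch(prcc(X[idx, , drop = FALSE], response[idx]),
                           error = function(e) rep(NA_real_, length(point)))
  }
  a <- (1 - level) / 2
  ci <- apply(reps, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(parameter = names(point), prcc = unname(point),
                    ci_low = pmin(ci[1L, ], point),
                    ci_high = pmax(ci[2L, ], point),
                    row.names = NULL)
  structure(out, class = c("prcc_result", "data.frame"),
            N = n, B = B, level = level)
}

#' Global sensitivity of emergence probability
#'
#' Latin hypercube sampling over the branching-process parameter ranges,
#' evaluation of the emergence probability (from a single wild-type
#' infection) for every sampled parameter set, and PRCC estimation with
#' bootstrap confidence intervals. Parameters can be pinned to fixed values
#' (e.g. \code{fixed = c(d = 0)}), in which case they are excluded from the
#' design and the PRCC table.
#'
#' @param ranges A \code{\link{param_ranges}} object.
#' @param N LHS sample size.
#' @param B Bootstrap replicates for the PRCC confidence intervals.
#' @param seed RNG seed (controls both the design and the bootstrap).
#' @param fixed Optional named numeric vector of pinned parameters.
#' @param start_type Start type for emergence (default "W").
#' @return List with elements \code{prcc} (a \code{prcc_result} data.frame),
#'   \code{design} (the LHS design of varied parameters) and \code{response}
#'   (emergence probabilities).
#' @examples
#' \donttest{
#' emergence_sensitivity(param_ranges(), N = 50, B = 50, seed = 1)$prcc
#' }
#' @export
emergence_sensitivity <- function(ranges = param_ranges(), N = 500L,
                                  B = 500L, seed = NULL, fixed = NULL,
                                  start_type = "W") {
  stopifnot(inherits(ranges, "param_ranges"))
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% names(ranges)))
      stop("'fixed' must be a named vector of known parameters",
           call. = FALSE)
    ranges <- structure(ranges[setdiff(names(ranges), names(fixed))],
                        class = "param_ranges")
  }
  design <- lhs_sample(ranges, N = N, seed = seed)
  response <- vapply(seq_len(nrow(design)), function(i) {
    args <- as.list(design[i, , drop = FALSE])
    args[names(fixed)] <- as.list(unname(fixed))
    emergence_probability(do.call(branching_params, args),
                          start_type = start_type)
  }, numeric(1))
  res <- bootstrap_prcc_ci(design, response, B = B,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  list(prcc = res, design = design, response = response)
}
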