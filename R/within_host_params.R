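#' Within-host model parameters
#'
#' Construct and validate the parameter set for the two-strain within-host
#' model. The model tracks the densities of a wild-type strain (W), a mutant
#' strain (M) and a strain-transcending immune response (I):
#' \deqn{dW/dt = r_w W - k W I}
#' \deqn{dM/dt = r_m M - k M I}
#' \deqn{dI/dt = s I (W + M) / (A + W + M)}
#' Transmission is a saturating (log10) function of weighted pathogen density,
#' pathology is a virulence-weighted linear function, and the infection ends
#' when pathology exceeds \code{phi} or combined density falls below
#' \code{omega}.
#'
#' @param rw Wild-type replication rate (per unit time).
#' @param rm Mutant replication rate (per unit time).
#' @param k Immune killing rate (per unit immune density per unit time).
#' @param s Immune growth rate (per unit time).
#' @param A Immune-sensitivity tuning density.
#' @param x Host-infectivity boost conferred by the mutant (dimensionless,
#'   >= 0). Applies to both strains, only when the infection contains the
#'   mutant.
#' @param z Relative transmissibility of the mutant (dimensionless, > 0).
#' @param v Relative virulence of the mutant (dimensionless, >= 0).
#' @param phi Pathology threshold: the infection ends when W + v*M exceeds it.
#' @param omega Clearance threshold: the infection ends when W + M drops
#'   below it.
#' @param w0,m0,i0 Initial densities of wild-type, mutant and immune response.
#' @param t_max Integration horizon (time units).
#' @param bottlenecks Integer vector of transmission bottleneck sizes n >= 1
#'   for which co-transmission summaries are accumulated.
#'
#' @return An object of class \code{within_host_params} (a named list).
#' @examples
#' p <- within_host_params()             # defaults: neutral mutant absent
#' p2 <- within_host_params(rm = 1.5, m0 = 1, phi = 1e12)
#' @export
within_host_params <- function(rw = 1, rm = 1, k = 1e-4, s = 0.8, A = 1e3,
                               x = 0, z = 1, v = 1,
                               phi = 1e8, omega = 1,
                               w0 = 1, m0 = 0, i0 = 1,
                               t_max = 1e4,
                               bottlenecks = c(1L, 2L, 5L, 10L)) {
  p <- list(rw = rw, rm = rm, k = k, s = s, A = A, x = x, z = z, v = v,
            phi = phi, omega = omega, w0 = w0, m0 = m0, i0 = i0,
            t_max = t_max, bottlenecks = as.integer(bottlenecks))
  class(p) <- "within_host_params"
  validate_within_host_params(p)
  p
}

validate_within_host_params <- function(p) {
  num1 <- function(nm) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    val
  }
  for (nm in c("rw", "rm", "k", "s", "A", "x", "v",
               "phi", "omega", "w0", "m0", "i0", "t_max"))
    num1(nm)
  nonneg <- c("rw", "rm", "k", "s", "A", "x", "v", "w0", "m0", "i0")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameters must be nonnegative: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(p$z) || p$z <= 0)
    stop("'z' must be > 0", call. = FALSE)
  if (!(p$phi > p$omega) || p$omega <= 0)
    stop("thresholds must satisfy phi > omega > 0", call. = FALSE)
  if (p$t_max <= 0) stop("'t_max' must be > 0", call. = FALSE)
  if (length(p$bottlenecks) < 1L || anyNA(p$bottlenecks) ||
      any(p$bottlenecks < 1L))
    stop("'bottlenecks' must be positive integers", call. = FALSE)
  invisible(p)
}

#' @export
print.within_host_params <- function(x, ...) {
  cat("Within-host model parameters\n")
  cat(sprintf("  replication: rw = %g, rm = %g\n", x$rw, x$rm))
  cat(sprintf("  immunity:    k = %g, s = %g, A = %g\n", x$k, x$s, x$A))
  cat(sprintf("  phenotype:   x = %g, z = %g, v = %g\n", x$x, x$z, x$v))
  cat(sprintf("  thresholds:  phi = %g, omega = %g\n", x$phi, x$omega))
  cat(sprintf("  initial:     w0 = %g, m0 = %g, i0 = %g\n", x$w0, x$m0, x$i0))
  cat(sprintf("  horizon:     t_max = %g\n", x$t_max))
  cat("  bottlenecks: ", paste(x$bottlenecks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replace fields of a within-host parameter set
#'
#' @param params A \code{within_host_params} object.
#' @param ... Named fields to replace (any constructor argument).
#' @return A validated \code{within_host_params} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "within_host_params"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(dots)] <- dots
  params$bottlenecks <- as.integer(params$bottlenecks)
  validate_within_host_params(params)
  params
}
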