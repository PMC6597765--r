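#' Emergence probability of within-host mutant phenotypes
#'
#' Links the two model layers: for each value of a phenotype parameter the
#' within-host scan provides the dominance d and, per bottleneck size n, the
#' co-transmission probabilities (b, c); the mutant reproduction number is
#' scaled from the wild-type's by relative total transmission,
#' \code{Rm = Rw * lambda_m / lambda_w}. These feed the branching process,
#' and the emergence probability from a single wild-type infection is
#' computed for every (phenotype value, n) pair.
#'
#' Rows where the mutant is exactly neutral (\code{lambda_m == lambda_w}, d
#' undefined) are retained with missing d and emergence, preserving grid
#' alignment. On every other row the pipeline asserts the internal
#' consistency identity \code{d*Rm + (1-d)*Rw == Rw * lambda_c / lambda_w}
#' (both sides follow from the definition of d).
#'
#' @param scenario One of the names of \code{\link{phenotype_scenarios}}.
#' @param grid Phenotype parameter values (default: the scenario's scan
#'   default, 50 evenly spaced points).
#' @param bottlenecks Bottleneck sizes n.
#' @param Rw Wild-type basic reproduction number (> 0).
#' @param mu1,mu2 Mutation and reversion probabilities.
#' @param params Baseline within-host parameters for the scan.
#' @return A data.frame with columns \code{scenario, value, n, d, b, c, Rm,
#'   emergence}.
#' @examples
#' \donttest{
#' phenotype_emergence("increased_growth", grid = c(1.2, 1.5),
#'                     bottlenecks = c(1, 10))
#' }
#' @export
phenotype_emergence <- function(scenario, grid = NULL,
                                bottlenecks = c(1L, 2L, 5L, 10L),
                                Rw = 0.9, mu1 = 0.01, mu2 = 0.01,
                                params = within_host_params()) {
  if (Rw <= 0) stop("Rw must be > 0", call. = FALSE)
  params <- update_params(params, bottlenecks = as.integer(bottlenecks))
  scan <- scan_phenotype(scenario, grid = grid, params = params)
  ns <- as.integer(bottlenecks)
  rows <- lapply(seq_len(nrow(scan)), function(i) {
    row <- scan[i, ]
    Rm <- Rw * row$lambda_m / row$lambda_w
    out <- data.frame(scenario = scenario, value = row$value, n = ns,
                      d = row$d, b = NA_real_, c = NA_real_, Rm = Rm,
                      emergence = NA_real_)
    for (j in seq_along(ns)) {
      out$b[j] <- row[[paste0("b_", ns[j])]]
      out$c[j] <- row[[paste0("c_", ns[j])]]
    }
    if (!is.na(row$d)) {
      Rc_direct <- row$d * Rm + (1 - row$d) * Rw
      Rc_scaled <- Rw * row$lambda_c / row$lambda_w
      if (abs(Rc_direct - Rc_scaled) >
          1e-6 * max(abs(Rc_scaled), .Machine$double.eps))
        stop("internal consistency failure: d*Rm + (1-d)*Rw != ",
             "Rw*lambda_c/lambda_w", call. = FALSE)
      for (j in seq_along(ns)) {
        bp <- branching_params(Rw = Rw, Rm = Rm, d = row$d,
                               c = out$c[j],
                               b = if (is.na(out$b[j])) 0.5 else out$b[j],
                               mu1 = mu1, mu2 = mu2)
        out$emergence[j] <- emergence_probability(bp, start_type = "W")
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
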