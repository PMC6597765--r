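#' Hypothetical mutant phenotype scenarios
#'
#' Five single-parameter mutant phenotypes, each of which can raise the
#' mutant's transmission potential above the wild-type baseline. Each
#' scenario varies one within-host parameter over a range and uses a
#' scenario-specific pathology threshold \code{phi}; all other parameters
#' stay at their defaults.
#'
#' \describe{
#'   \item{increased_growth}{rm in [1, 2], phi = 1e12 — faster replication,
#'     higher density, more transmission (until lethal overshoot).}
#'   \item{decreased_growth}{rm in [0, 1], phi = 1e6 — slower replication
#'     keeps density below the lethal threshold, lengthening transmission.}
#'   \item{decreased_virulence}{v in [0, 1], phi = 1e7 — less pathology per
#'     unit density, delaying or avoiding the lethal threshold.}
#'   \item{increased_transmissibility}{z in [1, 4], phi = 1e8 — a selfish
#'     transmission advantage for the mutant only.}
#'   \item{increased_infectivity}{x in [0, 4], phi = 1e8 — an unselfish boost
#'     to host infectiousness benefiting both strains.}
#' }
#'
#' @return A named list of scenarios, each with elements \code{param} (the
#'   varied parameter name), \code{range} (length-2 numeric), \code{phi} and
#'   \code{neutral} (the parameter value at which the mutant equals the
#'   wild-type).
#' @export
phenotype_scenarios <- function() {
  list(
    increased_growth = list(param = "rm", range = c(1, 2), phi = 1e12,
                            neutral = 1),
    decreased_growth = list(param = "rm", range = c(0, 1), phi = 1e6,
                            neutral = 1),
    decreased_virulence = list(param = "v", range = c(0, 1), phi = 1e7,
                               neutral = 1),
    increased_transmissibility = list(param = "z", range = c(1, 4), phi = 1e8,
                                      neutral = 1),
    increased_infectivity = list(param = "x", range = c(0, 4), phi = 1e8,
                                 neutral = 0)
  )
}

get_scenario <- function(scenario) {
  sc <- phenotype_scenarios()[[scenario]]
  if (is.null(sc))
    stop("unknown scenario '", scenario, "'; must be one of: ",
         paste(names(phenotype_scenarios()), collapse = ", "), call. = FALSE)
  sc
}

#' Scan a mutant phenotype over its parameter grid
#'
#' For each value of the scenario's phenotype parameter, runs three
#' deterministic simulations — wild-type only, mutant only, and co-infection
#' — with the scenario's pathology threshold, and summarises total
#' transmissions, dominance and per-bottleneck co-transmission probabilities.
#'
#' @param scenario One of the names of \code{\link{phenotype_scenarios}}.
#' @param grid Numeric vector of phenotype parameter values, within the
#'   scenario's range. Default: 50 evenly spaced values over the range.
#' @param params Baseline \code{\link{within_host_params}}; the scenario's
#'   \code{phi} and per-value phenotype parameter are overlaid. All three
#'   infection types start from the same total inoculum
#'   \code{T0 = params$w0 + params$m0} (falling back to \code{params$omega}
#'   if zero): wild-type-only runs use \code{(T0, 0)}, mutant-only runs
#'   \code{(0, T0)}, and co-infections split it equally, \code{(T0/2, T0/2)},
#'   so that comparisons of total transmission across infection types are not
#'   confounded by inoculum size.
#' @return A data.frame with one row per grid value: \code{value},
#'   \code{lambda_w}, \code{lambda_m}, \code{lambda_c}, \code{rel_m}
#'   (= lambda_m/lambda_w), \code{rel_c}, \code{d} (NA where the mutant is
#'   exactly neutral), \code{end_m}/\code{end_c} (termination cause of the
#'   mutant-only and co-infection runs; "pathology" marks lethal overshoot),
#'   and \code{b_<n>}/\code{c_<n>} for each bottleneck n.
#' @examples
#' \donttest{
#' scan_phenotype("increased_growth", grid = c(1.2, 1.5))
#' }
#' @export
scan_phenotype <- function(scenario, grid = NULL,
                           params = within_host_params()) {
  sc <- get_scenario(scenario)
  validate_within_host_params(params)
  if (is.null(grid))
    grid <- seq(sc$range[1], sc$range[2], length.out = 50L)
  if (any(grid < sc$range[1] - 1e-12) || any(grid > sc$range[2] + 1e-12))
    stop("grid values outside the scenario range [",
         sc$range[1], ", ", sc$range[2], "]", call. = FALSE)
  base <- update_params(params, phi = sc$phi)
  T0 <- base$w0 + base$m0
  if (T0 <= 0) T0 <- base$omega
  ns <- base$bottlenecks

  # lambda_w does not depend on the mutant phenotype parameter
  wt_only <- update_params(base, w0 = T0, m0 = 0)
  lam_w <- total_transmission(simulate_infection(wt_only, dense_n = 0))

  rows <- lapply(grid, function(val) {
    pv <- do.call(update_params, c(list(base), stats::setNames(list(val),
                                                               sc$param)))
    mut_only <- update_params(pv, w0 = 0, m0 = T0)
    co <- update_params(pv, w0 = T0 / 2, m0 = T0 / 2)
    sim_m <- simulate_infection(mut_only, dense_n = 0)
    sim_c <- simulate_infection(co, dense_n = 0)
    lam_m <- total_transmission(sim_m)
    lam_c <- total_transmission(sim_c)
    d <- if (lam_m == lam_w) NA_real_ else dominance(lam_w, lam_m, lam_c)
    bn <- sim_c$outcome$bottleneck
    out <- data.frame(value = val, lambda_w = lam_w, lambda_m = lam_m,
                      lambda_c = lam_c, rel_m = lam_m / lam_w,
                      rel_c = lam_c / lam_w, d = d,
                      end_m = sim_m$outcome$end_cause,
                      end_c = sim_c$outcome$end_cause)
    for (i in seq_along(ns)) {
      out[[paste0("b_", ns[i])]] <- bn$b[i]
      out[[paste0("c_", ns[i])]] <- bn$c[i]
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "scenario") <- scenario
  attr(res, "phi") <- sc$phi
  res
}
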