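#' Load a run configuration
#'
#' Reads a flat key-value YAML (or JSON-dialect) configuration file and
#' returns validated parameter sets for both model layers, with defaults
#' filled in for unspecified keys. Within-host keys: rw, rm, k, s, A, x, z,
#' v, phi, omega, w0, m0, i0, t_max, bottlenecks. Branching keys: Rw, Rm, d,
#' c, b, mu1, mu2 (defaults Rw = 0.75, Rm = 1.5, d = 0.5, b = c = 0.5,
#' mu1 = mu2 = 0.01). Extra keys: seed, out.
#'
#' @param path Path to the configuration file; an empty or absent body
#'   yields full defaults.
#' @return An object of class \code{run_config}: list with elements
#'   \code{within_host} (a \code{\link{within_host_params}}),
#'   \code{branching} (a \code{\link{branching_params}}), \code{seed} and
#'   \code{out}.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("rm: 1.5", f)
#' load_config(f)$within_host$rm
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop("config must be a flat key-value mapping", call. = FALSE)
  wh_keys <- c("rw", "rm", "k", "s", "A", "x", "z", "v", "phi", "omega",
               "w0", "m0", "i0", "t_max", "bottlenecks")
  bp_keys <- c("Rw", "Rm", "d", "c", "b", "mu1", "mu2")
  extra_keys <- c("seed", "out")
  unknown <- setdiff(names(cfg), c(wh_keys, bp_keys, extra_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  wh <- do.call(within_host_params, cfg[intersect(names(cfg), wh_keys)])
  bp <- do.call(branching_params, cfg[intersect(names(cfg), bp_keys)])
  structure(list(within_host = wh, branching = bp,
                 seed = cfg$seed, out = cfg$out,
                 path = path),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (", x$path, ")\n", sep = "")
  print(x$within_host)
  print(x$branching)
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' Write scenario configuration fixtures
#'
#' Writes one YAML configuration per mutant phenotype scenario (with the
#' scenario's pathology threshold and the varied parameter set to the upper
#' end of its range) plus a neutral-mutant configuration (equal inocula,
#' identical strains) used for closed-form co-transmission checks.
#'
#' @param out_dir Writable directory; created if missing.
#' @return Invisibly, the paths of the six files written.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scs <- phenotype_scenarios()
  paths <- character(0)
  for (nm in names(scs)) {
    sc <- scs[[nm]]
    cfg <- list(phi = sc$phi, w0 = 0.5, m0 = 0.5)
    cfg[[sc$param]] <- sc$range[2L]
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfg, p)
    paths <- c(paths, p)
  }
  neutral <- list(rw = 1, rm = 1, z = 1, v = 1, x = 0, w0 = 0.5, m0 = 0.5,
                  phi = 1e8)
  p <- file.path(out_dir, "neutral.yaml")
  yaml::write_yaml(neutral, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write a results table as CSV with a reproducibility header
#'
#' Prepends comment lines (\code{#}-prefixed) recording the package version,
#' the seed and the full parameter set used, then the CSV body.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param seed Seed used for any randomness in producing \code{df} (may be
#'   \code{NULL}).
#' @param params Named list (or params object) recorded in the header.
#' @return Invisibly, \code{path}.
#' @export
write_run_csv <- function(df, path, seed = NULL, params = NULL) {
  hdr <- c(
    paste0("# coidom ", as.character(utils::packageVersion("coidom"))),
    paste0("# date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("# seed: ", if (is.null(seed)) "none" else seed))
  if (!is.null(params)) {
    flat <- unlist(params)
    hdr <- c(hdr, paste0("# params: ",
                         paste(names(flat), flat, sep = "=",
                               collapse = " ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
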