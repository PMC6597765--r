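# trapezoid quadrature on an irregular grid; independent oracle for the
# auxiliary-state integrals accumulated during ODE integration
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# extinction probability of a single-type Poisson branching process with
# mean R: smallest root of q = exp(R * (q - 1)) in [0, 1]
poisson_extinction <- function(R) {
  if (R <= 1) return(1)
  stats::uniroot(function(q) q - exp(R * (q - 1)),
                 c(0, 1 - 1e-12), tol = 1e-13)$root
}

neutral_coinfection <- function(...) {
  within_host_params(w0 = 0.5, m0 = 0.5, ...)
}
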