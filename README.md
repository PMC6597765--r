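# coidom — co-infection dominance and evolutionary emergence

`coidom` is an R package for studying how two-strain co-infections shape
pathogen evolution, aimed at infectious-disease modellers. It asks: when a
maladapted wild-type pathogen (R₀ < 1) can be rescued from extinction by a
fitter mutant (R₀ > 1), how does the *dominance* of that mutant in
co-infected hosts govern the probability of evolutionary emergence?

The framework has two linked layers:

1. **Within-host layer.** A two-strain ODE model with a shared immune
   response,

       dW/dt = rw·W − k·W·I
       dM/dt = rm·M − k·M·I
       dI/dt = s·I·(W+M)/(A+W+M)

   with transmission rate λ(t) = log₁₀[(1+x·δM)(W+zM)], pathology
   α(t) = W+vM, and termination when α exceeds the lethal threshold Φ or
   total density drops below the clearance threshold Ω. Total transmission
   Λ = ∫₀^τ λ dt is proportional to R₀, and dominance is
   d = (Λc−Λw)/(Λm−Λw) from wild-type-only, mutant-only and co-infection
   runs. With a transmission bottleneck of n particles, the mutant fraction
   θ(t) = zM/(W+zM) yields the co-transmission probability c and the mutant
   share of single-strain transmission b as λ-weighted integrals.

2. **Between-host layer.** A three-type branching process
   (wild-type / mutant / co-infection) with Poisson offspring, mutation μ₁
   and reversion μ₂, and co-infection reproduction number
   Rc = d·Rm + (1−d)·Rw split into progeny types by (b, c). Emergence
   probability is 1 minus the minimal fixed point of the multi-type
   probability generating function, cross-checked by a Monte-Carlo chain
   simulator. Latin hypercube sampling with PRCC (plus bootstrap CIs)
   quantifies parameter influence, and `phenotype_emergence()` chains the
   two layers end to end.

## Worked example

```r
library(coidom)

# neutral co-infection: equal strains, equal inocula
sim <- simulate_infection(within_host_params(w0 = 0.5, m0 = 0.5),
                          dense_n = 0)
sim$outcome
#> Infection outcome: tau = 22.16, Lambda = 93.4125, end = clearance
#>   n   b         c
#>   1 0.5 0.0000000
#>   2 0.5 0.5000000
#>   5 0.5 0.9375000
#>  10 0.5 0.9980469
```

The co-transmission probability matches the closed form c = 1−(1/2)^(n−1)
for a neutral pair (θ ≡ 1/2), and b = 0.5 by symmetry; Λ ≈ 93.4 is the
wild-type baseline total transmission under default parameters.

```r
# dominant vs recessive mutant at the canonical between-host setting
emergence_probability(branching_params(Rw = 0.75, Rm = 1.5, d = 1,
                                       b = 0.5, c = 0.5,
                                       mu1 = 0.01, mu2 = 0.01))
#> [1] 0.01576307
emergence_probability(branching_params(Rw = 0.75, Rm = 1.5, d = 0,
                                       b = 0.5, c = 0.5,
                                       mu1 = 0.01, mu2 = 0.01))
#> [1] 0.005882652
```

A fully dominant mutant is here ~2.7× more likely to emerge than a fully
recessive one with the same R₀ values. The full phenotype pipeline — scan a
within-host mutant phenotype, derive (d, b, c, Rm), compute emergence per
bottleneck size:

```r
phenotype_emergence("decreased_virulence", grid = c(0.05, 0.5),
                    bottlenecks = c(1, 10))
#>              scenario value  n         d   b         c       Rm    emergence
#> 1 decreased_virulence  0.05  1 0.1805785 0.5 0.0000000 1.450087 0.0208346017
#> 2 decreased_virulence  0.05 10 0.1805785 0.5 0.9980469 1.450087 0.0026864626
#> 3 decreased_virulence  0.50  1 0.3738687 0.5 0.0000000 1.008628 0.0003085221
#> 4 decreased_virulence  0.50 10 0.3738687 0.5 0.9980469 1.008628 0.0000000000
```

A strongly attenuated mutant (v = 0.05) is recessive (d ≈ 0.18) yet emerges
~8× more readily through a tight bottleneck (n = 1) than a loose one
(n = 10): single-particle transmission separates it from the wild-type that
otherwise negates its advantage. At v = 0.5 the mutant is barely
supercritical (Rm ≈ 1.01) and emergence is marginal at best.

A thin command-line wrapper over the same functions is installed at
`inst/cli/coidom.R` (subcommands `simulate`, `scan`, `emergence`, `mc`,
`sensitivity`, `phenotype-emergence`, `fixtures`).

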