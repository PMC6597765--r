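---
title: "Methods: within-host co-infection dynamics, dominance, and evolutionary emergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-host co-infection dynamics, dominance, and evolutionary emergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coidom)
```

# The problem

When a pathogen finds itself in an unfavourable environment — a vaccinated
population, a novel host species — its basic reproduction number $R_0$ may
fall below one, so that extinction is certain unless a fitter mutant arises
and spreads in time: *evolutionary emergence*. Whether the mutant succeeds
depends not only on its own $R_0$ but on what happens when mutant and
wild-type share a host. `coidom` implements a two-level framework for this
question: a within-host ODE model that condenses the dynamics of a two-strain
co-infection into a handful of transmission summaries, and a three-type
branching process that turns those summaries into emergence probabilities.

The central concept is *dominance*. By analogy with diploid genetics, the
$R_0$ of a co-infection is written as an interpolation between the two
strains' values,
$$R_c = d\,R_m + (1-d)\,R_w,$$
and $d$ measures how much of the mutant's advantage survives the within-host
interaction: $d = 1$ is a fully dominant mutant, $d = 0$ a fully recessive
one, with under- ($d<0$) and overdominance ($d>1$) possible.

# The within-host layer

## Model

Densities of wild-type $W$, mutant $M$ and a strain-transcending immune
response $I$ follow
$$\frac{dW}{dt} = r_w W - kWI, \qquad
  \frac{dM}{dt} = r_m M - kMI, \qquad
  \frac{dI}{dt} = sI\,\frac{W+M}{A+W+M}.$$
Both strains grow exponentially until the immune response, stimulated by
total pathogen density with half-saturation $A$, controls and clears them.
Defaults ($r_w = r_m = 1$, $k = 10^{-4}$, $s = 0.8$, $A = 10^3$; densities
and times in arbitrary units) give an acute infection: growth to a peak near
$10^8$ around $t \approx 19$, immune control, clearance by $t \approx 22$.

Transmission is a saturating function of weighted density,
$$\lambda(t) = \log_{10}\!\big[(1 + x\,\delta_M)\,(W + zM)\big],$$
where $z$ weights only the mutant (a "selfish" transmissibility advantage)
and $x$ boosts the infectiousness of the whole host (an "unselfish" trait),
only in infections that contain the mutant ($\delta_M$). Pathology is
$\alpha(t) = W + vM$ with $v$ the mutant's relative virulence. The infection
ends at the first of: pathology reaching the lethal threshold $\Phi$,
combined density falling to the clearance threshold $\Omega$, or the horizon
`t_max`. Total transmission is $\Lambda = \int_0^\tau \lambda\,dt$, and
dominance at the within-host level is measured from the three infection
types as
$$d = \frac{\Lambda_c - \Lambda_w}{\Lambda_m - \Lambda_w}.$$

The mutant fraction of transmitted particles is
$\theta(t) = zM/(W + zM)$; a bottleneck of $n$ founding particles draws
Binomial($n$, $\theta$), giving the co-transmission probability and the
mutant share of single-strain events
$$c = \frac{1}{\Lambda_c}\int_0^\tau
      \big(1-\theta^n-(1-\theta)^n\big)\lambda\,dt, \qquad
  b = \frac{1}{(1-c)\Lambda_c}\int_0^\tau \theta^n \lambda\,dt.$$
For a neutral co-infection ($r_m=r_w$, $z=1$, equal inocula) $\theta \equiv
1/2$ and $c = 1-(1/2)^{n-1}$ exactly — the closed form used as a correctness
oracle in the test suite.

## Numerical choices

* **Integration.** `deSolve::ode(method = "lsodar")` — stiff-capable, with
  root-finding event location. Tolerances `rtol = 1e-8`, `atol = 1e-10`:
  thresholds span more than eight orders of magnitude, so event times must
  be located on a trajectory that is accurate in the large-density regime.
* **Auxiliary states.** $\Lambda(t)$ and the $b$/$c$ integrands for every
  requested $n$ are integrated alongside $(W, M, I)$, so all integrals stop
  exactly at the located event time with no post-hoc interpolation error.
  The dense trajectory returned for plotting is a second pass over
  $[0, \tau]$; the reported outcome never depends on it.
* **Termination events.** The inoculum may start at the clearance threshold
  $\Omega$, which would fire a naive $W+M \le \Omega$ event at $t = 0$. The
  clearance event is therefore *armed* only once total density first exceeds
  $10\,\Omega$ (phase A watches for that crossing and for pathology); an
  infection that only ever decays — e.g. $r_w = 0$ — never arms, and is
  instead detected as cleared when its density halves below
  $\min(\Omega, w_0+m_0)$. Runs reaching `t_max` (default $10^4$; slow-growth
  mutants with $r_m \to 0$ can linger for thousands of time units) are
  flagged `horizon` with a warning rather than silently truncated.
* **Clamping.** $\lambda = \max(0, \log_{10}(\cdot))$: the printed
  transmission function is negative below one density unit, and negative
  transmission is meaningless. Densities near $\Omega$ contribute
  essentially nothing to $\Lambda$ either way.
* **$\delta_M$ is fixed per infection** ($\delta_M = 1$ iff $m_0 > 0$): ODE
  densities never reach exactly zero, so a state-dependent indicator would
  be ill-defined.
* **$\theta$ is the mutant probability.** The formula $zM/(W+zM)$ defines
  the probability that a transmitted particle is the *mutant*; $b$ and the
  binomial bottleneck draw use it in that sense throughout.

## Initial conditions and the inoculum convention

Inoculum sizes are genuinely free parameters of the model; the package
defaults are $i_0 = 1$ (so immune growth $sI$ can act from the start) and a
total pathogen inoculum of one unit — the clearance-threshold scale.
In `scan_phenotype()` and the emergence pipeline, all three infection types
start from the *same total* inoculum $T_0 = w_0 + m_0$: $(T_0, 0)$ for
wild-type-only, $(0, T_0)$ for mutant-only, and an equal split
$(T_0/2, T_0/2)$ for co-infections. Splitting, rather than doubling, keeps
comparisons of $\Lambda$ across infection types free of inoculum-size
effects; with a doubled co-infection inoculum, an infectivity mutant
($x > 0$) would show $\Lambda_c \ne \Lambda_m$ purely because the
co-infection starts further up its growth curve, not because of any strain
interaction. With the equal split, $\Lambda_c = \Lambda_m$ holds to
integrator accuracy for that phenotype, as it should. The equal split also
makes the neutral co-infection exactly symmetric ($\theta \equiv 1/2$),
which the closed form for $c$ requires. `simulate_infection()` itself
imposes no convention: it integrates whatever $w_0, m_0$ it is given.

## Phenotype scenarios

Five one-parameter mutant phenotypes are built in
(`phenotype_scenarios()`), each scanned over a range with a
scenario-specific lethal threshold: increased growth ($r_m \in [1,2]$,
$\Phi = 10^{12}$), decreased growth ($r_m \in [0,1]$, $\Phi = 10^6$),
decreased virulence ($v \in [0,1]$, $\Phi = 10^7$), increased
transmissibility ($z \in [1,4]$, $\Phi = 10^8$) and increased host
infectivity ($x \in [0,4]$, $\Phi = 10^8$). The default grid is 50 evenly
spaced points — fine enough to resolve the non-monotone shapes produced by
lethal overshoot (a fast-growing mutant that crosses $\Phi$ loses
transmission time). Grid points where the mutant is exactly neutral give
$\Lambda_m = \Lambda_w$ and $d$ is reported as `NA` rather than $0/0$; such
rows are retained to preserve grid alignment.

Dominance in the increased-growth scenario approaches 1 only once the
mutant's advantage is substantial (for $r_m$ well above $r_w$ and below
lethal overshoot, $d > 0.99$); just above neutrality the wild-type persists
long enough to hold $d$ near 0.65. The package's dominance-ordering checks
therefore evaluate "essentially complete dominance" on the sub-lethal upper
half of the range ($r_m \ge 1.5$, mutant-only run immune-cleared), and
"near-total recessivity" of the decreased-growth mutant as $d < 0.1$ over
the majority of its grid.

# The between-host layer

## Branching process and PGFs

Infections are of three types — wild-type, mutant, co-infection — with
offspring generated per discrete generation. A wild-type infection mutates
with probability $\mu_1$, in which case it is *re-classified* as a
co-infection before reproducing; otherwise it leaves Poisson($R_w$)
wild-type progeny. Mutant infections revert with probability $\mu_2$,
symmetrically. A co-infection leaves Poisson progeny of all three types with
means $R_{cc} = cR_c$, $R_{cm} = (1-c)bR_c$, $R_{cw} = (1-c)(1-b)R_c$,
where $R_c = \max(0,\, dR_m + (1-d)R_w)$ (clamped: a negative Poisson mean
is undefined, which can otherwise arise under strong underdominance). When
$c = 1$ every transmission is a co-transmission and $b$ is irrelevant (both
single-strain means are zero).

The re-classification reading gives the generating functions
$$f_C(s) = e^{R_{cw}(s_W-1) + R_{cm}(s_M-1) + R_{cc}(s_C-1)},$$
$$f_W(s) = (1-\mu_1)\,e^{R_w(s_W-1)} + \mu_1 f_C(s), \qquad
  f_M(s) = (1-\mu_2)\,e^{R_m(s_M-1)} + \mu_2 f_C(s),$$
and the extinction probabilities $(q_W, q_M, q_C)$ are the minimal fixed
point of $q = f(q)$ in $[0,1]^3$; $P(\text{emergence}) = 1 - q$, evaluated
by default from a single wild-type infection.

## Solving the fixed point

Functional iteration from $q = 0$ converges monotonically to the minimal
fixed point, but only at rate $O(1/n)$ when a type is exactly critical, and
near a critical point $q - f(q)$ has a double root, so *any* root-based
stopping rule stalls at $\sqrt{\varepsilon_{\text{mach}}} \approx 10^{-8}$
from the truth. The solver therefore combines three ingredients:

1. **Certainty detection.** Extinction from type $i$ is certain iff the
   spectral radius of the mean offspring matrix restricted to the types
   reachable from $i$ is $\le 1$ (classical multi-type branching theory;
   the Poisson offspring law always puts mass at zero, so critical classes
   die out too). Those components are pinned at exactly $q_i = 1$ before
   solving, which settles critical cases ($R_w = 1$, $\mu_1 = 0$ gives
   emergence exactly 0) and removes their slow modes from the iteration.
2. **Monotone burn-in.** Up to 1000 functional iterations from zero
   (tolerance $10^{-12}$ on the sup-norm change).
3. **Newton polish.** If the residual is still above tolerance, Newton on
   $g(q) = q - f(q)$ with a numerical Jacobian, stopping on *step size*
   rather than residual for the double-root reason above, with a fallback
   to long plain iteration if a step fails to improve.

`simulate_chains()` is an independent Monte-Carlo check: vectorized
generation-by-generation simulation (binomial mutation splits, Poisson
offspring sums) across all chains at once. A chain is *emerged* when its
population reaches 1000 concurrent infections — a supercritical chain that
gets that far escapes extinction with overwhelming probability — *extinct*
at zero, and *censored* at 200 generations. Censored chains are counted as
emerged and the censoring fraction is reported, bounding the (upward) bias;
in practice censoring is rare because chains either die early or grow
geometrically.

# Sensitivity analysis

`lhs_sample()` stratifies each parameter range into $N$ equal-width
intervals with one uniform draw per interval and independent pairing across
parameters (via `lhs::randomLHS`). Default ranges: $R_w \in [0,1]$ (the
wild-type is maladapted; only an upper bound is inherent, and $R_0 \ge 0$ by
definition), $R_m \in [1,4]$, $d \in [0,1]$ or $[-0.5, 1.5]$ when
underdominance and overdominance are of interest, and $c, b, \mu_1, \mu_2
\in [0,1]$.

`prcc()` is the classic partial rank correlation: all columns are
rank-transformed (average ranks on ties), each parameter's ranks and the
response's ranks are regressed on the ranks of all *other* parameters, and
the PRCC is the correlation of the two residual vectors. It is invariant
under strictly monotone transforms of any column, which the tests exercise
directly. Confidence intervals are percentile bootstrap over design rows
(default $B = 500$, level 95%) — replicates and level are fixed by
convention; the percentile method is the simplest interval consistent with
them. The canonical analyses use $N = 500$ design points; at that size the
PRCC of dominance on emergence is ~0.84 with a bootstrap CI far from zero,
and the sign pattern across the remaining six parameters reverses between
pinned $d = 0$ and $d = 1$ exactly as the single-parameter slices lead one
to expect.

# Linking the layers

`phenotype_emergence()` feeds the within-host summaries into the branching
process: for each phenotype value, $R_m = R_w \Lambda_m/\Lambda_w$ (total
transmission is proportional to $R_0$), $d$ from the scan, and $(b, c)$ for
each bottleneck size, with $R_w = 0.9$ and $\mu_1 = \mu_2 = 0.01$ as the
canonical between-host setting. Every row asserts the internal identity
$dR_m + (1-d)R_w = R_w \Lambda_c/\Lambda_w$ (both sides follow from the
definition of $d$) to relative $10^{-6}$ — a guard against inconsistent
plumbing between the layers. Neutral grid points propagate as missing
emergence rather than being dropped.

Two robust findings from this pipeline: the increased-replication mutant
attains the highest emergence probability of the five phenotypes (it is
dominant *and* has the largest $R_m$), and the strongly
virulence-attenuated mutant — although recessive — comes next, with a
pronounced bottleneck effect: its emergence at $n = 1$ exceeds that at
$n = 10$ several-fold, because a recessive mutant only realizes its
advantage once separated from the wild-type, and tight bottlenecks do the
separating.

# Problem sizes and runtimes

The test suite and the acceptance script use: dense trajectories of 1001 to
2001 points for quadrature cross-checks; 50-point scan grids (21 points for
the five-scenario emergence pipeline, which multiplies grid × scenario ×
bottleneck); $N = 500$, $B = 500$ for the canonical PRCC runs; and 20,000
Monte-Carlo chains per analytic-vs-simulation comparison (binomial standard
error ~0.3 percentage points at $p \approx 0.1$). These sizes resolve every
qualitative contrast the framework makes with comfortable margins.

# What the model does and does not capture

The within-host layer is deliberately minimal: exponential growth, a single
strain-transcending immune compartment, deterministic dynamics, and
threshold-triggered endpoints. It emulates the *shapes* that matter for
dominance — competition through shared immunity, lethal overshoot,
duration/intensity trade-offs — but not antigenic differences between
strains, within-host stochasticity at low copy number, explicit immune
memory, or dose-dependent infectivity. Conclusions about specific pathogens
require re-deriving $(d, b, c, R_m/R_w)$ from a system-appropriate
within-host model; the branching-process layer consumes those four
quantities and is agnostic to their origin. The branching process itself
assumes an unstructured, effectively infinite susceptible population with
independent transmission chains — appropriate at the start of an outbreak,
not near herd-immunity thresholds or in small host populations.
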