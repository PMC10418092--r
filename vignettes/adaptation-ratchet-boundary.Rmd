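---
title: "The boundary between adaptation and Muller's ratchet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The boundary between adaptation and Muller's ratchet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratchetwave)
```

## The scientific question

In a large asexual population, many beneficial and deleterious mutations
segregate simultaneously on linked backgrounds. Clonal interference and
hitchhiking then make selection inefficient: deleterious mutations can fix
and beneficial ones can be wasted. Given a population size $N$, a total
mutation rate $U$, and a distribution of fitness effects (DFE) $\rho(s)$,
will mean fitness rise or fall? `ratchetwave` implements a quantitative
answer: the surface in parameter space on which the rate of change of mean
fitness is exactly zero ($v = 0$), where adaptation and Muller's ratchet
balance, together with two companion surfaces on which molecular evolution
merely *looks* neutral ($F = U$, where selected mutations fix at the
neutral rate, and $\alpha = 0$, where a McDonald–Kreitman-like contrast
vanishes).

## Model and core formulas

The population is haploid, non-recombining, of constant size $N$. Each
generation every individual gains $\mathrm{Poisson}(U)$ selected mutations
with effects drawn from $\rho(s)$ (and $\mathrm{Poisson}(U_n)$ neutral
ones); a mutation of effect $s$ adds $s$ to log-fitness $X$; offspring are
multinomial with weights $\propto e^{X}$.

In the rapidly evolving (moderate selection, strong mutation) regime, the
fixation probability of a new mutation is
$$p_\mathrm{fix}(s) \approx \frac{e^{T_c s}}{N},$$
for beneficial and deleterious effects alike, where $T_c \approx T_2/2$ is
half the mean pairwise coalescent time. Writing $v = NU\int \rho(s)\, s\,
p_\mathrm{fix}(s)\, ds$ and scaling effects as $\gamma = T_c s$, the $v=0$
condition becomes a property of the *scaled* DFE alone:
$$\int \tilde\rho(\gamma)\, \gamma e^{\gamma}\, d\gamma = 0 .$$

For a two-effect DFE (all beneficial effects $\gamma_b$, all deleterious
$-\gamma_d$, rate ratio $\eta = U_b/U_d$) this gives the closed form
$\eta|_{v=0} = \gamma_d e^{-\gamma_d} / (\gamma_b e^{\gamma_b})$, and for
exponentially distributed effect magnitudes
$\eta|_{v=0} = (\gamma_d/\gamma_b)\,\big((1-\gamma_b)/(1+\gamma_d)\big)^2$,
valid for $\gamma_b < 1$ (the adaptation integral diverges at mean scaled
effect 1 — a boundary the package localises numerically as well, as an
internal consistency check). Both surfaces have a **ridgeline** at
$\gamma_d^\ast = 1$: deleterious mutations are maximally impactful at
intermediate scaled effects, because weaker ones fix but cost little and
stronger ones are purged. Along it $\gamma_b^\ast = W(1/(e\eta))$
(two-effect; $W$ is the Lambert function), or
$\gamma_b^\ast = 1 + 2\eta - 2\sqrt{\eta^2+\eta}$ (exponential). Above
$\gamma_b^\ast$ a population adapts for *every* $\gamma_d$.

The exponential-family ridgeline coordinate is easy to mis-typeset; the
expression used here was derived directly from the surface condition and
is verified in the test suite against numerical maximisation of the
quadrature integral.

The companion surfaces use the kernels $e^\gamma - 1$ (for $F = U$, with
$F = U \int \tilde\rho\, e^{\gamma} d\gamma$ the total selected fixation
rate) and $e^\gamma - (e^{\gamma}-1)/\gamma$ (for $\alpha = 0$, with
$\alpha = 1 - U_n \pi_\mathrm{sel} / (F \pi_\mathrm{neu})$). The latter
kernel follows from the fixation-rate and sojourn/polymorphism integrals:
$(U/U_n)\,\pi_\mathrm{sel}/\pi_\mathrm{neu} = \int \tilde\rho\,
(e^\gamma - 1)/\gamma\, d\gamma$. It reproduces the strict ordering
$\eta|_{v=0} < \eta|_{\alpha=0} < \eta|_{F=U}$ for every two-component
DFE — so on the $v=0$ surface $\alpha < 0$ and $F < U$, and all three
surfaces merge onto $\eta = \gamma_d/\gamma_b$ in the neutral limit. The
test suite asserts the ordering on randomized sweeps.

## Fixing the coalescence timescale

$T_c$ is not a free parameter: it is pinned by $(N, U, \rho)$ through an
implicit traveling-wave relation,
$$\log(N x_c) = T_c (x_c - U) - \tfrac{1}{2} v T_c^2 +
U\!\int\! \rho(s)\,\frac{e^{T_c s}-1}{s}\, ds,$$
with the fitness-lead scale
$x_c = U\!\int\!\rho(s)[T_c s e^{T_c s} + 1 - e^{T_c s}]ds - b z_0 - 1/T_c$
and $b^3 = (U/2)\!\int\!\rho(s) s^2 e^{T_c s} ds$, where $z_0 \approx
-2.338$ is the least negative zero of $\mathrm{Ai}(z)$ — computed at first
use by root-finding a Bessel-function representation of the Airy function,
never hard-coded. We read the $b^3$ prefactor as $U/2$ on dimensional
grounds ($b$ must be a fitness rate). `solve_Tc()` scans $g(T_c)$ on a log
grid, bisects every sign change, and returns the root with the best
validity margin (preferring the neutral-end branch, $T_c \sim N$, when two
roots coexist close to neutrality); all roots are reported. Validity
diagnostics ($T_c b$, $T_c U_b$, typical fixed effects against the wave
width) are attached and produce warnings — never silent failures — when
$T_c U_b < 1$ or $T_c b < 2$; the thresholds are package constants chosen
because theory only demands "much greater than one".

For strongly deleterious effects the traveling-wave relation loses
accuracy (indeed, as implemented it does *not* reduce to the classic
background-selection limit), and a separate heuristic takes over:
$T_c = N \exp\left(-U_d \int \rho_d(s)\, \frac{1-e^{-T_c s}}{s}\,
ds\right)$, solved by damped fixed-point iteration; with a single strong
effect it reduces to $N e^{-U_d/s_d}$ (verified to 1% in the acceptance
suite). Unscaled $v=0$ curves in the $(N s_d, N s_b)$ plane therefore use
the traveling-wave branch up to the curve's maximal $N s_d$ — the
extremal point $(N s_d^\ast, N s_b^\ast)$ — and beyond it the patched
prediction $N s_b = \min(N s_b^\ast, (N s_b)_{NE})$, with the heuristic
$T_c$ combined with the single-locus diffusion fixation probability. The
$F=U$ curve keeps the traveling-wave branch throughout (strong purifying
selection never dominates there), and the $\alpha=0$ curve mirrors the
$v=0$ patching but switches at its own turning point — the exact
crossover rule for $\alpha = 0$ is a package decision, validated only
qualitatively. Points the solvers cannot resolve are emitted as `NA`
rows, never interpolated.

Two caveats discovered and documented during development: first, with
the implicit relation in the form implemented here (less-approximated
variants of the traveling-wave relation exist in the literature but are
not implemented), the unscaled extremal point lands at
$\gamma_d \approx 4\text{–}5$ rather than coinciding with the mapped
ridgeline at $\gamma_d^\ast = 1$; `star_vs_ridge_coincidence()` reports
and flags the offsets rather than asserting coincidence. Second, on the
curves themselves each emitted point is re-checked through its *own*
branch's condition (scaled residual for the traveling-wave branch,
normalised diffusion-$v$ for the heuristic branch); points clamped by the
$\min(\cdot)$ patch satisfy neither and carry `NA` residuals by design.

## The simulator and its estimators

The individual-based simulator (C++ core) tracks every mutation's
identity, effect, origin generation and fate. Heterozygosity is computed
exactly from carrier counts, $\pi = \sum_i 2 c_i (N - c_i) / (N(N-1))$,
which *is* the all-pairs average of pairwise differences for any $N$ — no
pair subsampling is needed at any size. Fixed mutations are compacted out
of genotypes into a ledger to bound memory. Runs follow the epoch
protocol: from a clonal start, the time to the first fixation sets the
epoch length; up to 100 epochs are run with mean fitness, $\pi_{neu}$,
$\pi_{sel}$ and fixation counts recorded at each epoch boundary. A run
whose first fixation exceeds a configurable generation cap is flagged,
not discarded. Estimators: $\hat v$ is the least-squares slope of mean
fitness over generations at epoch resolution; $\hat F$ counts selected
fixations per generation; $\hat T_c = \pi_{neu}/(4 U_n)$ averaged over the
second half of the epochs (the first half is discarded as the
equilibration from the clonal start — the transient lasts of order $N$
generations). The neutral mutation rate defaults to $U_n = 0.01$
(configurable); simulation-validation runs here use $U_n = 0.05$ so that
heterozygosity-based estimates accumulate quickly at small $N$.

What the synthetic runs emulate — and what they do not: the simulator
realises exactly the model the theory assumes (constant $N$, free
recombination absent, infinite sites, a fixed or fitness-indexed DFE). It
does not emulate demographic change, recombination, finite genomes with
back-mutation, or environmental fluctuation, so passing tests validate
the theory's internal consistency and its desk-scale predictive power,
not its adequacy for any particular natural population.

## Fitness-mediated epistasis

`epistasis_rule()` describes how effect magnitudes depend on an
individual's own log-fitness: diminishing returns
($s_b \propto e^{-X/L}$), increasing costs ($s_d \propto e^{+X/L}$),
decreasing costs, or both at once with $s_b s_d$ exactly conserved. The
length scale defaults to $L = 5$. In the individual-based version the
*next available* mutation's magnitude is updated after each mutation
event, per individual — population-mean fitness plays no role. The
`custom` pattern (arbitrary R callbacks) is available to
`effect_update()` and `theory_flow()` but not to the C++ simulator.

`theory_flow()` integrates $dX/dt = v(N, U, \rho(\cdot|X))$ under the
slow-epistasis assumption with adaptive explicit Euler: steps are capped
so per-step changes in the effect scales stay below 1%, and a step that
would cross $v = 0$ is halved rather than allowed to overshoot.
Termination declares a fixed point when $|v|$ falls below a tolerance
(default $10^{-3}$ of the initial $|v|$). `classify_fixed_points()`
intersects an epistatic constraint line with a $v=0$ curve and derives
stability from the sign of $v$ on either side plus the pattern's
direction of motion: diminishing returns always yields one stable point;
increasing costs below $N s_b^\ast$ yields a stable/unstable pair (none
above it); decreasing costs swaps the pair's stabilities. Because the
Euler flow approaches fixed points asymptotically, flow/intersection
agreement is asserted at percent-level tolerance, not machine precision.

## Numerical choices

* Kernels with removable singularities at $s=0$ use series branches below
  $|T_c s| < 10^{-6}$; tilted densities are assembled in log space and
  integrated in units of the tilted mean so that mutation-scale
  ($10^{-4}$-ish) mass is never lost; gamma shapes below 1 are integrated
  after a $t = u^2$ substitution removing the origin singularity.
* Closed forms exist for point-mass and exponential families; gamma and
  tabulated DFEs go through quadrature/direct summation. Every closed
  form is cross-checked against forced quadrature in the tests at
  $10^{-8}$ relative tolerance.
* Root solves in $\eta$ use bracketed bisection on $\log \eta$ over
  $[10^{-12}, 10^{3}]$ — the residual is monotone in $\eta$ by mixture
  linearity, so the bracket is safe.
* Ridgeline maximisation does a coarse log-scan, golden-section search,
  then polishes by root-finding the central-difference gradient with a
  shrinking step — the maximum is quadratically flat, so direct search
  alone cannot reach $10^{-6}$ in the argmax under quadrature noise.
* The divergence boundary of the exponential beneficial integral is
  classified from the integrand's tail exponent ($1 - 1/\gamma_b$) and
  bisected; the integral itself raises a typed divergence error
  (`ratchetwave_divergence`) at or beyond the boundary.

## Problem sizes used in validation

The validation suite runs at desk scale, chosen so the full battery
completes in minutes while every qualitative claim is still resolvable:
neutral-oracle runs at $N \in \{100, 500\}$ with $U_n = 0.05$ (over
$2\times10^4$ tracked mutant fates pooled across runs); a $5\times5$
$(N s_b, N s_d)$ sign-agreement grid at $NU = 10^2$, $\eta = 0.1$,
$N = 10^3$ with three replicate seeds per cell and a 2500-generation
budget per run; epistasis runs of 5000 generations recorded every 100 at
$N = 10^3$, $NU = 10^2$, $\eta = 0.1$, $s_{b0} s_{d0} = 2\times10^{-5}$.
Theory-curve comparisons use $NU \in \{10^2, 3\times10^2\}$. At these
mutation supplies the traveling-wave validity margin $T_c U_b$ sits at
1–5, so simulated boundaries are expected to track predictions in sign
and location but not to fine quantitative accuracy; agreement tightens
as $NU$ grows and the interference margins strengthen.

## Known limitations

* The implicit $T_c$ relation is implemented in its printed main-text
  form; its documented accuracy loss at strong purifying selection is
  inherited (and patched by the heuristic branch exactly as described
  above).
* Gamma-family surface theory is numerical only; no closed forms.
* The simulator supports neither recombination nor diploidy nor
  time-varying $N$; tree sequences are not recorded.
* Second-order selection on lineages carrying modified DFEs (an epistasis
  rule makes all individuals' DFEs shift identically with their own
  fitness) is outside the model.
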