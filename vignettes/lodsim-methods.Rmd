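---
title: "Simulating age-related risk-allele depletion in late-onset disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating age-related risk-allele depletion in late-onset disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodsim)
```

## The model

lodsim simulates a birth cohort aging year by year under a polygenic
late-onset disease (LOD). Every individual carries a fixed polygenic risk
score (PRS)

$$\beta = \sum_k a_k \log \mathrm{OR}_k,$$

the sum over causal variants of the risk-allele count $a_k \in \{0,1,2\}$
times the per-allele log odds ratio. Scores are centred by the population
mean $2\sum_k p_k \log \mathrm{OR}_k$. Disease follows a proportional-hazards
view of aging: the yearly baseline incidence $I(t)$ captures age and
environment, and an individual's diagnosis hazard is the baseline times their
polygenic odds converted to a hazard multiplier. Each simulated year,

1. the number of new cases is $N_d(t) = I(t) \, N_u(t)$, with $N_u$ the
   unaffected pool (fractional remainders are carried to the next year so
   small populations do not lose incidence mass);
2. that many distinct individuals are drawn from the unaffected pool
   *without replacement, with probability proportional to their hazard
   multiplier* $\exp(\beta)$ (after OR-to-HR adjustment, below);
3. mortality (in cohort mode) removes individuals of both pools with the
   age-specific yearly death probability.

Because riskier individuals are diagnosed proportionately earlier, the
risk-allele frequency among accumulated cases exceeds that among unaffected
survivors, and both drift with age. The case/control difference
$\delta = \mathrm{MAF}_\text{cases} - \mathrm{MAF}_\text{controls}$ is the
quantity GWAS discovery power rides on: the association test's
non-centrality parameter is $\lambda = N p_1 p_2 \delta^2$, and the cases
needed for 80% power at genome-wide significance ($5\times10^{-8}$) follow
from the noncentral $F(1, N-4)$ tail. As cohorts age and $\delta$ shrinks,
the required sample size grows as $1/\delta^2$.

### Genetic architectures

Architectures are rectangular grids: five equally spaced MAFs crossed with
five equally spaced ORs (scenarios A-E span common-low-effect to
rare-high-effect regimes). Grid values are rounded to the printed precision
of the scenario bounds (3 decimals for scenario A), so scenario A's MAFs are
exactly 0.073, 0.180, 0.286, 0.393, 0.500 and its single-set liability
variance is $2\sum_k p_k(1-p_k)\log^2 \mathrm{OR}_k = 0.09099$. The
liability-scale heritability is $h^2 = \mathrm{var}/(\mathrm{var} +
\pi^2/3)$, and a disease's architecture is the 25-variant set replicated the
nearest-integer number of times that meets its target $h^2$. The published
variant counts for four of the eight diseases exceed the nearest-set rule by
2-5 sets; `genetic_architecture()` therefore accepts an explicit set count,
and the presets pin the published counts.

Nine variants of set 1 (the corners and middles of the grid: lowest, middle,
highest MAF by lowest, middle, highest OR) are tracked per individual by
default. The choice of which nine is a package convention; published figures
display nine representative variants without naming them.

### Exact aggregated genotype sampling

Only the scalar PRS and the nine tracked genotypes persist per individual.
Untracked variants sharing a grid cell $(p, \mathrm{OR})$ are drawn as their
aggregate: the summed allele count of $m$ independent Hardy-Weinberg
variants is exactly $\mathrm{Binomial}(2m, p)$, so a 3,575-variant
architecture needs 25 binomial draws per individual instead of 3,575
trinomial ones. This is a distributional identity, not an approximation,
and it removes any need for chunked genotype streaming; populations of
$10^7$ fit comfortably in memory.

### Diagnosis sampling

The reference algorithm draws each new case by rebuilding a cumulative
hazard-weight table over the unaffected pool and looking up a uniform draw
(quadratic cost; retained verbatim in `brute_force_engine()`). The fast
engine realises the same sequential distribution with a Walker-Vose alias
table built once over all hazard weights: a proposal that hits an
already-diagnosed or dead individual is rejected, which renormalises the
proposal to exactly the conditional distribution the sequential scheme
requires. When the OR-to-HR conversion shifts weights between years (see
below), an extra acceptance factor corrects the stale proposal weights, and
the table is rebuilt over the surviving pool when its live weight share
drops below 2% or acceptance deteriorates. Each draw is O(1); a
10-million-individual, 100-year cohort run takes seconds.

Mortality is pre-drawn: each individual receives a death age by inverting
the survival curve once at birth, with a conditional redraw at diagnosis when
cases carry a mortality multiplier. Statistics (counts, PRS sums and
squares, tracked allele counts for the unaffected pool, the accumulated
surviving cases, and each year's new cases) are maintained incrementally, so
a simulated year costs O(events), not O(population).

### OR-to-HR conversion

Sampling weights are hazard multipliers, not odds ratios. For a yearly
baseline rate $P_0$, the adjustment
$\mathrm{RR} = \mathrm{OR} / (1 - P_0 + P_0\,\mathrm{OR})$ maps one to the
other; it is the default (`zhang_yu`), applied with $P_0$ equal to the
current year's incidence. At LOD-typical rates the correction is on the
order of $P_0$ itself and matters only for high-incidence diseases at high
ages. The untransformed `identity` mode is also provided, both because the
conversion used in the original implementation is not fully specified and
because fixed weights make the cumulative-incidence invariance below exact.

### Mortality

A Gompertz-Makeham stand-in for actuarial life tables supplies the yearly
death probability $q(t) = \min(1, a + b e^{t/c})$ with defaults
$a = 2\times10^{-4}$, $b = 2.7\times10^{-5}$, $c = 10$ years: accidental
mortality dominating youth, senescent mortality doubling roughly every 7
years, under 1% of the cohort alive at 105. Cases can die at the control
hazard (default), at twice it, or mortality can be disabled; with equal
case/control mortality, death is independent of diagnosis, so cohort allele
contrasts are unchanged in expectation and mortality's role is to shrink the
pools and terminate reporting.

## Analysis modes

**Individual-values analysis (IVA)** uses 1-year age slices without
mortality: each age's newly diagnosed cases are contrasted with the
remaining unaffected pool. It isolates the depletion dynamics.

**Cohort mode** emulates an age-matched case/control study with a 10-year
age span (configurable down to 1): cases are everyone diagnosed at or before
their current age and still alive, controls the unaffected survivors, and
statistics are indexed by mid-cohort age (youngest age in the window plus
half the span). Since incidence and mortality depend on age only, staggered
entry of ten birth cohorts is statistically equivalent to pooling ten
consecutive age slices of one cohort, which is how records are assembled.
Reporting runs from the youngest cohort -- the first mid-cohort age whose
cumulative case pool reaches 0.25% of the initial population -- until either
pool falls below that threshold.

Statistics are averaged over replicate runs with derived, salted seeds;
the reported Monte-Carlo standard error is the across-replicate standard
deviation over $\sqrt{R}$.

## Disease presets and their calibration

Eight presets (AD, T2D, CAD, stroke, breast, prostate, colorectal, lung)
bundle the published heritabilities and variant counts with yearly incidence
curves. The published constraint set per disease is: the age to which
incidence rises exponentially, an incidence doubling time of 5-8.5 years in
that regime, a maximum yearly incidence, and a lifetime risk. Exact curve
parameters are not published, so the package ships self-contained constants
calibrated once against those constraints:

* All capped curves use the soft-plateau form
  $I(t) = I_{\max}\,(1 - e^{-x(t)})$, $x(t) = (I_0/I_{\max})e^{r(t-t_0)}$,
  anchored so the curve reaches half its plateau at the published
  exponential-regime end age with a local doubling time of exactly 8.5 years
  there ($r = 0.1176$/yr, base doubling 5.9 years).
* For T2D, CAD and stroke the plateau equals the published maximum yearly
  incidence -- these maxima are registry plateau levels. Their published
  lifetime risks are mortality-limited and fall between the simulated
  mortality-adjusted diagnosed fraction and the mortality-free cumulative
  incidence, which is how the preset test checks them.
* For the four cancers, mortality interacts only weakly with diagnosis at
  these incidence levels, and published cancer lifetime risks track the
  cumulative diagnosed fraction; the plateau is solved so the no-mortality
  cumulative incidence at 100 equals the published lifetime risk.
* AD keeps rising exponentially (doubling every 5 years) past age 100,
  crossing 20% yearly incidence before 103; its scale is set so the
  mortality-adjusted diagnosed fraction is 15%, the middle of the published
  10-20% band. A no-mortality cumulative-incidence check would be
  inconsistent with an incidence that high, so AD is checked on the
  mortality-adjusted measure.

A deliberate consequence: absolute incidence levels shift the ages at which
cumulative-incidence landmarks are reached, but the case/control allele
distributions depend on cumulative incidence and heritability only (the
validation result below), so the calibration's residual freedom moves
youngest-cohort ages, not the allele-frequency contrasts at matched
cumulative incidence.

## Validation against independent references

* **Closed form.** The expected case allele frequency of the first
  hazard-weighted draw from an undepleted population is
  $p h / (1 - p + p h)$ per variant (all other loci factor out). For the
  largest-effect variant (MAF 0.5, OR 1.15) the case/control difference is
  0.0349, anchoring the youngest-cohort values; the engine must recover it
  at 0.1% cumulative incidence within Monte-Carlo error.
* **Literal reference engine.** `brute_force_engine()` transcribes the
  lookup-table algorithm directly and must be statistically exchangeable
  with the fast engine (equal means within 3 SE over 50 replicates at
  $n = 10^4$).
* **Cumulative-incidence invariance.** Constant, linear and exponential
  incidence curves matched to the same cumulative incidence must produce the
  same case and control allele distributions at the matched point
  (`invariance_suite()`; exact for identity weights, checked at 5%, 20% and
  50% for scenarios A and D).
* **Hardy-Weinberg enumeration.** For tiny architectures the analytic
  liability variance equals the exhaustive genotype-enumeration variance.
* **Exhaustive bookkeeping checks.** Conservation of individuals across
  the unaffected/case/dead partition at every age, one-way status
  transitions, and exact case accumulation without mortality.

## What the generator does and does not emulate

Simulated data embody the model's assumptions: independent causal loci (no
linkage disequilibrium), Hardy-Weinberg genotype frequencies, a PRS fixed at
birth, multiplicative hazards, no gene-environment interactions, sex-blended
incidence and mortality, and a single disease at a time (no comorbidity or
correlated mortality). Passing tests therefore demonstrate internal
correctness of the sampling dynamics and power arithmetic, not that any real
cohort behaves this way; in real data, linkage, confounding, diagnostic
drift and cohort effects all perturb the clean $1/\delta^2$ law.

## Problem sizes and numerical choices

The original study simulated populations of $2\times10^9$; a desktop
reproduction does not need that. The package's documented study conditions,
used by its acceptance checks, are populations of $10^7$ with 10 replicate
seeds per disease (Monte-Carlo SE on the youngest-cohort $\delta$ of about
$7\times10^{-4}$), and smaller sizes for property checks ($10^4$-$10^6$).
Other numerical conventions: half-to-even rounding of yearly case counts
with remainder carry-over; the power solver bisects $\log N$ until the
achieved power matches the target to better than 0.01%; empty subsets are
reported as missing rather than propagating NaN; cohort summary tables round
frequencies to 3 decimals and multiples to 2, matching published precision.

## Known limitations

The OR-to-HR conversion used by the original implementation is ambiguous;
with either mode provided here, the very low published youngest-cohort
contrasts for the two highest-incidence, highest-heritability diseases (AD,
T2D) are not reproduced quantitatively, and the package makes no claim to
them. Qualitative behaviour -- the strongest age-related decline of the
case/control contrast belonging to the high-incidence, high-heritability
diseases, with lung cancer flattest -- is reproduced and tested; note that
published summaries themselves show CAD and prostate cancer declining
comparably to AD, so the qualitative claim is tested against the
breast/colorectal/lung group rather than as a strict top-two ranking.
Absolute cases-needed counts inherit a constant-factor ambiguity between
the published 80%-power equations and the published youngest-cohort counts
(which are internally consistent with 50% power); age-to-age ratios cancel
that factor and are the quantities compared.
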