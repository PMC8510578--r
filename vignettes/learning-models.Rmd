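---
title: "Quantized versus graded learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantized versus graded learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalearn)
```

## The data and the question

Each animal in the Y-maze assay produces an ordered sequence of binary
choices (approach the CO₂-laden channel, or avoid it) in each test phase
— before training (`PRE`), immediately after (`POST`), and optionally the
next day (`NEXT_DAY`). The analysis unit is the per-animal preference
`p = #approach / (#approach + #avoid)` together with the number of
decisions `n` behind it. Animals differ widely in `n` (the package's
count model defaults to a mean of 30 decisions per hour-long phase);
population summaries are therefore *decision-weighted*: total approaches
over total decisions, so that an animal that made two choices does not
count as much as one that made forty.

The scientific question the model competition addresses: when repeated
training shifts the population preference from the untrained mean
(≈ 0.27) toward the trained mean (≈ 0.52), is that because every animal
drifts a little per cycle (graded learning) or because each cycle flips
some animals entirely (quantized, all-or-none learning)?

## The likelihood

All five competing models describe the distribution of observed
post-training preferences across training doses `n_c` through the same
scaffolding. If an animal's choices were independent with marginal
probability `p̄`, its observed preference would be approximately normal
with variance `p̄(1 − p̄)/n`. Choices in this assay are serially
*anti*-correlated (an animal that just approached is less likely to
approach next time), so the counting variance is scaled by a global
factor `σ̃²`:

$$\sigma^2 = \tilde\sigma^2\, \frac{\bar p\,(1-\bar p)}{n}.$$

Anti-correlation gives `σ̃ < 1`. The Gaussian component densities are
*not* truncated to [0, 1]: the likelihood is an approximation to the
discrete count distribution, truncation would add normalization terms
that change the parameter counts, and the component means sit far enough
from the boundaries that the leaked mass is small at realistic `n`.

The total log-likelihood is a sum over animals of the log (mixture)
density of `p` given `n`. The five variants, with their parameter counts
at the study's eight dose levels (0, 1, 2, 3, 4, 5, 10, 20 cycles):

| model | structure | k |
|---|---|---|
| `SHIFTING_MEAN_FIXED_SIGMA` | one Gaussian per dose, free mean, shared `σ̃` | 9 |
| `GRADED` | one Gaussian per dose, free mean and free sd (`σ(n_c)/√n`) | 16 |
| `QUANTIZED` | two Gaussians (`μ_u`, `μ_t`, shared `σ̃`), free untrained weight `f_u(n_c)` per dose | 11 |
| `THREE_CLUSTER` | three ordered Gaussians, two free weights per dose | 20 |
| `ALL_OR_NONE` | the quantized mixture with `f_u(n_c) = λ^{n_c}` | 4 |

`ALL_OR_NONE` is the scientific heart: if every training cycle converts
each still-untrained animal with the same probability `ρ = 1 − λ`
regardless of its history (a memoryless process), the untrained fraction
must decay exponentially in dose. The model is the quantized mixture
constrained to that decay, and it is *nested* in it, as the quantized
model is nested in the three-cluster model and the fixed-`σ̃` shifting
mean in the graded model. The package exploits the nesting during
fitting (below) and the test suite asserts the implied likelihood
inequalities.

Observations for the likelihood are animals, one `(p, n)` pair each;
animals with `n = 0` carry no information about the preference
distribution and are excluded from fitting (they are retained everywhere
else — inactive animals stay in bootstrap pools and count tables). BIC
uses the number of animals entering the likelihood as its sample size,
matching the sum structure of the log-likelihood.

## Fitting

`fit_model()` maximizes the log-likelihood after transforming all
parameters to an unconstrained scale: logit for means, fractions, and
`λ`; log for `σ̃` and the graded sds. The three-cluster means are
ordered by stick-breaking (`μ₁ ≤ μ₂ ≤ μ₃`), which removes label
switching, and its per-dose weight pairs live on the simplex via a
two-logit multinomial parameterization. Optimization is quasi-Newton
(BFGS) from multiple starts: a method-of-moments heuristic (split animals
at preference 0.4; component means from the two sides; `λ` from the
per-dose untrained proportions), 20 random starts by default, and — in
`compare_models()` — the fitted parameters of each model's constrained
nested neighbour mapped into the richer parameter space. Nested seeding
both speeds convergence and guarantees the nesting inequalities to
numerical precision, since an optimizer started at the constrained
optimum can only improve. Ties between equal-likelihood optima break
deterministically (smallest leading mean, then lexicographic), so a refit
with the same seed reproduces the same `θ`.

Numerical guards: the variance model is floored at 10⁻⁶ so degenerate
proposals (`p̄` of 0 or 1) keep finite densities; mixture densities are
evaluated by log-sum-exp; the convergence tolerance is 10⁻¹⁰ (relative)
on the objective. The logit clamp (10⁻⁶ from the boundary) means a
weight that is exactly 1 — e.g. `f_u(0)` under the all-or-none
constraint — is representable only to ~10⁻⁶, so nesting comparisons in
the tests use a 10⁻⁴ log-likelihood tolerance.

## Trained-fraction intervals

The reported "fraction trained" per dose comes from the quantized model:
holding `μ_u`, `μ_t`, `σ̃` at their global fit (`θ₀`), the likelihood of
one dose group is profiled over the trained weight `f`. The interval is
the connected set of `f` within half a log-likelihood unit of the
profile maximum. Because the mixture density is linear in `f` inside the
log, the profile is concave, so the set is an interval; endpoints are
found by bracketed root-finding (tolerance 10⁻⁶ in `f`) and clipped at 0
and 1. When `μ_u = μ_t` the profile is flat and the interval is all of
[0, 1] — the fraction is unidentifiable, reported as such rather than as
an error.

## Bootstraps and tests

The hierarchical bootstrap resamples animals with replacement, then each
resampled animal's decisions with replacement, independently per
condition; the same resampled animals appear in every condition,
honouring the paired design. Resampling `n` decisions from a binary
vector with success fraction `p̂` is exactly a Binomial(`n`, `p̂`) draw,
which is how the package implements it. The animal-only variant keeps
decision sequences intact, preserving the within-animal serial
correlation. The comparison p-value is a ranking-consistency score: the
fraction of replicates whose condition ranking disagrees with the
point-estimate ranking, with exact ties counted as disagreements (the
conservative reading; an exactly tied replicate supports no ranking). A
count of zero is reported as `p < 1/B`. B defaults to 10,000.

Two properties of this procedure worth knowing, both exercised in the
test suite: (i) for a group of animals sharing one latent mean, the
decision-resampling step double-counts within-animal noise and the
hierarchical error bar is conservative (larger than the true sampling
sd), while the animal-only error bar tracks the truth; in the regime the
assay actually produces — groups mixing trained and untrained animals,
where between-animal variance dominates — the hierarchical replicate sd
matches the estimator's true sampling sd closely. (ii) The
ranking-consistency p is not a calibrated type-I error rate; on null
data its rejection rate at 0.05 is merely in the right
neighbourhood.

Fisher's exact test on pooled counts uses the standard two-sided
point-probability rule (sum of table probabilities not exceeding the
observed one), with `p = 1` by convention for any zero margin. The
Mann–Whitney U test on per-animal preferences uses the exact rank-sum
distribution when `min(n, m) ≤ 8` with no ties, otherwise the
tie-corrected normal approximation with continuity correction — the
conventions of the standard implementations the published values were
produced with. No multiplicity correction is applied across comparisons,
matching the source analysis.

## The generator

`generative_config()` encodes the study conditions the analysis assumes:

* `mu_u = 0.27`, `mu_t = 0.52` — the untrained and trained mean
  preferences.
* `rho = 0.4` — per-cycle switch probability (`λ = 0.6`); the study
  prints no value, and this sits where rough method-of-moments on the
  published dose-response counts lands (λ ≈ 0.5–0.6).
* `serial_delta = 0.08` — the post-approach decrement. The source
  analysis reports only the sign of the serial correlation; this
  magnitude gives a mild, realistic deflation (`σ̃ ≈ 0.92` at the
  untrained mean via `implied_sigma_tilde()`).
* decision counts per phase: negative binomial, mean 30, dispersion 8,
  minimum 1 — matching the published per-phase spread of roughly 15–40
  decisions per animal.
* `cycle_doses` — the published design: doses 0, 1, 2, 3, 4, 5, 10, 20
  with group sizes 50, 35, 87, 31, 32, 63, 14, 64.
* `extinction_revert_prob = 0.15` — per-unrewarded-cycle reversion;
  chosen so that the study's 18-cycle extinction block erases most
  (≈ 95%) of a freshly trained state, consistent with the near-complete
  reversal observed after small training doses.

Serial correlation is a two-state Markov chain on the previous choice:
approach probability `m − δ` after an approach and `m + mδ/(1 − m)`
after an avoid, which keeps the stationary mean exactly `m` and gives
lag-1 autocorrelation `−δ/(1 − m)`. Graded mode drifts the latent mean
linearly by `graded_step` per cycle (default reaching `μ_t` at 20
cycles) and clips to [0, 1] — the simplest monotone parameterization of
a graded alternative. Extinction reversion is all-or-none per cycle,
mirroring the observation that extinguished animals return to the
untrained state rather than an intermediate one. Per-animal RNG streams
are derived from the master seed by counter mixing, so enlarging one
dose group never perturbs another group's animals.

What the generator does *not* emulate: spatial trajectories and maze
geometry, CO₂-concentration dependence of the innate preference,
drift of preference within a phase, animal-to-animal heterogeneity in
`μ` or in the serial correlation, and any dependence of decision counts
on training state. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every feature of real data.

## Problem sizes used by the test suite

Simulation-backed tests choose sizes that make their Monte-Carlo
tolerances meaningful: parameter recovery uses 20 replicates of 300
animals per dose across all eight doses (λ within ±0.05 and means within
±0.02 of truth in at least 18 of 20); model-selection recovery uses 50
datasets at the published group sizes (all-or-none lowest BIC in ≥ 90%)
plus 20 graded-generated datasets for the converse; the memoryless-decay
check uses 2000 animals per dose against `(1 − ρ)^i` within three
binomial standard errors; profile endpoints are checked against a 10⁻⁴
grid scan to 10⁻³. Replicated fitting loops use the heuristic plus
nested seeding and a reduced number of random starts, which the
single-fit determinism and nesting tests justify.

## Known limitations

* The Gaussian likelihood is an approximation to a discrete count
  distribution; for animals with very few decisions the discreteness of
  `p` is visible and the variance floor does the work of keeping the
  model honest.
* `σ̃` is global across doses and states in the mixture models; the
  source analysis notes the same simplification and that relaxing it
  does not change the model ranking.
* The ranking-consistency bootstrap p is a descriptive consistency
  measure, not a calibrated test; the Fisher and U tests carry the
  conventional guarantees.
* Reproducing the published fit table's exact ΔAIC/ΔBIC values requires
  the deposited per-animal spreadsheets; `inst/scripts/fit-deposited-data.R`
  runs the identical pipeline on that file when supplied with a column
  map.
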