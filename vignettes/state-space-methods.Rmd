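---
title: "Multidimensional SOFA state-space analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional SOFA state-space analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sofaspace)
```

## The problem and the model

Sepsis trials conventionally compare arms on the total SOFA score — six
organ-system subscores, each 0–4, summed to 0–24. The sum is degenerate
(`(4,0,0,0,0,0)` and `(1,1,1,1,0,0)` both total 4) and discards most of the
routinely measured clinical state. This package takes the opposite view:
every patient-day is a point in the full feature space, and recovery is
movement of that point toward a *reference healthy region*.

Because genuinely healthy states (SOFA = 0) are vanishingly rare in a severe
sepsis cohort, the reference is the empirical distribution of all state
vectors with total SOFA = 1. Dissimilarity is the Mahalanobis distance

$$D(A, R) = \sqrt{(A-\mu)\,\Sigma^{-1}\,(A-\mu)^{\mathsf T}},$$

with $\mu$, $\Sigma$ the reference mean and covariance, which accounts for
feature scale and correlation. Per arm and day $t$ the package reports the
cumulative sum $\mathrm{CumSum}(t) = \sum_{p=1}^{P(t)} D_p(t)$ over the
$P(t)$ patients still present, the per-patient mean
$\mathrm{CumSum}(t)/P(t)$, and both divided by the normalization constant
$c$ — the mean pairwise Mahalanobis distance among the reference members
under the same metric. After normalization, "1" means "as dissimilar as
SOFA = 1 patients are from one another", and the reference's own normalized
self-distance is exactly 1 by construction (a tested invariant).

Two quantities are deliberately reported side by side: the sum conflates
recovery with attrition (arms shrink as patients exit, and arm sizes differ),
so the per-patient mean is treated as the headline recovery curve while the
sum is kept for fidelity to the protocol. Which of the two the original
figure used is not derivable from the protocol text; emitting both sidesteps
the ambiguity.

### Regularization

Reference membership (dozens of states) is typically much smaller than the
feature dimension, so $\Sigma$ is singular. The inverse is computed from
$\Sigma + \lambda I$ with $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/d$ by
default (configurable, including $\lambda = 0$ for well-conditioned cases).
The same regularized inverse is used in the numerator distances and in $c$,
keeping the normalization unit-consistent. At $\lambda = 0$ the whole
normalized analysis is invariant to a global rescaling of the feature space
(a tested property); with $\lambda > 0$ the invariance is approximate, which
is one reason $\lambda$ is kept proportional to the covariance trace rather
than absolute.

## Encoding heterogeneous features

Distances require a continuous, commonly scaled space. Discrete and
pathogen features are mapped through a smoothed target-mean encoding
(category $\mapsto$ (sum of its training targets $+ s\cdot$prior)/(count
$+ s$), prior = global training-target mean, smoothing $s = 1$ by default;
unseen categories fall back to the prior), then all features are
standard-scaled. Both steps are fitted **on training rows only**; the
transform of any row uses exclusively stored training statistics, which the
tests assert by tampering with held-out rows.

The encoding target is the total SOFA score — the only supervised signal the
selection pipeline uses; the protocol names the encoder family but not its
target or configuration. Ordered/permutation-aware encoding variants are
out of scope because distances, not gradient-boosted trees, consume the
encodings. Zero-spread columns scale by 1 (constant features map to 0, never
NaN).

## Feature selection

A genetic-algorithm wrapper selects the feature subset used for the state
space, scored by patient-grouped cross-validated negative mean absolute
error of a SOFA-total regressor (random forest on raw features, or a linear
model on encoded + scaled features, per scenario). Protocol-scale defaults:
populations of 160 fixed-cardinality subsets, 100 generations, cv = 5, 100
repetitions, a 10% pick-frequency threshold, then a final GA over the
thresholded union; a k-sweep with repeated k-fold scoring (10 splits × 3
repeats) supports choosing the subset size.

The GA operators are not specified in the protocol; the package uses
tournament selection (size 3), set-preserving uniform crossover (a child is
$k$ distinct features drawn from the parents' union), a per-individual swap
mutation (rate 0.1), and elitism of 1 — the last makes the best-so-far
fitness trace monotone by construction, which is asserted in tests. CV
folds are grouped by patient throughout: ungrouped folds would leak
within-patient autocorrelation into the fitness. Train/test splits are
re-drawn per repetition from seeds derived deterministically from the run
seed. If the frequency threshold leaves an empty candidate pool, the
fallback is the top-$k$ features by frequency, with a loud warning.

Four scenarios mirror the protocol: (1) all features, raw, forest; (2) all
features, encoded + scaled, linear; (3) and (4) repeat these with three
independent GA runs on the continuous / discrete / pathogen groups, whose
chosen subsets are concatenated — a divide-and-conquer that by construction
cannot capture cross-group interactions. Empty groups are skipped and
logged.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is checked. Each patient carries a latent
six-organ dysfunction vector; subscores are equal-width threshold bins
(cuts at 0.5, 1.5, 2.5, 3.5) of the latent level, clamped to 0–4 — the
clinical SOFA cut-points are deliberately not modeled. Dynamics and
defaults:

* **Initial dysfunction**: per organ, Gamma(shape 6, scale 1/3) — mean 2,
  coefficient of variation ≈ 0.41, giving admission totals around 10–12.
  The narrow spread reflects severe-sepsis inclusion criteria selecting
  patients of broadly similar severity; it is a modeling assumption, chosen
  once.
* **Recovery**: deterministic exponential decay of the latent levels;
  control rate 0.15/day, TDM 0.25/day from `effectOnsetDay = 2` (both arms
  decay at the control rate before onset, so arms are exchangeable at day
  1 — a tested invariant). Equal rates encode the null.
* **Observation**: informative continuous features are signed 1–3-organ
  linear mixes of the latents plus Gaussian noise (sd 0.3); the rest are
  pure noise. Discrete features threshold a nonnegative mix; pathogen flags
  are baseline Bernoulli draws with arm-shared prevalences, constant over
  the stay.
* **Exits**: discharge alive once total SOFA ≤ 1; death with per-day hazard
  $1 - e^{-0.004\,\sum_o L_o}$ (≈ 20% ten-day mortality at the defaults);
  otherwise administrative censoring at `maxDays = 10`.
* **Scale**: defaults emulate the motivating study — 123 + 125 patients,
  199 features (150 continuous, 13 discrete, 36 pathogen flags) of which 28
  are informative, yielding state-vector counts of the same order as the
  study's 2,376.

What the generator does **not** emulate: clinically calibrated SOFA
thresholds and lab-unit systems, pharmacokinetics, measurement drift,
informative missingness, or within-day dynamics. Passing tests therefore
demonstrate that the *pipeline* recovers planted structure under its stated
assumptions — not that the method is validated on real ICU data.

### Why effect-recovery checks keep discharge enabled

An implementation finding worth recording: with exits disabled, fully
recovered patients travel *past* the SOFA = 1 reference (which is not the
healthy origin) and their Mahalanobis distance rises again on late days,
letting the faster-recovering arm's curve cross back above control — an
artifact impossible under the real protocol, where patients are discharged
on recovery. Effect-recovery simulations therefore keep discharge at
SOFA ≤ 1 and disable only the death hazard (isolating recovery dynamics
from mortality attrition), and compare arms on days where both are still
represented.

## Statistics

* **KS statistic**: supremum difference of the two right-continuous
  empirical CDFs, computed from per-patient exit-day samples (the
  statistically standard object; the alternative of comparing cumulative
  exit-count curves directly is noted but not used). Checked against
  `stats::ks.test` on random instances.
* **Hellinger distance**: the standard form
  $\sqrt{\tfrac12\sum_i(\sqrt{f_i}-\sqrt{g_i})^2}$ on a shared integer-day
  bin grid. The protocol's printed formula omits the square roots of the
  densities; only the standard form satisfies the accompanying claim of
  being bounded in [0, 1], so the standard form is implemented. Verified
  against the Gaussian closed form
  $\sqrt{1-e^{-\Delta^2/8}}$ on a fine grid.
* **Two-factor ANOVA**: OLS fit of `last_sofa ~ group + time` on alive
  leavers before day 11, with marginal (Type-2) sums of squares as the
  named choice and the sequential (Type-1) decomposition exposed as an
  option — the two coincide on balanced orthogonal designs (tested). Time
  enters as a continuous covariate by default (single degree of freedom);
  a categorical-day option exists. The analytic p-value is checked against
  a label-permutation p-value, and its null rejection rate is calibrated in
  simulation.
* **Day-1 similarity**: per-patient mean Euclidean distance to all other
  day-1 states (after encoding + scaling), compared between arms with a
  seeded 1,000-permutation test; calibrated to ~5% null rejection.

## Numerical and design choices

* Mode ties in imputation break lexicographically; medians of even counts
  average the two central values — deterministic, seed-free.
* Missing-fraction thresholds: drop above 0.5, impute below 0.05 (the
  protocol states the 5% imputation bound; the drop cutoff is a default,
  both configurable).
* Continuous/discrete split at more than 11 distinct observed values;
  pathogen-derived columns always keep the pathogen kind.
* PCA embeddings fix signs by making each component's largest-magnitude
  loading positive; the t-SNE path is an exact $O(n^2)$ implementation
  (perplexity-calibrated Gaussian affinities, early exaggeration, momentum
  gradient descent), seeded, and adequate for the few thousand state
  vectors this package targets.
* Stage seeds derive from the master seed via a fixed 32-bit-safe integer
  recurrence, so end-to-end runs are byte-identical — the report manifest
  hashes every artifact, figures included (cairo PNG, no embedded
  timestamps).
* Degenerate inputs error loudly and early: fewer than two (distinct)
  reference members, dimension mismatches, unknown units or pathogen codes,
  all-missing columns reaching imputation, single-level ANOVA factors,
  rates outside [0, 1).

## Problem sizes used by the test suite

Simulation-backed checks run at reduced, fixed scales chosen once: effect
recovery at 2 × 60 patients × 10 days × 50 seeds per effect size (rate
difference 0.3/day vs null); GA planted-subset recovery at 5 informative +
20 noise features, populations of 40, 25 generations, 20 repetitions;
null calibrations at 200 seeds; the end-to-end determinism check on a
24-patient smoke configuration. Protocol-scale settings (160 × 100 × 100)
remain available through `gaConfig()`.

## Known limitations

* The reference is a population proxy for health; individualized healthy
  states are out of scope.
* The latent-dynamics generator is linear-Gaussian with deterministic
  decay; it supports parameter-recovery testing, not clinical realism.
* With the default ridge, normalized distances are only approximately
  invariant to feature rescaling.
* Exact GA planted-subset recovery is only identifiable when the planted
  features are not mutually redundant; with correlated informative
  features the pick-frequency contrast (informative ≫ noise) is the
  meaningful statement.
* Real-data results of the motivating study (its KS, Hellinger and ANOVA
  values) require the request-only trial data and are not reproduced here.
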