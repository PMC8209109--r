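---
title: "Quantifying sample-size-driven misestimation of classifier accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sample-size-driven misestimation of classifier accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An accuracy estimate is a statistic, and like any statistic it has a
sampling distribution. When a case/control classifier is evaluated on `m`
held-out subjects, the estimate takes values `k/m` and its spread scales
like `1/sqrt(m)`. For the sample sizes common in neuroimaging-style
prediction studies (tens of subjects), that spread is enormous: a study
whose classifier is truly 61% accurate can report anything from ~35% to
~95% at N = 20, and a classifier that is *exactly at chance* will appear to
reach 70% in about one of every seventeen N = 20 test sets. Because
over-estimates are more likely to be published than under-estimates, this
mechanism alone can explain why small studies systematically report higher
accuracies than large ones.

`misestimatr` makes this mechanism measurable. It provides (i) a synthetic
cohort generator with an exactly known true (Bayes) accuracy, (ii)
leakage-free classification pipelines with a LOOCV evaluator and a
chance-level baseline, (iii) the three resampling experiments that separate
overall, training-set and test-set size effects, and (iv) exact analytic
oracles for the two cases where the sampling distribution is fully known —
a chance-level classifier (binomial) and a fixed classifier evaluated on
subsamples of a frozen prediction pool (hypergeometric).

## The generative model and its calibration

`generate_cohort()` draws features from two equal-covariance spherical
Gaussian classes in `p` dimensions. The class-mean difference has
Mahalanobis norm `d`, spread uniformly over the features (per-feature shift
`d/sqrt(p)`), so the Bayes-optimal rule is linear and its accuracy has the
closed form Φ(`d`/2) (`bayes_accuracy()`). The generator is calibrated by
inverting this: `calibrate_separation(a) = 2·Φ⁻¹(a)`, and the round trip is
exact to numerical precision. The default target of 0.61 corresponds to a
weakly separable problem of the kind motivating the package.

```{r}
library(misestimatr)
calibrate_separation(0.61)      # Mahalanobis separation 0.559
bayes_accuracy(0.559)           # ~0.61 back again
```

Why this model: it is the simplest generative family whose true accuracy is
known exactly, which is what makes every downstream claim testable — the
tests validate the calibration by classifying generated cohorts with the
*true* class-mean direction and checking the hit rate against the target
within binomial Monte-Carlo bands.

What the generator emulates and what it does not. It reproduces the
post-preprocessing *shape* of an image-derived feature matrix — a wide
numeric subjects × features table with binary labels, imbalanced class
counts (default 1306 cases vs 934 controls) and a weak linear signal — plus
an optional multi-site structure as additive per-site feature offsets
(default scale 0; site effects in the motivating data were negligible, the
knob exists for sensitivity checks). It does *not* emulate spatial
correlation between features, non-Gaussian marginals, heteroscedastic
classes, nonlinear class boundaries, or demographic covariates, and the
default dimension is 500 features rather than tens of thousands (keeping
`p >> N` for the sample sizes under study while staying desk-scale). Tests
passing on these cohorts therefore demonstrate properties of the
*estimation procedure*, which is the object of study — not claims about any
particular real dataset, whose feature distribution the generator does not
model. Class imbalance is removed up front by `random_undersample()`
(uniform without-replacement thinning of the majority class), exactly so
that prevalence cannot leak into accuracy.

## Pipelines and the leakage contract

Every pipeline stage — zero-variance filter, per-feature standardization,
PCA or F-test feature selection, classifier — is fit on training rows only,
and `loocv_accuracy()` refits the entire pipeline inside every fold. This
is deliberately strict: recomputing the zero-variance filter per fold is
nearly a no-op on Gaussian data, but it keeps the contract unconditional.
The scaler is the stage where leakage is classically introduced, so the
evaluator also exposes an intentionally leaky variant
(`scaler_scope = "global"`) whose only purpose is to demonstrate, in the
test suite, that the two code paths produce different LOOCV accuracies on a
crafted dataset with extreme-valued subjects.

Numerical and procedural choices:

* SVMs use conventional defaults — `C = 1`; the RBF width defaults to
  `1/(p · var(X))` computed on the (standardized) training matrix. Decision
  ties are resolved deterministically by the underlying libsvm
  implementation.
* `reducer_pca(k)` caps `k` at `min(training rows − 1, columns)` at fit
  time; `reducer_f_select(k)` scores each feature by the one-way ANOVA F
  statistic and breaks ties toward the lower column index, so selection is
  fully deterministic.
* A training fold containing a single class is an error for discriminative
  classifiers, never silently tolerated; balanced cohorts with `N ≥ 4`
  cannot trigger it under LOOCV.
* The 48-configuration sweep (`default_config_grid()`) is 6 classifier
  settings (linear and RBF SVM at `C ∈ {0.1, 1}`, random forests with 100
  and 500 trees) × 8 reducer settings (none, PCA `k ∈ {10, 50, 100}`,
  F-selection `k ∈ {10, 50, 100, 500}`). PCA components stop at 100 because
  the reducer is bounded by training rows for the sample sizes the sweep
  targets, while univariate F-selection has no such bound. This grid is the
  package's own reconstruction of a broad robustness sweep; it is the
  documented default, not a canonical external artifact.

## The chance-level baseline

`dummy_prior()` ignores all features and draws each predicted label from
the class prevalence of its training data. On balanced data its true
accuracy is exactly 50% and its *estimated* accuracy over `m` test
predictions is exactly `Binomial(m, 1/2)/m` — which is what makes it the
analytic reference for "how much apparent accuracy does sample size alone
buy".

One subtlety deserves record. Under leave-one-out evaluation the training
fold of a balanced sample of N is one subject short of balance, so a prior
refit inside each fold equals `(N/2 − 1)/(N − 1)` for the held-out
subject's class — systematically *below* ½ (at N = 20, 9/19 ≈ 0.474), a
mild relative of the classic majority-vote LOOCV pathology (which the
package ships as `majority_vote()`, scoring exactly 0 on balanced samples).
Because the baseline is defined by the prevalence of the balanced sample
under analysis — exactly 50% — `loocv_accuracy()` fits the feature-blind
dummy's prior on that full sample and draws each subject's prediction
independently from it, preserving the exact binomial reference
distribution. Wherever a genuine training/test split exists (the
training-size and test-size analyses), the dummy is refit on the training
set like any other classifier.

A related empirical note: the leakage-free LOOCV of a *real* classifier on
zero-signal data is itself slightly pessimistic (each fold's model
anti-correlates with its held-out subject), so the package's tests assert
the absence of *optimistic* bias at chance rather than an exact 50% mean
for the SVM.

## The three experiments

All three experiments share `sampling_plan()`: a grid of sizes, a replicate
count, and a master seed. Balanced subsamples draw `N/2` subjects per class
uniformly without replacement; replicates are independent and may overlap.
A literally balanced sample requires even N, so the default
`balance_mode = "even_only"` rejects odd sizes; `"near_balanced"` admits a
step-1 grid by assigning the extra subject's class with a seeded coin flip
per replicate (the full-scale preset uses this mode).

1. **Overall size** (`overall_sample_size_analysis()`): for each (N,
   replicate), a fresh balanced subsample is evaluated by LOOCV of the full
   pipeline — the design of a small self-contained study. Both training and
   test information shrink together; this is where misestimation is worst.
2. **Training-set size** (`training_set_size_analysis()`): one balanced
   test set (default 300) is drawn once and held fixed; training sets of
   size N are drawn disjointly from the remainder. Isolates what training
   size does to the *true* performance and its stability.
3. **Test-set size** (`test_set_size_analysis()`): one balanced prediction
   pool (default 300) is drawn once; from the remainder a balanced holdout
   (default 20% per class) is set aside and a single model is trained on
   the rest — on a 934 + 934 cohort the partition is exactly 150 + 150 /
   157 + 157 / 627 + 627. The model's per-subject correctness over the pool
   is frozen; every (N, replicate) accuracy is then a deterministic
   function of which pool subjects are drawn. This isolates pure test-set
   sampling error, and makes the exact hypergeometric oracle applicable.

**Seeding.** The master seed derives a per-analysis stream and a
per-(N, replicate) substream by pure counter arithmetic
(`master → stream → (N, rep)`), so results are bit-identical across reruns,
independent of execution order, and extending `reps_per_n` never alters
earlier replicates. Configuration sweeps derive an independent child master
seed per configuration label (`sweep_child_plan()`), making a sweep of one
configuration exactly reproducible by a direct call.

## The exact oracles

For a fixed classifier with `K₁` of `M₁` cases and `K₂` of `M₂` controls
predicted correctly in the pool, the number of correct predictions in a
balanced without-replacement subsample of `n` is the sum of two independent
hypergeometric counts. `pool_subsample_moments()` returns the exact mean
and SD, including the per-class finite-population correction
`(M − n/2)/(M − 1)`; `pool_subsample_exceedance()` convolves the two mass
functions for exact threshold probabilities. The test suite cross-checks
three independent routes — closed-form moments, brute-force convolution,
and seeded simulation (`simulate_pool_subsample()`) — against each other.

Thresholds are inclusive ("70% or higher") and are always compared on
integer correct counts (`correct ≥ ⌈τ·m⌉`, with a small epsilon guarding
the ceiling), both in the oracles and in `summarize_grid()`, so floating
point can never move an accuracy across a threshold boundary. Summary SDs
use the sample (n−1) convention, recorded in the table's attributes; at
1000 replicates the difference from the population convention is below
0.1%.

## Scale of the shipped analyses

The full-scale plan (sizes 4–150 step 1, 1000 replicates — 147,000
subsample draws, ~11.3 million LOOCV fits in the overall analysis) is
available as `preset_plan("full-scale")` but is not the default. The
package's own test and acceptance runs use deliberately reduced designs:
even sizes with 40–300 replicates, cohorts of 100 features for the
overall-LOOCV properties, and 5-feature cohorts for the training- and
test-size properties — the low-dimensional setting is chosen so the
learning curve actually moves within N ≤ 150, which is what makes the
"SD decreases with N" and "mean rises toward the Bayes ceiling" properties
observable against Monte-Carlo noise at these replicate counts. The
properties checked are identical at every scale; only their Monte-Carlo
resolution differs.

## Known limitations

* The Gaussian generator is a stand-in: no claim is made that any real
  imaging dataset has this feature distribution, and effects that depend on
  heavy tails, feature correlation or site-by-class confounding are out of
  scope.
* The exceedance oracles condition on a *frozen* pool; they describe
  test-set sampling error only, not variability of the trained model
  itself (that is what the training-size experiment measures empirically).
* Execution is single-process; the counter-based seeding is
  worker-independent by construction, but no parallel backend is bundled.
* `run_study()` figures are optional conveniences behind ggplot2/patchwork;
  the CSV/JSON artifacts are the canonical outputs.
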