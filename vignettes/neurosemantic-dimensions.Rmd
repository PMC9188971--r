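---
title: "Decoding and factoring abstract-concept representations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and factoring abstract-concept representations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodims)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical choices made where the published
methodology leaves room, and what the synthetic validation does and does not
establish about real data.

## The analysis problem

Participants from two language cohorts think about the same set of 28
abstract concepts while fMRI volumes are acquired once per second. Each
concept is presented 6 times. The analysis asks three questions of
increasing generality: can a concept be identified from one participant's
activation pattern (within-participant decoding); is the code shared across
speakers of a language (between-participant decoding); and is it shared
across languages (cross-language decoding, and a factor analysis that makes
the shared dimensions explicit)?

## Trial activation measure

The per-trial measure (`compute_mpsc`) is the mean of the four images
acquired 5–8 s after stimulus onset — around the hemodynamic peak — at
each gray-matter voxel, expressed as percent signal change against a
fixation baseline. Each trial's voxel vector is then z-scored across
voxels, so patterns rather than global amplitude carry information.

Two conventions needed fixing:

* **SD convention.** Trial z-scoring divides by the sample SD (n − 1),
  matching R's `scale()` and `sd()`; a two-voxel trial with values (1, 3)
  becomes (−0.707, +0.707). Idempotence (normalizing twice equals
  normalizing once) holds either way; only cross-package comparability is
  affected.
* **Onsets** are 0-based sample offsets, so `window_offset = 5`,
  `window_length = 4` selects exactly the images 5, 6, 7 and 8 seconds
  post-onset. A window that leaves the recorded span, a duplicated concept
  within a presentation block, and a zero-variance trial are all rejected
  with informative errors rather than silently patched.

## Voxel stability and feature selection

A voxel is useful for decoding when its *tuning curve* — its activation
across the 28 concepts — is reproducible. Stability is the mean pairwise
Pearson correlation of tuning curves across presentation blocks (within a
participant) or across presentation-averaged participants (between). Voxels
with zero tuning variance in any unit have no defined correlation; they are
flagged `NA` and excluded from ranking rather than scored 0, so dead voxels
cannot be promoted by ties. Ties among defined scores break by ascending
voxel index, making selection deterministic.

Defaults follow the paradigm's conventions: classifiers use the **120**
most stable voxels; the factor analysis uses **410** voxels allocated
across six broad regions (40 + 30 + 60 + 60 + 60 + 160). The path from a
stable-voxel map to that particular allocation involves anatomical
judgment, so the allocation is configuration (`allocate_by_roi` takes any
named region → count vector); `default_roi_allocation()` records the
canonical one. Atlases are not bundled: region labels are user-supplied,
and `synthetic_roi_labels()` partitions a simulated grid proportionally so
the mechanism can be exercised with known truth.

Stability used for feature selection is always computed on training data
only — training blocks within a CV fold, training participants in
leave-one-out — and the tests include a metamorphic check that corrupting
held-out data cannot change the selected features.

## Gaussian naive Bayes decoding and rank accuracy

The classifier (`gnb_train`) models each concept as a Gaussian per feature.
Design choices:

* **Pooled (tied) within-class variance** per feature, the robust choice at
  4 samples per class; per-class variances sit behind
  `pooled_variance = FALSE`.
* **Variance floor** of 1e-6 × the mean pooled variance (absolute 1e-6 when
  that mean is zero) so degenerate features cannot produce infinite
  likelihoods.
* **Uniform priors**, reflecting the balanced design.
* Posteriors are computed in log space and normalized by log-sum-exp, so
  well-separated classes yield exact 0/1 posteriors instead of NaN.

Performance is **normalized rank accuracy**: with the correct concept at
rank r (average rank under ties) of N alternatives, accuracy is
(N − r)/(N − 1); 1 means ranked first, 0 last, and a fully tied posterior
scores exactly 0.5 — the same value as the expectation under random
ranking, which is why 0.5 is the chance level.

The cross-validation schemes:

* **Within-participant:** train on the single-trial patterns of 4 of the 6
  blocks (each block contributes one sample per concept; only the test pair
  is averaged), test on the average of the held-out 2, over all
  choose(6, 2) = 15 folds. Stability and the 120-voxel selection are
  recomputed per fold from the training blocks.
* **Between-participant:** leave one participant out; training samples are
  the presentation-averaged signatures of the remaining participants, and
  features are the top cross-participant stable voxels among them.
* **Cross-language:** train on all of one cohort, test on each participant
  of the other; per-concept accuracies are averaged over test participants
  and then over the two directions. Features are typically the
  factor-location voxels, connecting the decoding result to the dimensional
  account.

**Permutation test.** The null distribution permutes the test-set concept
labels with the trained model's posteriors fixed, recomputing the mean rank
accuracy per iteration; p = (1 + #{null ≥ observed})/(1 + n_iter), with
accuracy cutoffs reported at α ∈ {.05, .01, .001}. Label permutation with
fixed fits is exact here because the classifier never saw the test labels.
A retraining variant would answer a different question (sensitivity of
feature selection to labels) at 10,000× the cost; it was not implemented.

## Two-level factor analysis

The dimensional analysis factors each participant's presentation-averaged
28 × 410 matrix into 7 factors (`first_level`), then factors the
concatenated 28 × 112 matrix of all participants' factor scores into 6
group factors (`second_level`). The two-level structure lets participants
differ in where a dimension lives voxel-wise while the group level finds
score patterns over concepts that recur across participants and cohorts.

`principal_axis_fa` implements iterated principal-axis factoring:
squared-multiple-correlation starting communalities, eigendecomposition of
the reduced correlation matrix, communality update, iterated until the
largest change falls below 1e-4 (at most 100 iterations; non-convergence is
an error that reports the last delta). Numerical choices worth recording:

* With 28 observations and hundreds of variables the correlation matrix is
  structurally rank-deficient. The SMC start uses a ridge of 1e-8 (applied
  quietly in the n ≤ p case, with a warning otherwise), communalities are
  clamped to [0, 0.999] (Heywood protection), and **regression factor
  scores use the eigenvalue-thresholded pseudo-inverse** — a plain ridge
  inverse amplifies null-space rounding noise by ~1e8 and visibly corrupts
  scores on exactly low-rank data.
* **Varimax rotation** (the conventional default; `rotate = "none"`
  available) is started from a fixed non-trivial orthogonal rotation. The
  identity start is a stationary point of the varimax criterion for exactly
  symmetric loading configurations — cloned participants produce tied
  eigenvalues and an unrotatable 45° mixture without this.
* Factors are sorted by explained variance and sign-anchored so each
  factor's largest-|loading| entry is positive, making solutions
  reproducible across runs and input orderings.
* Factor scores are standardized to mean 0, SD 1 per column.

**Factor locations.** A group factor is projected back to voxels through
each participant's best-matching first-level factor (by |score
correlation|), sign-aligned, averaged over the participants whose match
reaches the loading threshold, then thresholded at 0.4, cut into connected
components (6-connectivity by default; 18/26 available), and clusters of at
least 15 voxels (10 in figure-style reporting; both supported) are kept,
with spheres of 6 mm (configurable — no canonical value exists) around the
centroids. Restricting the projection to expressing participants matters
for cohort-specific dimensions: averaging over everyone dilutes a dimension
carried by only one cohort below threshold. On default synthetic runs it is
typical for five of the six group factors to localize and for one residual
factor to yield no cluster.

**Matching solutions across cohorts** (`match_factors`) maximizes the total
|score correlation| over one-to-one factor assignments. Factor counts never
exceed seven, so the optimum is found by exact exhaustive search with
branch-and-bound pruning (guarded at > 9 factors); signs are flipped so
matched correlations are positive, and the full cross-correlation matrix is
reported for inspection.

## Rating-based encoding

`encode_evaluate` asks whether an independent group's 1–7 ratings of each
concept on each dimension suffice to predict the concept's activation
pattern in the factor locations. Per voxel, activation is regressed on the
rating dimensions (OLS with intercept — 27 training concepts against ≤ 5
predictors is well-posed; no regularization) and the held-out concept's
pattern is predicted from its ratings.

Scoring needed one substantive design decision. The classic evaluation
ranks the Euclidean distance from the predicted pattern to the held-out
concept's observed pattern among its distances to all 28 observed patterns.
Its 27 competitor distances involve patterns that were fitting targets, and
OLS pulls predictions toward its targets: under a true null (ratings
independent of activation) the measured mean accuracy is ≈ 0.46, not 0.5,
and a permutation test that relabels predictions with fits held fixed
inherits the asymmetry and is not calibrated. The package therefore scores
by **leave-pair-out** comparisons by default (`scoring = "pair"`): for each
ordered pair of concepts, both are excluded from the fit, the first is
predicted from its ratings, and the prediction is checked for being closer
to the first's observed pattern than to the second's. Every comparison is
out-of-sample, chance is exactly 0.5 by exchangeability, and the
permutation test — which relabels the observed patterns and re-derives all
predictions through a precomputed hat-matrix, at one matrix product per
iteration — is exactly calibrated. The classic scheme remains available as
`scoring = "loco"` with the fixed-fit relabeling permutation, for
comparability.

## The synthetic generator

`simulate_cohorts` generates the two-cohort study design: activation of
participant p, presentation r, concept c, voxel v is

    sum_k  w[p,k] · salience[cohort,k] · S[c,k] · L[v,k]  +  noise,

z-scored per trial. The factor scores S (orthonormalized, standardized) and
clustered loadings L are shared across cohorts for the `K_shared = 4`
semantic dimensions; one cohort-specific dimension — the analogue of
written word length, whose visual form differs across scripts — keeps its
loading cluster but draws cohort-specific scores correlated at ≈ 0.2.
Loading clusters are disjoint axis-aligned blocks (40 voxels each by
default) so the contiguity rules of `factor_locations` can be exercised
against known truth. The grid defaults to 10 × 10 × 6 voxels at
3.125 × 3.125 × 6 mm spacing, mirroring an echo-planar acquisition, so
mm-based sphere radii behave realistically.

Defaults were fixed once to emulate the regime the paradigm reports for
real data: presentation noise `noise_sd = 2` (≈ 2.5× the in-cluster signal
SD) puts single-trial within-participant decoding in the 0.85–0.95 range
with 120 features, and participant weight dispersion
`participant_sd = 0.3` leaves clear cross-participant generalization. The
generator draws independent Gaussian noise: it emulates neither spatial
autocorrelation, hemodynamic temporal structure, motion artifacts, nor
anatomical variability. Passing recovery tests on it therefore shows the
*algorithms* are correct and calibrated — not that real cohorts of this
size would yield the same accuracies.

`null_cohort` produces size-matched pure-noise data for false-positive
calibration; `synthetic_ratings` maps planted scores onto a bounded 1–7
scale with rater noise.

## Problem sizes used in validation

The test suite validates at two scales: a small spec (120 voxels, 12
concepts, 4 + 3 participants, 4 presentations) for operation-level
properties, and the default preset (600 voxels, 28 concepts, 9 + 7
participants, 6 presentations) for end-to-end recovery — 10 generator
seeds for the planted-dimension recovery check, 20 for stability ranking,
Monte-Carlo sizes of 10,000 for chance calibration and 100 independent
datasets for permutation-calibration KS checks.

## Known limitations

* Preprocessing (motion correction, spatial normalization, GLM estimation)
  is out of scope; inputs are PSC time series or trial matrices on a common
  grid.
* The per-region voxel allocation is taken as configuration; the package
  does not derive allocations from an atlas.
* Factor interpretability (naming a dimension "verbal" or "social") is a
  human judgment over score extremes and locations; the package computes
  the evidence (scores, locations, rating correlations) but attaches no
  labels.
* `match_factors` is exact but exponential; it is guarded above 9 factors.
* Storage is delimited text plus JSON manifests; no NIfTI import/export.
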