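# neurodims

Multivariate pattern analysis of concept-evoked fMRI activation, built
around one question: do different people — and speakers of different
languages — use a common set of neurosemantic dimensions to represent
abstract concepts such as *ethics*, *causality* or *forgiveness*?

The package implements the full analysis chain for a paradigm in which two
cohorts (e.g. 9 English and 7 Mandarin speakers) each think about the same
28 abstract concepts, 6 presentations per concept, while whole-brain
activation is recorded on a common voxel grid:

- **Trial activation measure** — the mean of the four images acquired 5-8 s
  after stimulus onset (the hemodynamic peak), z-scored across voxels within
  each trial (`compute_mpsc`).
- **Stability-based voxel selection** — a voxel's stability is the mean
  pairwise Pearson correlation of its 28-concept tuning curve across
  presentations (within a participant) or across participants
  (`voxel_stability_within`, `voxel_stability_between`); classifiers use the
  120 most stable voxels, the factor analysis 410 voxels allocated across
  regions (`select_top_k`, `allocate_by_roi`).
- **Gaussian naive Bayes decoding** with normalized rank accuracy
  `(N − r)/(N − 1)` (chance 0.5), under three cross-validation schemes:
  within participant (train on 4 of 6 presentations, test on the average of
  the held-out 2; all 15 folds), between participants (leave one out), and
  cross-language (train on one cohort, test on the other, both directions),
  with permutation-test significance (`within_participant_cv`,
  `between_participant_cv`, `cross_language_classify`, `permutation_test`).
- **Two-level factor analysis** — principal-axis factoring with varimax
  rotation per participant (28 concepts × 410 voxels, 7 factors), then a
  group factoring of the 16 × 7 = 112 concatenated factor-score vectors
  (6 factors), yielding shared semantic dimensions; high-loading (≥ 0.4)
  voxels forming contiguous clusters (≥ 15 voxels) give each dimension its
  brain location (`first_level`, `second_level`, `factor_locations`,
  `match_factors`).
- **Rating-based encoding** — leave-one-concept-out regression of voxel
  activation on behavioral 1-7 ratings of each dimension's salience,
  scored by Euclidean-distance rank accuracy with permutation significance
  (`fit_predict_loco`, `encode_evaluate`).
- **Synthetic two-cohort generator** with planted latent dimensions
  (`simulate_cohorts`, `null_cohort`), so every stage can be validated
  against ground truth.

## Worked example

Simulate two cohorts whose activation patterns share four planted semantic
dimensions (plus one cohort-specific word-length dimension), decode concepts
within and between participants, and recover the planted dimensions with the
two-level factor analysis:

```r
library(neurodims)

sim <- simulate_cohorts(generative_spec(seed = 42))
sim$cohorts$english
#> activation_dataset: 9 participants (english), 6 presentations, 28 concepts, 600 voxels

within_participant_cv(sim$cohorts$english, 1)
#> decode_result (within_participant): mean rank accuracy 0.881 over 15 folds, 28 concepts

between_participant_cv(sim$cohorts$english)
#> decode_result (between_participant): mean rank accuracy 0.989 over 9 folds, 28 concepts

# two-level factor analysis over both cohorts
comb <- combine_cohorts(sim$cohorts$english, sim$cohorts$mandarin)
stab <- voxel_stability_between(comb)
vox  <- allocate_by_roi(stab, synthetic_roi_labels(comb$grid),
                        default_roi_allocation())
fls  <- lapply(seq_along(comb$participant_ids),
               function(p) first_level(comb, p, vox))
sl   <- second_level(fls)
sl
#> fa_solution (second level): 112 variables, 28 observations, 6 factors, 68.1% variance

# each planted shared dimension re-emerges as a group factor
apply(abs(cor(sim$truth$scores_shared, sl$factor_scores)), 1, max)
#> 0.990 0.995 0.995 0.997
```

A rank accuracy of 0.881 means that, averaged over folds and concepts, the
correct concept sat in the 88th percentile of the classifier's 28-way
probability-ranked list; 0.5 is chance. The planted-dimension correlations
near 1 show the group factoring recovering the latent structure the
generator embedded in both cohorts.

`run_pipeline(run_config())` chains all stages — simulation, stability,
the three decoding schemes, per-cohort and combined factor analyses with
cross-cohort factor matching, factor locations and rating-based encoding —
and can write per-concept accuracy tables, factor-score extremes and the
cross-cohort factor correlation matrix to an output directory.

## Scope

Scanner acquisition, motion correction, spatial normalization and GLM
estimation are out of scope: the package starts from percent-signal-change
trial data (or precomputed trial activation matrices) on a common grid.
Anatomical atlases are not bundled; region labels for the per-region voxel
allocation are user-supplied (or generated synthetically for simulated
grids).
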