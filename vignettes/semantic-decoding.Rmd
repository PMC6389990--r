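---
title: "Zero-shot semantic decoding and searchlight RSA: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot semantic decoding and searchlight RSA: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdecode)
```

## The scientific setting

`semdecode` implements an analysis pipeline for a class of fMRI experiments in
which object concepts are probed *indirectly*: on every trial the participant
reads a triplet of verbal clues (semantic features such as "has legs", "has a
trunk") and silently infers the target object, which is never shown. The
design of interest has 60 target objects in four semantic categories (15
each), nine clue features per target arranged into six unique triplets, hence
360 trials, and trial-level beta maps estimated from the BOLD signal.

Two questions drive the analysis:

1. **Zero-shot decoding.** Can a linear mapping, learned between voxel
   patterns and corpus-derived word-embedding coordinates of *other* objects,
   identify objects it was never trained on?
2. **Pattern completion.** Are the evoked patterns better described by the
   semantic coordinates of the *full feature set* of the target object than by
   the coordinates of the three clues that were actually presented? If so, the
   brain has enriched the fragmentary input with stored knowledge.

## Semantic coordinate models

Every trial is assigned a D-dimensional coordinate (D = 300 by default) in a
word-embedding space under six models (`coordinate_models()`): the third clue
alone (`CLUE3`), the sum of the three presented clues (`CLUE123`), the target
word (`TARGET`), the sum over the target's full feature norm (`ALL_FEATURES`),
the clue sum of a *donor* trial of the same target with disjoint clues
(`MIXED_CLUES`), and the feature-norm sum excluding all nine clue features
(`ALL_NONCLUES`). Feature texts resolve to a single key token through a
table-driven keyword map; vectors are summed **without** length
normalization, so the exact identity

> `ALL_FEATURES = ALL_NONCLUES + (sum of the 9 clue vectors)`

holds component-wise and is asserted in the test suite. Multi-word features
are represented by one key word each; we do not average constituent word
vectors. Lookup is exact after lower-casing, with no fuzzy fallback:
upstream lemmatization is treated as an input, not something this package
attempts.

## The decoder

The mapping from voxel space to semantic space is per-dimension ridge
regression with an intercept. Predictors and responses are *centered* with
training-fold means; we deliberately do not rescale voxels to unit variance.
Betas share one physical unit across voxels, centering is what the intercept
requires, and — unlike per-voxel rescaling — centering is exactly expressible
in the gram (kernel) form `K = X X'` that makes the exhaustive evaluation
schemes tractable. The primal and gram solutions are verified against each
other in the tests.

The regularization strength is chosen by generalized cross-validation (GCV)
over a 41-point logarithmic grid scaled to the spectrum of the training
predictors, always inside the training fold; a fixed value can be supplied
instead. In multi-subject single-trial runs we select the strength once by
in-fold GCV on the first subject (median over its folds) and hold it fixed
for the remaining subjects: this keeps the analysis deterministic and cheap
while using no data of the subjects it is applied to.

**Evaluation** is zero-shot leave-two-out: for each unordered pair of
targets, all their data are removed, the mapping is fitted on the remainder,
both held-out items are predicted, and the pairing is correct iff

`d(p1,t1) + d(p2,t2) < d(p1,t2) + d(p2,t1)`

with `d` the cosine distance. Exact equality of the sums is a tie and scores
0.5; ties occur by construction when the two true coordinates coincide (e.g.
same-target trial pairs under the `TARGET` model). With 60 targets the
averaged-data scheme has `choose(60,2) = 1770` folds; the single-trial scheme
enumerates all `choose(360,2) = 64620` trial pairs, trains distinct-target
folds on the 348 trials of the other 58 targets, and reports same-target
pairs (900 of them) as a separate stratum excluded from the headline
accuracy, since their "identity" cannot be decided under trial-invariant
models.

Within the averaged scheme, **stability selection** keeps the 500 voxels
whose six repetition profiles correlate most consistently (mean of the 15
pairwise Pearson correlations across the 58 training targets, recomputed in
every fold; zero-variance profiles contribute r = 0; ties break by voxel
index). The selection provably never sees the held-out targets, which the
tests assert by perturbing held-out data. Single-trial decoding uses all
masked voxels: with every trial carrying a different clue triplet there are
no repetitions to stabilize over, and selection could erase exactly the
trial-level variability under study.

**Chance calibration** uses permutation: each iteration shuffles the
coordinate-to-target assignment in the training set only, reruns the full
scheme, and records the overall accuracy; the significance threshold is the
empirical 95th percentile (type-1 / order-statistic quantile) of the null.
Because stability scores depend only on the betas — never on the coordinates
— the per-fold voxel selection is *identical* under permutation, so it is
reused, as is each fold's GCV-chosen strength; predictions are recomputed
against the shuffled training coordinates while the held-out truths stay
intact.

Model accuracies are compared across subjects with paired two-sided t-tests,
Bonferroni-corrected by the number of pairwise comparisons (15 for six
models). Zero-variance difference vectors use the limiting convention
(all-zero differences: t = 0, p = 1; constant nonzero offset: |t| = Inf,
p = 0). The mapping is also invertible: `predict_activation()` returns the
minimum-norm least-squares preimage of a semantic coordinate under the
fitted weights (Moore–Penrose), which predicts activation patterns for novel
concepts and behaves as an affine map (tested).

## Searchlight RSA and group inference

For each mask voxel with at least two in-sphere voxels (radius 7 mm on the
3.1 mm grid), the activation RDM over the sphere (1 − Pearson correlation
between trial patterns) is compared to the semantic model RDM (cosine
distances between trial coordinates; 360 × 360 in the full design) by
Spearman rank correlation of the strictly-lower-triangle vectors. Using only
the lower triangle avoids double-counting the symmetric matrix; all
off-diagonal pairs are included, same-target pairs among them, since those
carry exactly the within-concept similarity structure the analysis is about.
Ties receive average ranks, making the statistic invariant under any strictly
monotone transform of the model distances (tested with a cubic). The
correlation is Fisher-transformed, with |rho| = 1 capped at `1 - 1e-15` so
the map stays finite in degenerate toys; constant RDM vectors yield 0 with a
warning.

Group inference is a one-sample nonparametric test over the subjects'
(6 mm-FWHM pre-smoothed) z maps: the pseudo-t statistic divides the subject
mean by a standard error whose variance image is itself smoothed at 6 mm
FWHM, stabilizing the denominator at this sample size. Smoothing kernels are
Gaussian with `sigma = FWHM / (2 sqrt(2 ln 2))`, evaluated only between
in-mask voxels and row-renormalized, so no signal bleeds across the mask
boundary and a constant image is a fixed point (tested). The null flips the
sign of whole subject maps (valid under the symmetric-null assumption);
if the requested permutation count reaches `2^n` the distinct sign patterns
are enumerated exhaustively. Family-wise error is controlled by the maximum
statistic: the threshold is the empirical 95th percentile of the max-null
distribution, and per-voxel FWE p values come from the same distribution.
Significant voxels are reported as 6-connectivity clusters with extent and
peak (`cluster_table()`).

## What the generator emulates — and what it does not

`sim_config()` / `simulate_experiment()` generate every input the pipeline
needs, with known ground truth:

* **Semantic space.** Category centroids `N(0, sigma_category^2 I)` (default
  1), targets at `centroid + N(0, sigma_item^2 I)` (default 0.5), features at
  `alpha * target + N(0, sigma_feature^2 I)` (defaults 0.8 and 0.6), in
  dimensionless embedding units. This reproduces the two properties the
  analysis relies on: strong category structure plus item-specific detail,
  and features that are noisy copies of their concept.
* **Design.** Nine ranked clues per target split into three position groups;
  set 1 shows the within-rank triplets, set 2 regroups them with cyclic
  shifts so every clue keeps its within-triplet position while groupings
  differ — six pairwise-distinct triplets per target, each clue shown once
  per set. Triplets are ordered least-to-most distinctive, and every trial
  gets a clue-disjoint donor trial from another block for `MIXED_CLUES`.
* **Forward model.** Trial betas are `W s_t + N(0, noise_sd^2)`, where `s_t`
  is the target's **ALL_FEATURES** coordinate and `W` is nonzero on 500
  informative voxels (weights `N(0, 1/D)`, which makes the per-voxel signal
  scale independent of D). Driving voxels with the full feature sum — not
  with the clues actually shown — encodes the pattern-completion hypothesis
  as the generative truth, so recovery of the model ordering
  (`ALL_FEATURES > CLUE123 > CLUE3`, `ALL_NONCLUES` above chance) is a
  meaningful end-to-end check rather than a tautology.
* **Geometry.** A 24×24×24 grid of 3.1 mm isotropic voxels with an
  inscribed-sphere analysis mask (~6,500 voxels). Informative voxels are
  placed uniformly at random by default (the decoder makes no spatial claim)
  or as one contiguous blob (`informative_layout = "blob"`) for searchlight
  localization studies. Subjects share the stimulus design and the
  informative *locations* (shared functional anatomy) but have independent
  weights and noise.

The default `noise_sd = 60` was fixed once from the forward-model
signal-to-noise calculation (per-voxel signal SD ≈ 17 under the default
dispersions) together with a pilot run, so that default-noise averaged-data
decoding lands in the meaningful mid-range between chance and ceiling
(~93% overall, ~76% within-category with a single default-seed subject)
rather than saturating; it is a package default, not an empirical claim
about any dataset.

Deliberately **not** modeled: hemodynamics and GLM estimation (the pipeline
consumes betas; trial time courses are out of scope), spatially correlated
noise, physiological or motion artifacts, and inter-subject anatomical
variability. Passing tests therefore demonstrate the correctness and
calibration of the *analysis* under a linear forward model with white noise
— not robustness to fMRI preprocessing pathologies. On real data the
absolute accuracies will differ; the structural guarantees (zero-shot
training-set hygiene, null calibration, FWE control) are the transferable
part.

## Numerical choices

* Ridge via SVD (primal) or symmetric eigendecomposition of the
  double-centered gram matrix; eigenvalues clamped at 0; the single-trial
  fold loop runs in compiled code with one factorization per fold shared by
  all six models.
* GCV grid: `mean(spectrum) * 10^seq(-5, 5, length 41)`; degrees of freedom
  include +1 for the intercept; the smallest-GCV grid point wins.
* Tie in the pair rule: exact equality of the distance sums (ties arise from
  identical truths, where the two sums are computed from identical inputs).
* Permutation thresholds: type-1 (order statistic) empirical percentiles, so
  thresholds are reproducible exactly from the stored null values.
* Seeds split hierarchically (master → stage → subject) via
  `sample.int(2^31 - 1)` streams, so every stage can be rerun in isolation;
  full end-to-end determinism is asserted by hash-comparing reports.
* Degenerate inputs have defined behavior throughout: zero-norm coordinate
  vectors are errors in distance computations, an all-clue target warns and
  returns the zero `ALL_NONCLUES` vector, `k` larger than the voxel count
  selects everything with a warning, searchlight radii below the voxel size
  degrade to single-voxel spheres with a warning.

## Problem sizes used in the validation suite

The test suite and the acceptance script exercise the full 60-target /
360-trial design combinatorics at the default D = 300, and run the heavier
multi-subject analyses at reduced sizes chosen to keep the whole suite in a
few minutes on one core: 17 subjects at D = 60 on a 12×12×12 grid for
model-ordering recovery; a 16-target configuration for the 250-iteration
permutation null; 8 subjects, 12 targets and a contiguous blob on a
12×12×12 grid for searchlight localization, with exhaustive (2^8 = 256)
sign flips; and 120 null group simulations for the FWE false-positive rate.
Accuracy-bearing conclusions (orderings, calibration bounds) — not absolute
runtimes — are what these sizes were chosen to support.

## Known limitations

* White voxel noise makes stability selection somewhat easier than on real
  data, where physiological noise is spatially structured.
* The pseudo-t variance smoothing uses the same FWHM as map smoothing by
  default; they are separate parameters if you need them to differ.
* `MIXED_CLUES` requires the generator's donor assignment; real datasets
  must supply a donor column with verified clue-disjointness (the package
  asserts it and errors otherwise).
* The permutation null reuses each fold's GCV strength from the unpermuted
  fit; re-optimizing under every permutation would be conservative in
  principle but is indistinguishable at the grid resolution used and an
  order of magnitude slower.
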