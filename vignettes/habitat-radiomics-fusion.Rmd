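---
title: "Habitat radiomics with multisequence feature fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics with multisequence feature fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitomics)
```

## The problem

High-grade gliomas that look alike on conventional MRI can carry different
genotypes — notably IDH-mutant grade 4 astrocytoma versus IDH-wildtype
glioblastoma (GBM) — with different prognosis and management. habitomics
implements a subregion-based radiomic classification pipeline for this kind
of two-class problem on co-registered multisequence MRI (T1WI, post-contrast
T1WI, T2WI, T2-FLAIR): lesions are partitioned into subregions, a fixed
radiomic feature vector is extracted per subregion per sequence, features
are fused across sequences with a supervised linear projection, and a grid
of selector–classifier models is ranked by cross-validated AUPRC, with the
top models combined into a consensus predictor.

The package operates on pre-aligned volumes: all four sequences of a subject
must share grid shape and voxel spacing, and the package verifies (but never
performs) that alignment. Since real patient volumes cannot ship with the
package, a tumor-phantom generator provides synthetic cohorts with known
geometry and class effects; every quantitative claim in the test suite is
made on phantoms.

## Subregion definitions

**Manual algebra.** From the three delineated compartments — non-enhanced
tumor (nET), enhanced tumor (ET) and peritumoral edema (pTE) — Boolean
algebra defines seven subregions: `VOI_1` (nET), `VOI_2` (ET), `VOI_3`
(pTE), and the unions `VOI_12`, `VOI_13`, `VOI_23`, `VOI_123`. When raw
masks overlap, voxels are resolved by the precedence ET > nET > pTE before
the algebra; enhancement is the most specific radiographic signal, so it
wins contested voxels. Rater agreement is quantified by the Dice
coefficient; at Dice ≥ 0.9 the consensus is the voxelwise intersection,
below it the pair is flagged for manual adjudication. Dice of two empty
masks is defined as 1 (vacuous agreement).

**Habitats.** Within the whole-lesion mask `VOI_123`, the post-contrast T1
and T2-FLAIR intensities are min-max normalized per subject to [0, 1] and
each is split into "high" and "low" by two-class K-means. The four AND
combinations form the habitats H1 (high/high), H2 (high T1WI+C, low FLAIR),
H3 (low T1WI+C, high FLAIR) and H4 (low/low), which partition `VOI_123`
exactly. All 15 non-empty unions (`H_1` … `H_1234`) are candidate
subregions; together with the manual seven, each subject contributes 22
candidate subregions per sequence.

Two numerical choices deserve a note. Min-max normalization (rather than
z-scoring) keeps the high/low split on a bounded, subject-comparable scale;
a constant in-mask signal maps to zero and is flagged degenerate. And the
two-class K-means is solved *exactly*: in one dimension the optimal 2-means
partition is a split of the sorted values, so the package enumerates all
splits with prefix sums instead of iterating Lloyd's algorithm from a
heuristic start. This is deterministic without a seed, immune to local
optima, and testably equal to the exhaustive-split oracle. Values equal to
the split boundary join the low cluster.

## The 109-feature radiomic vector

Each (subregion, sequence) pair yields 19 first-order, 15 shape and 75
texture features (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM), following
the standard (IBSI-consistent) formulas. Conventions:

* **Discretization**: fixed bin count, default 32 bins over the in-mask
  range. This makes all texture features exactly invariant to affine
  intensity rescaling, which is the right default for arbitrary-scale
  synthetic and normalized data; fixed bin width is available.
* **Texture geometry**: 13 unique 3-D direction offsets at distance 1,
  symmetric co-occurrence, matrices summed (merged) over directions before
  feature computation. Run and zone statistics likewise accumulate over
  directions; GLSZM zones use 26-connectivity; GLDM dependence counts the
  center voxel plus its equal-level 26-neighbors (alpha = 0).
* **Shape**: surface area and mesh volume come from an interpolating
  marching-tetrahedra isosurface (level 0.5) of the occupancy field after a
  separable binomial [1, 2, 1]/4 smoothing. Smoothing removes the
  voxelization faceting that would otherwise inflate surface area by tens of
  percent; a rasterized sphere of radius 10 voxels measures within about 1%
  of its analytic area and volume, giving sphericity ≈ 0.99. Masks too small
  or thin for the smoothed field to cross the iso-level fall back to meshing
  the raw binary field. Diameters use voxel-center coordinates of boundary
  voxels; axis lengths are 4·sqrt(eigenvalue) of the voxel-coordinate
  covariance. `SphericalDisproportion` (the reciprocal of sphericity) is
  kept in the 15-member list alongside the modern 14 shape features.
* **Degenerate inputs**: skewness and kurtosis of a constant signal are 0;
  a single gray level after discretization yields the analytic single-level
  limits (GLCM contrast 0, joint energy 1, MCC 1, …) with a warning; empty
  subregions are excluded from cohort tables with a logged exclusion rather
  than an error.

Shape features depend only on the mask, so cohort extraction computes them
once per subject and shares them across the four sequences.

## Fusing features across sequences

For each feature *j*, the values observed on the *m* chosen sequences form
an n × m matrix (standardized per sequence with training statistics).
Fusion learns a unit-norm direction **w** maximizing the Fisher criterion —
between-class scatter over within-class scatter of the projection — with the
within-class scatter regularized by λI, λ = 10⁻³·trace(S_w)/m. For two
classes the optimum is closed-form, w ∝ (S_w + λI)⁻¹(μ₁ − μ₂). The fused
value provably attains a Fisher ratio at least as large as any single
sequence's coordinate (tested exactly), and in particular can recover class
signal that lives only in a combination of sequences, e.g. their sum. The
projection is per-feature with fused dimension r = 1 by default (r > 1 is
supported through the generalized eigenproblem, but with two classes the
between-class scatter has rank 1, so r = 1 is the meaningful choice); a
between-class-only variant ("between") is available behind a switch. Signs
are fixed (first nonzero weight positive) so runs are bit-reproducible.
Zero-variance features pass through as constant zero with a warning.

Crucially, fusion is supervised, so inside cross-validation it is fitted on
the training fold only; applying it uses stored training constants and never
touches labels of the applied set. An instrumented test perturbs held-out
labels and asserts that no fused feature, selection or prediction changes.

## Feature selection

Six selectors operate on the fused table. Five are greedy forward filters
under mutual-information criteria — MIM (relevance only), JMI (joint MI with
each selected feature), CMIM (minimal conditional relevance), DISR (joint MI
normalized by joint entropy), ICAP (relevance minus positive interaction
penalty) — and SPEC ranks all features by consistency with the spectral
structure of an RBF sample-similarity graph (normalized-Laplacian variant,
bandwidth = median pairwise distance). MI is estimated by the plug-in
estimator on equal-frequency bins (default 5), computed via ranks, which
makes the five MI selectors exactly invariant to strictly monotone
transforms of any single feature. On the first pick all five MI criteria
reduce to the relevance argmax (DISR up to its entropy normalization). Ties
break lexicographically by feature name. The number of selected features
defaults to k = 10 per model — a conventional filter-selection size for
cohorts of this scale, configurable.

## The model grid, imbalance and consensus

The grid crosses the 6 selectors with 4 tree-ensemble classifiers:
extremely randomized trees (`ranger`, 300 trees, extratrees splitting),
a depth-wise exact-greedy gradient booster, a histogram gradient booster
(both via `xgboost`), and a leaf-wise histogram gradient booster (xgboost's
lossguide grow policy, 31 leaves — the leaf-wise growth strategy popularized
by LightGBM). Hyperparameters are library defaults with fixed seeds and a
single thread; all 24 specs are evaluated on identical stratified five-fold
splits.

Class imbalance (the phantoms default to 1:4 minority:majority, mirroring a
grade 4 astrocytoma vs GBM cohort) is handled by SMOTE applied to the fused
*training* fold only: synthetic minority samples are convex combinations of
a minority point and one of its k ≤ 5 nearest minority neighbors, balancing
the classes to the majority count.

Specs are ranked by mean AUPRC across folds (ties by mean AUC, then spec
id). AUPRC — average precision, the step-wise integral of the
precision-recall curve — is the primary metric because it is sensitive to
minority-class performance at high prevalence; AUC, accuracy, sensitivity,
specificity, F1 and precision/recall are reported alongside (threshold 0.5,
positive class = the majority GBM, matching the high printed precision at
prevalence near 0.9). The top three specs are fused by AUPRC-proportional
weights into a consensus probability (an equal-weight variant is a config
switch away). Two models are compared by a stratified paired bootstrap of
the AUPRC difference over subjects (2000 replicates, two-sided), a
distribution-free choice that respects the pairing of predictions on the
same subjects.

## The phantom: what it does and does not emulate

A phantom subject is three nested ellipsoids — core (non-enhanced tumor),
rim (enhancing), edema — on an isotropic grid, with per-compartment mean
intensities per sequence and spatially correlated Gaussian noise
(unit-variance field from separable Gaussian smoothing of white noise,
correlation length 2 voxels). The default contrasts guarantee the habitat
structure the pipeline expects: the rim is bright on post-contrast T1 and
dark on FLAIR (→ H2), the edema the reverse (→ H3). Class signal is
injected only into the edema shell — a standardized mean shift
(`edema_effect_size`, default 1.5) plus a variance ratio (default 1.25) —
reflecting the finding that edematous subregions discriminate between the
two genotypes. The defaults of 64³ voxels at 1 mm spacing emulate a
realistic lesion; validation runs use geometrically scaled-down 16³–32³
grids so that whole-cohort studies complete quickly (the test suite runs
cohorts of up to 200 subjects at 24³, and the seeded many-replicate checks
at 16³). These sizes are the package's validation choices; the geometry is
parameterized, not hard-coded.

What passing tests on phantoms do *not* show: robustness to MRI physics
(bias fields, motion, partial volume), registration error, scanner
heterogeneity, or realistic lesion morphology. The phantom's class effect is
a clean location/scale shift in a known compartment; real radiogenomic
signal is weaker and less localized. Phantom results validate the
*machinery* — masks, features, fusion, selection, ranking, anti-leakage —
not clinical performance.

## Null behavior and calibration checks

Two cohort-level checks anchor the pipeline's calibration. With a strong
edema effect (effect size 1.5, 40/160 subjects, seed 42) the top-3 mean
cross-validated AUPRC on the H_34 subregion with four-sequence fusion must
reach at least 0.90. With a zero effect the same statistic must fall inside
a Monte-Carlo null band: the band's lower edge is the 2.5% quantile of a
single uninformative model's mean AUPRC and its upper edge the 97.5%
quantile of the best of 24 independent uninformative models, simulated on
the same labels and folds. The grid's 24 specs are positively correlated
(shared folds and features), so their top-3 mean is stochastically bracketed
by these two extremes; the band is deliberately conservative against either
failure direction. A further stochastic property asserts that with class
signal spread evenly across all four sequences (per-sequence effect 0.45,
12/36 subjects), four-sequence fusion beats the best single sequence in at
least 80% of 20 seeded replicates.

## Known limitations

* The 109-feature list fixes one defensible member set per family
  (19/15/75); other radiomics implementations differ in individual member
  choices and direction-aggregation conventions, so values are comparable
  within this package, not across toolkits.
* SPEC operates on raw (standardized) feature values and is therefore not
  binning-invariant like the five MI selectors.
* GLRLM/GLSZM/GLDM "non-uniformity" and percentage statistics depend on the
  direction-merging convention; values are internally consistent but not
  numerically interchangeable with per-direction-averaged implementations.
* The consensus weights, selected-feature count, MI bin count and SMOTE
  placement are principled defaults rather than uniquely correct choices;
  all are configurable through `grid_config()`.
* r > 1 fused dimensions are supported but untested science: with two
  classes the Fisher problem has a single informative direction.
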