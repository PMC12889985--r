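---
title: "Methods: instance-level cyst quantification and its validation phantoms"
author: "cystquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instance-level cyst quantification and its validation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystquant)
```

## The problem

In autosomal dominant polycystic kidney disease (ADPKD) and polycystic
liver disease, prognosis tracks not only organ volume but cyst-level
biomarkers: the total cyst number (TCN), total cyst volume (TCV), and the
cyst-parenchyma surface area (CPSA), the area over which cysts interface
with functional tissue. Measuring these requires *instance* segmentation —
each cyst individually delineated — which is hard because cysts pack into
dense clusters with shared walls. A practical route is to segment
semantically with an **edge/core decomposition**: each cyst is represented
as an interior *core* plus a one-or-more-voxel *edge* shell, so that
touching cysts remain separable, and a deterministic post-processing step
reconstructs instances. `cystquant` implements that post-processing, the
biomarker computations, and the machinery to evaluate agreement between two
instance segmentations of the same organ.

No patient imaging ships with the package. Instead a seeded phantom
generator produces labeled volumes with exact ground truth, so every
algorithmic claim here is backed by a test the package runs on synthetic
data.

## From semantic mask to instances

`buildInstances()` converts a four-label semantic mask (background,
parenchyma, cyst edge, cyst core) into an instance map in three steps:

1. **Core seeding.** Connected components of core voxels become instance
   seeds (`labelCores()`). The default neighbourhood is 26-connectivity;
   6 and 18 are available. Ids are assigned in column-major first-encounter
   order, so results are reproducible.
2. **Edge attachment.** Each edge voxel joins the *geodesically nearest*
   core (`assignEdges()`): a multi-source Dijkstra expansion over the
   edge-union-core region, with 26-neighbour steps weighted by their
   physical length under the anisotropic voxel spacing. Restricting paths
   to cyst tissue means a cyst can never claim edge voxels across
   parenchyma or background. The edge label exists precisely to separate
   touching cysts, so cores — not watershed basins on intensity — are the
   natural seeds. Distance ties (e.g. a one-voxel septum exactly between
   two cores) go to the smaller core id; ties are detected with an absolute
   tolerance of 1e-9 mm. Cores separated by a one-voxel edge septum stay
   distinct, with the septum split by distance.
3. **Orphans and filtering.** Edge components that reach no core are
   *promoted* to their own instances by default — at coarse slice spacing a
   sub-voxel-core cyst can be all edge, and discarding such components
   would bias TCN downward. `orphanPolicy = "discard"` drops them instead.
   Finally `filterMinVolume()` removes instances strictly below a volume
   threshold. The threshold is 0 by default: the conventional 1-ml
   small-cyst filter is an explicit analysis step, never silent. "Smaller
   than 1 ml" is read strictly, so an exactly-1-ml cyst survives.

With promotion and no filtering, the cyst voxels of the output are exactly
the edge-union-core voxels of the input (a tested conservation property),
and the construction inverts `semanticFromInstances()` exactly for
well-separated cysts with non-empty cores (a tested round-trip property
across seeds).

## Biomarkers

* **TCN** — the number of instances; **TCV** — the sum of per-cyst volumes,
  with each voxel contributing `dx*dy*dz / 1000` ml. Both are invariant
  under relabeling.
* **Surface areas** are estimated by *voxel-face counting*: every face
  whose 6-neighbour does not carry the same instance id is exposed, and is
  weighted by the product of the two spacings orthogonal to its normal.
  Face counting was chosen over marching cubes because it is exact on the
  voxel model, deterministic, and verifiable against a brute-force
  enumeration — the test suite checks it on a corpus of 100 random grids
  up to 8^3, exactly. A cyst-cyst wall counts toward both cysts' totals:
  it is cyst surface and is not outer.
* **CPSA** is the summed total cyst surface minus the *outer* surface, the
  subset of faces adjacent to background (outside the organ mask, where
  the organ is parenchyma plus all cyst voxels; voxels beyond the grid
  count as background). This operationalises the exophytic/endophytic
  distinction: an exophytic cyst bulging beyond the organ contour has its
  background-facing area excluded. CPSA is reported in cm^2, the unit of
  the slope predictor below; liver pipelines, where cysts are endophytic
  and no organ mask is supplied, compute TCN and TCV only.
* **Predicted 8-year eGFR slope** uses the shipped affine predictors
  `slope = -0.792 - 0.007 * TCN` and `slope = -1.075 - 0.002 * CPSA`
  (eGFR units per 8 years, CPSA in cm^2). Coefficients are fields of
  `egfrSlopeModel()`, so a recalibrated or mm^2-based model drops in
  without code changes.

Quantification is always performed in the spacing of the supplied volume;
the package neither resamples nor assumes isotropy.

## Comparing two segmentations

`overlapScores()` gives voxel-level Dice, Jaccard, precision and recall on
the flattened cyst foreground (two empty masks score 1 by convention;
ratios with empty denominators score 0).

Instance-level comparison uses the split/merge correspondence taxonomy.
`buildCorrespondenceGraph()` forms a bipartite graph whose edges are
instance pairs with Dice >= tau (default 0.1, inclusive), and
`classifyCorrespondences()` classifies each connected component by its
(M reference, N prediction) pattern: 1-1 correct detection, 1-0 false
negative, 0-1 false positive, 1-N split, M-1 merge, M-N split-merge. Two
design points matter:

* the same tau gates *every* edge, not only one-to-one candidates — a
  single thresholded graph yields one consistent partition in which every
  instance is counted exactly once, so split-merges cannot be double
  counted as both a split and a merge;
* components are maximal connected subgraphs; no secondary assignment
  optimisation (e.g. Hungarian matching) is performed, because the goal is
  pattern classification, not optimal matching.

A conservation identity — every reference id and every prediction id
appears in exactly one component — is asserted by the tests on every
comparison they run, and counts can never be negative by construction.
`summarizeCases()` aggregates per-case reports into totals, means, SD
(n - 1 denominator; a single case reports SD 0 with `sd_defined = FALSE`)
and ranges; zero-instance cases participate with zero counts.

## Agreement statistics

`percentDifferences()` uses the symmetric Bland-Altman form
`100 * (reference - comparison) / mean(pair)` — the pair mean is the
standard denominator when bias may be proportional to size — with the sign
convention that a larger comparison (model) value gives a *negative*
percentage: negative bias means model overestimation. Cases where both
values are 0 are excluded with a warning. `blandAltman()` reports the mean
difference and `bias +/- 1.96 * SD` limits of agreement (SD with n - 1);
`correlationAndFit()` wraps Pearson's r (with its two-sided p-value) and
OLS of comparison on reference; no multiple-testing correction is applied.
`egfrSlopeAgreement()` maps a paired biomarker series through the slope
predictor before running both analyses — since the map is affine, r is
unchanged, which the tests assert exactly. When biomarkers from several
readers are averaged for comparison, the raw biomarkers are averaged
first, then differenced.

## The phantom generator

`generatePhantom()` emulates the *label geometry* of a polycystic organ CT
segmentation, not the CT itself:

* grid 72 x 72 x 52 voxels at (0.74, 0.74, 3.0) mm — in-plane spacing at
  the median of abdominal CT practice and a deliberately anisotropic slice
  thickness, so all code paths face anisotropy by default;
* a solid ellipsoidal organ (semi-axes 22 x 22 x 70 mm) holding a target
  number of ellipsoidal cysts (default 50) placed by seeded rejection
  sampling, first placed wins; placement keeps at least one empty voxel
  (Chebyshev) between cysts so instances are non-adjacent at default
  settings;
* log-normal cyst radii (`meanlog log(3)` mm, `sdlog 0.55`, clamped to
  1.5-12 mm) putting most cysts below 1 ml with a tail of larger ones —
  the regime in which small cysts dominate detection disagreement, and the
  reason the 1-ml filter path is exercised by default;
* a configurable exophytic fraction (default 0.25) of cysts placed across
  the organ boundary so part of their surface faces background; endophytic
  cysts keep one voxel of parenchymal clearance, so at
  `exophyticFraction = 0` the outer surface is exactly zero (tested);
* `semanticFromInstances()` re-encodes ground truth as edge/core by
  peeling a 6-connected erosion shell of configurable thickness (default
  1 voxel); instances too small to keep a core become all edge.

`degrade()` injects the disagreement modes the taxonomy names — deletes,
spurious adds, merges (relabeling a volume-compatible pair; partners are
restricted to volume ratio <= 10 so the merged instance keeps Dice
>= 2/12 with both originals at tau = 0.1), splits (an axis-aligned plane
through the centroid, accepted only when both halves keep >= 20% of the
voxels, hence Dice >= 1/3 against the original), and one-voxel boundary
jitter — on disjoint instance sets, logging every operation. For such
non-interacting operations the correspondence module recovers the injected
counts category-for-category, which the tests assert exactly for a
50-cyst phantom with 5 deletes, 5 adds, 5 merges and 5 splits.

What the phantoms deliberately do **not** model: CT intensities, noise or
contrast phases (the segmentation network is out of scope — the package
starts from label volumes); anatomically shaped organs; cysts with shared
walls in the *ground truth* (cysts touch only after degradation). Passing
tests therefore demonstrate correctness of the post-processing, biomarker
and evaluation code on known geometry — they are not evidence about the
accuracy of any upstream segmentation model on real CT.

## Numerical and scale choices

* Geodesic distances are sums of 26-neighbour step lengths; equality
  within 1e-9 mm is a tie, broken toward the smaller id, making outputs
  bit-reproducible.
* NIfTI headers store spacing as 32-bit floats; round trips preserve grids
  bit-exactly and spacing to header precision (about 1e-7 relative).
* Test problem sizes — 72 x 72 x 52 phantom grids with up to 50 cysts, a
  100-case random-grid oracle corpus at <= 8^3, ten round-trip seeds at
  48^3 — were chosen so the full suite completes in well under a minute
  while still covering every code path at realistic anisotropy; the whole
  suite plus the acceptance script runs comfortably on one CPU.

## Limitations

Promotion of orphan edge components can create instances smaller than any
real cyst; combine with the explicit 1-ml filter when that matters. The
geodesic tie rule is a convention: a septum voxel equidistant between two
cores has no physically correct owner. CPSA's face-count estimator
overestimates the area of smooth surfaces by up to a factor ~1.5 (the
voxelisation bound); since both sides of any comparison use the same
estimator, agreement analyses are unaffected, but absolute CPSA values are
estimator-specific. The eGFR-slope predictors are fixed published linear
models — the package evaluates them, it does not refit them.
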