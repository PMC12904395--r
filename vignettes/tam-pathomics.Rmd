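---
title: "3D pathomic profiling of tumor-associated macrophages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D pathomic profiling of tumor-associated macrophages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macropath)
```

## The problem

Macrophages in lymph nodes change shape, size, marker expression and
spatial organization when a tumor reprograms their microenvironment.
`macropath` quantifies these changes from three-dimensional confocal
images of thick (about 20 µm) tissue sections stained for CD68 (a
pan-macrophage marker, often read as an M1 proxy), CD163 (alternatively
activated, M2 macrophages) and DAPI. Six diagnoses are covered: reactive
lymphadenitis (LA) as the baseline, and five neoplastic entities — CLL,
DLBCL, FL, and the two classical Hodgkin lymphoma subtypes MCcHL and
NScHL.

The pipeline has five computational stages, each with its own module:

1. **Synthetic data** (`make_entity_preset`, `simulate_image`,
   `simulate_profile_table`) — seeded generators at two levels, so every
   downstream stage is testable without any imaging data.
2. **Morphometry** (`segment_channel`, `measure_cells`,
   `compute_cell_density`) — 3D segmentation and per-cell shape and
   intensity features.
3. **Cell graphs** (`compute_edge_threshold`, `build_cell_graph`,
   `graph_features`) — geometric unit-disk graphs over cell centroids
   and their spectral/efficiency features.
4. **Profiles** (`assemble_profile`, `read_profile_table`) — the
   24-feature per-image pathomic profile.
5. **Statistics** (`prototype_all`, `run_diversity`,
   `feature_attribution`) — feature-wise Mann-Whitney prototyping
   against LA, and repeated-split bagged-tree diversity classification.

## The 24-feature pathomic profile

Each image is summarized by exactly 24 features
(`feature_registry()`): one cell density per marker (summed cell volume
divided by image volume), four distribution features of the pooled cell
graph (mean degree, local communication efficiency, Estrada index,
isolated-cell count), and per-marker medians of nine per-cell features
(volume, surface, sphericity, prolate and oblate ellipticity, major
axis length, DAPI and own-marker mean intensity, antigen density).
Medians use the usual convention: even counts average the two central
values. A marker with no cells in an image contributes missing
morphology medians — never zeros — and a density of 0.

The count 24 pins down one reading of the feature table: the four graph
features and the two densities are shared per image, and only the nine
morphology features are duplicated per marker (2 + 4 + 2 × 9 = 24).
Consequently the cell graph is built over *both* markers pooled, not one
graph per marker.

## Morphometry: estimators and numerical choices

**Segmentation.** Per channel, a threshold (Otsu on the intensity
histogram by default, or a fixed value) defines foreground; connected
components under 26-connectivity become cells; objects below
`min_volume_um3` (default 65 µm³, a ~5 µm sphere) are removed as debris.
Touching cells are deliberately not split by a watershed: confluent
staining produces merged objects in surface-based commercial pipelines
too, and the synthetic generator reproduces this by resolving — but not
fully eliminating — overlaps.

**Volume** is voxel count × voxel volume, exactly.

**Surface area** uses a normal-weighted exposed-face estimator: every
voxel face between foreground and background contributes its physical
face area times |n·e|, where n is the local unit surface normal
estimated from a Gaussian-smoothed copy of the mask (smoothing scale
1.5 voxels of the coarsest axis) and e the face direction. Plain
voxel-face counting overestimates a sphere's area by roughly 50% and
would corrupt sphericity; the weighted estimator is exact for
axis-aligned planes, consistent for tilted ones, and in the test suite
reproduces a digital ball's area to well under 1% and the cube's
closed-form sphericity (π/6)^(1/3) ≈ 0.806 within the stated 0.05
tolerance. It is spacing-aware, so anisotropic z-steps are handled.

**Shape.** The second central moment tensor of the voxel centres is
eigen-decomposed; under the uniform-ellipsoid relation the principal
semi-axes are √(5λᵢ), sorted a ≥ b ≥ c; the major axis length is 2a.
Sphericity is π^(1/3)(6V)^(2/3)/A. The profile's "cigar-shapedness" and
"disc-shapedness" have no standard closed form, so the package defines

* prolate (cigar): 2(a² − b²) / (2a² + b² + c²),
* oblate (disc): 2(b² − c²) / (a² + 2b² + c²),

both in [0, 1), zero for a sphere; the functions are arguments of
`measure_cells()`, so an alternative convention can be swapped in
without touching callers. Objects thinner than two voxels along every
axis get missing shape features rather than misleading numbers.

**Intensity.** Means are raw (no background subtraction; whether the
original analysis subtracted background is unknowable, so the simpler
convention is used and stated). Antigen density is the own-channel
intensity sum over the cell's voxels divided by its surface — a proxy
for expression per membrane area. The profile's intensity features are
read as own-marker means; the centroid is the unweighted mask centroid
so graph distances reflect positions, not staining brightness.

## Cell graphs

The graph is a geometric unit-disk graph: one node per cell (both
markers), an edge whenever the centroid distance is at most an
image-specific threshold — the median major axis length of all
macrophages in that image. The disk is closed (distance equal to the
threshold is an edge), the standard unit-disk convention. Above 400
cells a spatial grid accelerates neighbour search; the test suite
checks it against the brute-force double loop for exact equality.

Features: mean degree 2|E|/n; isolated count; the Estrada index
Σᵢ exp(λᵢ) over adjacency eigenvalues (a spectral compactness measure,
n for an edgeless graph, computed with a dense symmetric solver and
cross-checked against trace(expm(A)) in tests); and communication
efficiency. The profile names this feature "local" while describing the
global mean inverse shortest path; both readings are implemented —
the default follows the name (Latora–Marchiori local efficiency:
average over nodes of the mean inverse shortest-path length inside each
node's neighbour-induced subgraph, 0 for fewer than two neighbours) and
`efficiency = "global"` follows the description. Note that igraph's
`local_efficiency()` is a third variant (paths may leave the
neighbourhood), which is why the test oracle is a direct brute-force
computation. A config switch likewise restricts the Estrada index to
the largest connected component for the strict "connected cells"
reading; the default uses the full graph.

## Prototyping

Each neoplastic entity is compared to LA feature by feature with the
two-sided Mann-Whitney U test; a feature is coded increased/decreased
when p < α (default 0.05) with the sign of the median difference,
unchanged otherwise. Choices that matter:

* U counts x > y pairs with ties counted half (mid-ranks).
* p-values are exact (from the U distribution) for min(n, m) ≤ 8
  without ties; otherwise the normal approximation with tie-corrected
  variance and a 0.5 continuity correction — matching
  `wilcox.test(exact = FALSE, correct = TRUE)` to 10⁻⁶, which the test
  suite uses as the independent reference.
* No multiple-testing correction by default, reproducing the p < 0.05
  convention of the original analysis; Benjamini–Hochberg is available
  behind `p_adjust = "BH"`.
* All images of a case enter this stage. Multiple sections of one case
  are not independent; the result object carries this caveat in its
  `notes` field rather than silently ignoring it.

## Diversity classification

For the multiclass analysis the table is first downscaled to one
profile per case — the first section, resolved as the natural-order
minimum of `image_id` (so "s2" precedes "s10"), overridable via an
explicit ordering column — to avoid overrepresenting multi-image cases.
Then, over `n_iterations` (default 1000) random splits:

* **Stratified 75/25 splits.** Per class, the training count is
  round-to-nearest of 0.75 n (half rounds up), clamped so every class
  keeps at least one training and one test case. Stratification is the
  default (the alternative, a single global split redrawn until every
  class reaches training, is available).
* **Bagged decision trees.** The ensemble is `randomForest` with
  `mtry = p` — bootstrap-sampled unpruned trees with *all* features
  available at every split, i.e. bagging rather than a random forest.
  The original hyperparameters are unreported; the defaults here are
  100 trees, node size 1, no depth cap, all exposed in
  `diversity_config()`.
* **Imputation.** Missing features (e.g. images without CD163 cells)
  are filled with training-split medians only; the test fold never
  influences them. This boundary is unit-tested with a sentinel
  outlier planted in the test fold.
* **Aggregation.** Per-(true, predicted) counts accumulate over all
  iterations; each confusion cell is the percentage of that true
  class's test appearances, so rows sum to 100 exactly and counts are
  recoverable from percentages.
* **ROC/AUC.** One-vs-rest scores are the ensemble's vote fractions.
  Curves are vertically averaged on a fixed 101-point FPR grid; the
  per-class AUC is the mean of per-iteration trapezoidal AUCs (computed
  via the rank identity).

Feature attribution uses a model trained on the full downscaled table
without splitting: a model-agnostic permutation explainer that permutes
one feature at a time and reports the mean absolute change of the
predicted class probabilities (a constant feature scores exactly 0).

A note on null behaviour: with permuted labels on a *fixed* data draw,
repeated splitting converges to that draw's accidental structure, not
to 16.7% — individual classes can sit several points above or below
chance however many iterations are run. Chance-level checks therefore
average over independent permutations; that is how the acceptance
checks evaluate the null.

## The synthetic generator

The generator defines the study conditions for every test. Its default
cohort copies the study composition — 82 cases, 160 images: LA 20/44,
CLL 15/25, DLBCL 15/28, FL 11/20, MCcHL 9/16, NScHL 12/27 — with images
distributed as evenly as possible over the cases of an entity.

**Direction codes.** Each entity preset carries a ±1/0 code per
feature, reconstructed from the qualitative entity descriptions: CLL —
fewer, smaller, more spherical CD68⁺ cells with fewer contacts and more
isolated cells; DLBCL — enlarged CD68⁺ cells with lower surface antigen
density at constant density, highly interconnected; FL — reduced
density of both markers and sparser graphs with unaltered morphology;
MCcHL/NScHL — increased CD68⁺ density, compact highly connected
arrangements, smaller CD163⁺ cells, MCcHL additionally with enlarged,
less antigen-dense CD68⁺ surfaces; reduced DAPI intensity everywhere
except CLL. Where geometry couples features, the codes are made
consistent (a surface increase at fixed volume implies lower sphericity
and higher ellipticity — sphericity is a function of V and A only).

**Effect magnitudes are free parameters.** The source material reports
directions, not sizes. One unit of `effect_scale` shifts a coded
feature by 0.6 within-entity standard deviations on its transformed
scale — chosen once as a moderate, realistic shift — and `effect_scale
= 0` reproduces LA exactly. Synthetic effect sizes must not be read as
estimates of the real data.

**Profile level.** Features are drawn independently per image on
transformed scales: log-normal for positive features, logit-normal for
unit-interval features, and a log-linked Poisson for the isolated-cell
count. A case-level random effect (half the within-entity SD, with the
image-level residual scaled to keep the total SD fixed) correlates
images of one case, which is what makes the per-case downscaling stage
meaningful.

**Image level.** The default geometry is 171 × 171 × 20 µm — consistent
with a 1024 × 1024 px field at 0.167 µm/px and the 18–33 µm section
range — at 0.5 µm isotropic spacing (a deliberate computational choice;
spacing is configurable and all morphometry is spacing-aware). Cells
are random-orientation triaxial ellipsoids (a = cq, b = c√q with a
log-normal volume and a shifted axis ratio q ≥ 1), placed by a
Matérn-style cluster process: Poisson parents, offspring uniform in a
ball whose radius shrinks for the "compact" Hodgkin presets. The cell
count is Poisson at the programmed rate and positions are assigned to
parents, so realized counts match the programmed mean in distribution.
Overlap is suppressed by rejection sampling on centre distances
(equivalent-sphere radii, 20 retries) and residual overlaps are left to
merge at segmentation time, as confluent staining does. Marker channels
get each cell's intensity; DAPI gets a scaled-down nucleus per cell
plus background lymphocyte nuclei; all channels receive additive
Gaussian noise (background 10, SD 4 a.u. by default). One global seed
fans out into per-image child seeds via a documented 31-bit hash
(`child_seed`), so cohorts are reproducible image by image.

**What the generator does not emulate:** anatomical B/T-zone/medulla
architecture, autofluorescence and quenching chemistry, partial-volume
and PSF blur, z-dependent attenuation, and real staining heterogeneity.
Passing tests on synthetic data therefore demonstrate correctness of
the estimators and statistics under controlled conditions, not
performance on real confocal material.

## Problem sizes and runtime choices

The shipped analyses and checks use sizes chosen to run in seconds to a
few minutes on one core: validation images of 100 × 100 × 20 µm at
0.5 µm spacing, the full 82-case profile-level cohort for the
statistical stages, 200 split iterations for classification sanity
checks (the full protocol uses 1000), and 2000 replicates for the
type-I-error calibration of the rank test. The numbered scripts under
`analysis/` run the same stages at the same sizes and write their
tables under `results/`.

## Known limitations

* Reproduction of the printed per-class accuracies requires the study's
  deposited per-image table, which is not redistributable with the
  package; the reproduction check documents where to place it and
  fails visibly otherwise.
* Merged touching cells are measured as single objects by design;
  heavily confluent images bias per-cell medians upward in volume.
* Ensemble hyperparameters of the original classifier are unreported;
  agreement on real data is expected only within stochastic tolerance.
* The Mann-Whitney stage treats images of one case as independent;
  the case-level random effect in the generator quantifies how
  optimistic that makes p-values, but the stage mirrors the original
  analysis rather than fitting a hierarchical model.
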