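# macropath

3D pathomic profiling of tumor-associated macrophages (TAMs) in human
lymph node tissue.

Tumors reprogram the macrophages of their microenvironment, and the
reprogramming leaves measurable traces: cell bodies grow or shrink,
become spherical or elongated, express more or less surface antigen,
and pack together or disperse. `macropath` quantifies these traces from
three-dimensional confocal images of thick tissue sections stained for
CD68 (pan-macrophage / M1 proxy), CD163 (M2 macrophages) and DAPI, and
asks two questions of the resulting per-image feature vectors:

* **Prototyping** — which features of each lymphoma entity (CLL, DLBCL,
  FL, MCcHL, NScHL) differ significantly from reactive lymphadenitis
  (LA)? Feature-wise two-sided Mann-Whitney U tests at p < 0.05, coded
  as increased / decreased / unchanged.
* **Diversity** — how unique is each entity's overall pathomic
  signature? A bagged decision-tree classifier over many stratified
  75/25 train-test splits (default 1000), summarized as an aggregated
  confusion matrix, averaged one-vs-rest ROC/AUC curves, and
  permutation-based feature attribution.

It is written for computational pathology and bioimage-analysis
researchers who want the full pipeline — or any single stage — as
tested, seeded, reusable functions.

## The pathomic profile

Every image is reduced to 24 features. Per marker m ∈ {CD68, CD163}:
the cell density (Σ cell volume / image volume) and the per-image
medians of nine per-cell features — volume V, surface A, sphericity
π^⅓(6V)^⅔ / A, prolate and oblate ellipticity from the principal
semi-axes a ≥ b ≥ c of the inertia tensor (semi-axis = √(5λ)), major
axis length 2a, DAPI and own-marker mean intensity, and antigen density
(Σ intensity / A). Shared across markers: four features of the
geometric **unit-disk cell graph**, in which two cells are joined iff
their centroid distance is at most the image-specific median major axis
length — mean degree 2|E|/n, isolated-cell count, the Estrada index
Σᵢ e^{λᵢ} over the adjacency spectrum (3D packing), and local
communication efficiency (mean inverse shortest-path length within each
node's neighbour subgraph).

A seeded synthetic generator produces both voxel-level images (ellipsoid
cells, Matérn-style clustering, Gaussian noise, full ground truth) and
profile-level cohorts for all six diagnoses, with entity presets that
encode the direction of every programmed alteration — so the whole
pipeline is testable end to end without any imaging data.

## Worked example

```r
library(macropath)

# synthetic study cohort: 82 cases / 160 images, six diagnoses
cohort <- simulate_cohort_profiles(effect_scale = 1, seed = 1)

# stage 1: feature-wise prototyping against reactive tissue
pm <- prototype_all(cohort, reactive_label = "LA")
pm
#> <prototype_matrix> 5 entities x 24 features vs 'LA' (alpha 0.05, none)
#> significant cells: 17 increased, 28 decreased, 75 unchanged
as.matrix(pm, "direction")[, c("cd68_density", "cd68_volume",
                               "average_connections", "isolated_count")]
#>       cd68_density cd68_volume average_connections isolated_count
#> CLL              0           0                  -1              1
#> DLBCL            0           1                   1              0
#> FL              -1           0                  -1              1
#> MCcHL            1           0                   1             -1
#> NScHL            0           0                   1              0

# stage 2: diversity classification (downscales to one image per case)
dr <- run_diversity(cohort, diversity_config(n_iterations = 200, seed = 1))
dr
#> <diversity_result> 6 classes, 200 iterations
#> aggregated confusion (% of test appearances per true class):
#>        predicted
#> true      LA  CLL DLBCL   FL MCcHL NScHL
#>   LA    64.6 14.3   3.4  6.6   2.4   8.7
#>   CLL   40.9 28.7   8.6 19.6   0.1   2.0
#>   DLBCL 17.0  5.4  57.8  4.1   2.8  13.0
#>   FL    30.3 35.5   1.7 30.5   1.5   0.5
#>   MCcHL 29.2  2.0  26.2  0.2  30.5  11.8
#>   NScHL 30.7  5.8  32.5  3.7   8.5  18.8
#> mean one-vs-rest AUC:
#>    LA   CLL DLBCL    FL MCcHL NScHL
#> 0.730 0.764 0.830 0.865 0.799 0.728
```

The direction grid recovers programmed alterations (e.g. DLBCL's
enlarged, better-connected CD68⁺ cells; FL's reduced density with more
isolated cells). In the confusion matrix, rows are true diagnoses and
cells are percentages of that class's test appearances over all splits:
diagonal values are per-entity accuracies, off-diagonal mass shows
which entities share a pathomic signature at this (moderate) synthetic
effect size.

The voxel-level route runs the same stages from raw images:

```r
sim  <- simulate_image(make_entity_preset("LA"),
                       image_geometry(c(100, 100, 20), c(0.5, 0.5, 0.5)),
                       seed = 1)
prof <- image_to_profile(sim$image, list(case_id = "LA_c01",
                                         image_id = "s1", diagnosis = "LA"))
```

The numbered scripts under `analysis/` run the full workflow in order —
`01_simulate.R` (cohort + demo image), `02_morphometry.R` (segmentation
validated against ground truth), `03_prototyping.R`, `04_diversity.R` —
writing their tables under `results/`.

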