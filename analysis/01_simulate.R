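#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohort.
#
# Draws the full profile-level cohort (82 cases / 160 images across the
# six diagnoses, moderate effect scale) and one demonstration 3D voxel
# image with ground truth. Profile table goes to results/; the voxel
# image (binary TIFF) goes to scratch/.

library(macropath)

seed <- 20260930L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cohort <- simulate_cohort_profiles(effect_scale = 1, seed = seed)
write_profile_table(cohort, "results/synthetic_profiles.csv")
cat(sprintf("cohort: %d images over %d cases, %d diagnoses\n",
            nrow(cohort), length(unique(cohort$case_id)),
            length(unique(cohort$diagnosis))))
print(table(cohort$diagnosis))

sim <- simulate_image(make_entity_preset("LA"),
                      image_geometry(c(100, 100, 20), c(0.5, 0.5, 0.5)),
                      seed = seed)
write_voxel_image(sim$image, "scratch/demo_la")
gt <- sim$cells
gt$rotation <- NULL
write.csv(gt, "scratch/demo_la_ground_truth.csv", row.names = FALSE)
cat(sprintf("demo image: %d ground-truth cells (%d CD68+, %d CD163+)\n",
            nrow(gt), sum(gt$marker == "cd68"), sum(gt$marker == "cd163")))
cat("wrote results/synthetic_profiles.csv and scratch/demo_la_*.tif\n")
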