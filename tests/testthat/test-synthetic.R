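test_that("reference preset has no programmed alterations and scale 0 reproduces it", {
  la <- make_entity_preset("LA", 1.0)
  expect_true(all(la$direction_code == 0L))
  for (ent in setdiff(pathomic_entities(), "LA")) {
    null_preset <- make_entity_preset(ent, 0.0)
    expect_equal(null_preset$profile_model$location,
                 la$profile_model$location)
    expect_equal(null_preset$image_params, la$image_params)
  }
})

test_that("entity presets encode the expected alteration directions", {
  cll <- direction_codes("CLL")
  expect_equal(unname(cll[c("cd68_density", "cd68_volume", "cd68_sphericity",
                            "average_connections", "isolated_count")]),
               c(-1L, -1L, 1L, -1L, 1L))
  dlbcl <- direction_codes("DLBCL")
  expect_equal(unname(dlbcl[c("cd68_volume", "cd68_antigen_density",
                              "average_connections", "cd68_density",
                              "cd163_density")]),
               c(1L, -1L, 1L, 0L, 0L))
})

test_that("unknown entity labels are rejected by name", {
  expect_error(make_entity_preset("HL", 1.0), "HL")
  expect_error(make_entity_preset("LA", -1), "non-negative")
})

test_that("preset generative shifts agree in sign with every direction code", {
  for (ent in setdiff(pathomic_entities(), "LA")) {
    preset <- make_entity_preset(ent, 1.0)
    la <- make_entity_preset("LA", 1.0)
    shift <- preset$profile_model$location - la$profile_model$location
    code <- preset$direction_code[preset$profile_model$feature]
    expect_equal(unname(sign(shift)), unname(as.numeric(code)),
                 info = paste("entity", ent))
  }
})

test_that("profile tables are deterministic and honour the cohort layout", {
  presets <- list(LA = make_entity_preset("LA"), CLL = make_entity_preset("CLL"))
  a <- simulate_profile_table(presets, n_cases = 4, images_per_case = 3, seed = 11)
  b <- simulate_profile_table(presets, n_cases = 4, images_per_case = 3, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 4 * 3)
  expect_identical(names(a), profile_columns())

  # zero cases for one entity: absent from output, no error
  z <- simulate_profile_table(presets, n_cases = c(LA = 3, CLL = 0),
                              images_per_case = 1, seed = 2)
  expect_false("CLL" %in% z$diagnosis)
  expect_equal(nrow(z), 3)

  expect_error(
    simulate_profile_table(presets, 3, 1, seed = 1, features = "not_a_feature"),
    "not_a_feature")
})

test_that("default synthetic cohort mirrors the study composition", {
  spec <- default_cohort_spec()
  expect_equal(sum(spec$n_cases), 82L)
  expect_equal(sum(spec$n_images), 160L)
  co <- simulate_cohort_profiles(effect_scale = 1, seed = 4)
  expect_equal(nrow(co), 160L)
  expect_equal(length(unique(co$case_id)), 82L)
  counts <- table(co$diagnosis)
  expect_equal(as.integer(counts[spec$entity]), spec$n_images)
})

test_that("identical LA presets for all labels give null feature differences", {
  presets <- stats::setNames(
    lapply(1:2, function(i) make_entity_preset("LA")), c("LA", "XX"))
  tab <- simulate_profile_table(presets, n_cases = 10, images_per_case = 2,
                                seed = 31)
  p <- vapply(feature_registry(), function(f) {
    mann_whitney_u(tab[[f]][tab$diagnosis == "XX"],
                   tab[[f]][tab$diagnosis == "LA"])$p
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.90)
})

test_that("coded feature medians move in the programmed direction", {
  presets <- list(LA = make_entity_preset("LA"),
                  CLL = make_entity_preset("CLL", 3),
                  MCcHL = make_entity_preset("MCcHL", 3))
  tab <- simulate_profile_table(presets, n_cases = 40, images_per_case = 2,
                                seed = 17)
  for (ent in c("CLL", "MCcHL")) {
    code <- direction_codes(ent)
    for (f in names(code)[code != 0L]) {
      delta <- stats::median(tab[[f]][tab$diagnosis == ent]) -
        stats::median(tab[[f]][tab$diagnosis == "LA"])
      expect_equal(sign(delta), as.numeric(code[[f]]),
                   info = paste(ent, f))
    }
  }
})

test_that("voxel images are reproducible and carry one ground-truth row per cell", {
  geom <- image_geometry(c(50, 50, 12), c(0.5, 0.5, 0.5))
  preset <- make_entity_preset("LA")
  a <- simulate_image(preset, geom, seed = 5)
  b <- simulate_image(preset, geom, seed = 5)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$cells[, setdiff(names(a$cells), "rotation")],
                   b$cells[, setdiff(names(b$cells), "rotation")])
  # semi-axes sorted, centres inside bounds
  expect_true(all(a$cells$a_um >= a$cells$b_um & a$cells$b_um >= a$cells$c_um))
  expect_true(all(a$cells$x_um >= 0 & a$cells$x_um <= 50))
  expect_true(all(a$cells$z_um >= 0 & a$cells$z_um <= 12))
})

test_that("an expected-zero-cell preset yields a noise-only image", {
  preset <- make_entity_preset("LA")
  for (m in pathomic_markers()) {
    preset$image_params$markers[[m]]$rate_per_1e5_um3 <- 1e-9
  }
  sim <- simulate_image(preset, image_geometry(c(30, 30, 10), rep(0.5, 3)),
                        seed = 3)
  expect_equal(nrow(sim$cells), 0L)
  expect_lt(max(sim$image$channels$cd68),
            preset$image_params$noise$background + 6 * preset$image_params$noise$sd)
})

test_that("unresolvable voxel spacing is rejected", {
  expect_error(
    simulate_image(make_entity_preset("LA"),
                   image_geometry(c(50, 50, 20), c(6, 6, 6)), seed = 1),
    "unresolvable")
})

test_that("realized cell counts follow the programmed Poisson mean", {
  geom <- image_geometry(c(60, 60, 15), c(0.5, 0.5, 0.5))
  preset <- make_entity_preset("LA")
  v_img <- prod(geom$size_um)
  mu <- (preset$image_params$markers$cd68$rate_per_1e5_um3 +
           preset$image_params$markers$cd163$rate_per_1e5_um3) * v_img / 1e5
  n_seeds <- 20
  counts <- vapply(seq_len(n_seeds), function(s) {
    nrow(simulate_image(preset, geom, seed = 100 + s)$cells)
  }, numeric(1))
  # mean of n_seeds Poisson draws: within 3 sd of the programmed mean
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n_seeds))
})

test_that("written and re-read voxel images round-trip", {
  sim <- simulate_image(make_entity_preset("LA"),
                        image_geometry(c(30, 30, 8), rep(0.5, 3)), seed = 9)
  prefix <- file.path(withr::local_tempdir(), "img")
  write_voxel_image(sim$image, prefix)
  back <- read_voxel_image(prefix)
  expect_equal(back$spacing_um, sim$image$spacing_um)
  for (ch in names(sim$image$channels)) {
    expect_lt(max(abs(back$channels[[ch]] - sim$image$channels[[ch]])) /
                max(sim$image$channels[[ch]]), 1e-6)
  }
})
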