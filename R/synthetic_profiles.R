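#' Study cohort layouts for the synthetic generator
#'
#' `default_cohort_spec()` mirrors the study composition: 82 cases with
#' 160 images over six diagnoses — LA 20 cases / 44 images, CLL 15/25,
#' DLBCL 15/28, FL 11/20, MCcHL 9/16, NScHL 12/27. Images are distributed
#' over the cases of an entity as evenly as possible (remainders go to the
#' first cases). `fast_cohort_spec()` is a reduced layout (4 cases x 2
#' images per entity) for smoke tests.
#'
#' @return Tibble with columns `entity`, `n_cases`, `n_images`.
#' @export
default_cohort_spec <- function() {
  tibble::tibble(
    entity   = pathomic_entities(),
    n_cases  = c(20L, 15L, 15L, 11L, 9L, 12L),
    n_images = c(44L, 25L, 28L, 20L, 16L, 27L))
}

#' @rdname default_cohort_spec
#' @export
fast_cohort_spec <- function() {
  tibble::tibble(entity = pathomic_entities(),
                 n_cases = 4L, n_images = 8L)
}

# per-case image counts for one entity: as even as possible
images_per_case_counts <- function(n_cases, n_images) {
  if (n_cases == 0L) return(integer(0))
  base <- n_images %/% n_cases
  extra <- n_images %% n_cases
  base + as.integer(seq_len(n_cases) <= extra)
}

#' Draw pathomic-profile tables directly from entity presets
#'
#' The fast simulation path: per-image 24-feature profiles are sampled
#' from each preset's shifted feature distributions without rasterizing
#' any voxel data. Features are drawn on a transformed scale (log for
#' positive features, logit for unit-interval features, a log-linked
#' Poisson for the isolated-cell count) with a case-level random effect
#' (SD = half the within-entity SD) shared by all images of a case, so
#' that images of one case are correlated as in real serial sections.
#'
#' @param presets named list of [make_entity_preset()] objects; names are
#'   used as the diagnosis labels of the output.
#' @param n_cases integer vector (recycled or named by preset) of cases
#'   per entity; an entity with 0 cases is absent from the output.
#' @param images_per_case images per case (single value or named by preset).
#' @param seed integer seed; identical seeds give identical tables.
#' @param features features to generate (default: the full registry);
#'   requesting a feature outside the registry is an error.
#' @return Tibble in [profile_columns()] order, one row per image.
#' @export
simulate_profile_table <- function(presets, n_cases, images_per_case = 2L,
                                   seed = 1L, features = feature_registry()) {
  stopifnot(is.list(presets), length(presets) >= 1)
  if (is.null(names(presets)) || any(names(presets) == "")) {
    stopf("presets must be a named list (names = diagnosis labels)")
  }
  unknown <- setdiff(features, feature_registry())
  if (length(unknown)) {
    stopf("feature(s) missing from registry: %s", paste(unknown, collapse = ", "))
  }
  labels <- names(presets)
  n_cases <- rep_named(n_cases, labels)
  images_per_case <- rep_named(images_per_case, labels)

  withr::with_seed(child_seed(seed, "profile_table"), {
    rows <- list()
    for (lab in labels) {
      if (n_cases[[lab]] == 0L) next
      model <- presets[[lab]]$profile_model
      model <- model[model$feature %in% features, , drop = FALSE]
      for (ci in seq_len(n_cases[[lab]])) {
        case_id <- sprintf("%s_c%02d", lab, ci)
        case_eff <- stats::rnorm(nrow(model), 0, 0.5 * model$sd)
        for (ii in seq_len(images_per_case[[lab]])) {
          latent <- model$location + case_eff +
            stats::rnorm(nrow(model), 0, sqrt(0.75) * model$sd)
          value <- back_transform(latent, model$transform)
          row <- stats::setNames(as.list(value), model$feature)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            case_id = case_id, image_id = sprintf("s%d", ii),
            diagnosis = lab, !!!row)
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    missing <- setdiff(features, names(out))
    for (f in missing) out[[f]] <- NA_real_
    out[, c("case_id", "image_id", "diagnosis", features)]
  })
}

rep_named <- function(x, labels) {
  if (!is.null(names(x))) {
    miss <- setdiff(labels, names(x))
    if (length(miss)) stopf("missing entries for: %s", paste(miss, collapse = ", "))
    return(as.list(x[labels]))
  }
  stats::setNames(as.list(rep_len(x, length(labels))), labels)
}

back_transform <- function(latent, transform) {
  out <- numeric(length(latent))
  for (i in seq_along(latent)) {
    out[i] <- switch(transform[i],
      log   = exp(latent[i]),
      logit = inv_logit(latent[i]),
      count = stats::rpois(1L, exp(latent[i])),
      stopf("unknown transform '%s'", transform[i]))
  }
  out
}

#' Simulate the full synthetic study cohort at profile level
#'
#' Convenience wrapper building one preset per entity at a common
#' `effect_scale` and drawing a profile table whose per-entity case and
#' image counts follow `spec` exactly.
#'
#' @param effect_scale shift magnitude passed to [make_entity_preset()].
#' @param spec cohort layout, see [default_cohort_spec()].
#' @param seed integer seed.
#' @return Tibble in [profile_columns()] order.
#' @export
simulate_cohort_profiles <- function(effect_scale = 1.0,
                                     spec = default_cohort_spec(),
                                     seed = 1L) {
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    ent <- spec$entity[i]
    counts <- images_per_case_counts(spec$n_cases[i], spec$n_images[i])
    preset <- list(make_entity_preset(ent, effect_scale))
    names(preset) <- ent
    for (u in unique(counts)) {
      idx <- which(counts == u)
      part <- simulate_profile_table(preset, n_cases = length(idx),
                                     images_per_case = u,
                                     seed = child_seed(seed, ent, u))
      # re-number cases so the entity's cases are unique across blocks
      old <- unique(part$case_id)
      part$case_id <- sprintf("%s_c%02d", ent, idx[match(part$case_id, old)])
      rows[[length(rows) + 1L]] <- part
    }
  }
  out <- dplyr::bind_rows(rows)
  out[natural_order(paste(out$case_id, out$image_id, sep = "/")), ]
}
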