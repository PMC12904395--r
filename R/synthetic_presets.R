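#' Direction codes of the entity-specific pathomic alterations
#'
#' For each diagnosis, each of the 24 profile features carries a code:
#' `+1` (increased vs reactive LA), `-1` (decreased) or `0` (unchanged).
#' LA itself is all-zero. The codes encode the qualitative alteration
#' pattern of each entity: CLL — fewer, smaller, more spherical CD68+
#' macrophages with fewer contacts and more isolated cells; DLBCL —
#' enlarged CD68+ cells with reduced surface antigen density at constant
#' cell density, highly interconnected; FL — reduced density of both
#' markers with sparser graphs but unaltered morphology; MCcHL/NScHL —
#' increased CD68+ density and a compact, highly connected arrangement
#' with smaller CD163+ cells, MCcHL additionally with enlarged CD68+
#' surfaces and reduced CD68 antigen expression. All entities except CLL
#' show reduced DAPI intensity. Mechanically coupled features (e.g. a
#' surface increase at constant volume implies reduced sphericity and
#' increased ellipticity) are coded consistently.
#'
#' @param entity one of [pathomic_entities()].
#' @return Named integer vector over [feature_registry()] with values in
#'   `{-1, 0, 1}`.
#' @export
direction_codes <- function(entity) {
  entity <- match.arg(entity, pathomic_entities())
  code <- stats::setNames(integer(length(feature_registry())), feature_registry())
  set <- function(code, ...) {
    v <- c(...)
    bad <- setdiff(names(v), names(code))
    if (length(bad)) stopf("unknown feature in direction table: %s", paste(bad, collapse = ", "))
    code[names(v)] <- as.integer(v)
    code
  }
  switch(entity,
    LA = code,
    CLL = set(code,
      cd68_density = -1, average_connections = -1,
      local_communication_efficiency = -1, estrada_index = -1,
      isolated_count = +1,
      cd68_volume = -1, cd68_surface = -1, cd68_sphericity = +1,
      cd68_ellipticity_prolate = -1, cd68_ellipticity_oblate = -1,
      cd68_major_axis_length = -1, cd68_antigen_density = -1),
    DLBCL = set(code,
      average_connections = +1, local_communication_efficiency = +1,
      estrada_index = +1, isolated_count = -1,
      cd68_volume = +1, cd68_surface = +1, cd68_major_axis_length = +1,
      cd68_intensity_mean_dapi = -1, cd68_intensity_mean_marker = -1,
      cd68_antigen_density = -1, cd163_intensity_mean_dapi = -1),
    FL = set(code,
      cd68_density = -1, cd163_density = -1,
      average_connections = -1, local_communication_efficiency = -1,
      estrada_index = -1, isolated_count = +1,
      cd68_intensity_mean_dapi = -1, cd163_intensity_mean_dapi = -1),
    MCcHL = set(code,
      cd68_density = +1,
      average_connections = +1, local_communication_efficiency = +1,
      estrada_index = +1, isolated_count = -1,
      cd68_surface = +1, cd68_sphericity = -1,
      cd68_ellipticity_prolate = +1, cd68_ellipticity_oblate = +1,
      cd68_major_axis_length = +1, cd68_intensity_mean_dapi = -1,
      cd68_intensity_mean_marker = -1, cd68_antigen_density = -1,
      cd163_volume = -1, cd163_surface = -1, cd163_major_axis_length = -1,
      cd163_intensity_mean_dapi = -1, cd163_antigen_density = -1),
    NScHL = set(code,
      cd68_density = +1,
      average_connections = +1, local_communication_efficiency = +1,
      estrada_index = +1, isolated_count = -1,
      cd68_intensity_mean_dapi = -1,
      cd163_volume = -1, cd163_surface = -1, cd163_major_axis_length = -1,
      cd163_intensity_mean_dapi = -1, cd163_antigen_density = -1))
}

# profile-level generative model for the reactive (LA) baseline:
# per feature a transform ("log", "logit", "count"), a location on the
# transformed scale, and the within-entity sd on that scale.
la_profile_model <- function() {
  f <- function(name, transform, location, sd) {
    tibble::tibble(feature = name, transform = transform,
                   location = location, sd = sd)
  }
  dplyr::bind_rows(
    f("cd68_density",  "log", log(0.025), 0.35),
    f("cd163_density", "log", log(0.012), 0.35),
    f("average_connections", "log", log(3.0), 0.30),
    f("local_communication_efficiency", "logit", logit(0.25), 0.50),
    f("estrada_index", "log", log(800), 0.80),
    f("isolated_count", "count", log(12), 0.35),
    f("cd68_volume",  "log", log(500), 0.25),
    f("cd163_volume", "log", log(350), 0.25),
    f("cd68_surface",  "log", log(380), 0.20),
    f("cd163_surface", "log", log(300), 0.20),
    f("cd68_sphericity",  "logit", logit(0.75), 0.35),
    f("cd163_sphericity", "logit", logit(0.70), 0.35),
    f("cd68_ellipticity_prolate",  "logit", logit(0.15), 0.40),
    f("cd163_ellipticity_prolate", "logit", logit(0.22), 0.40),
    f("cd68_ellipticity_oblate",  "logit", logit(0.12), 0.40),
    f("cd163_ellipticity_oblate", "logit", logit(0.16), 0.40),
    f("cd68_major_axis_length",  "log", log(12.0), 0.15),
    f("cd163_major_axis_length", "log", log(11.5), 0.15),
    f("cd68_intensity_mean_dapi",  "log", log(80), 0.20),
    f("cd163_intensity_mean_dapi", "log", log(80), 0.20),
    f("cd68_intensity_mean_marker",  "log", log(120), 0.20),
    f("cd163_intensity_mean_marker", "log", log(110), 0.20),
    f("cd68_antigen_density",  "log", log(150), 0.25),
    f("cd163_antigen_density", "log", log(130), 0.25))
}

# image-level generative baseline (reactive LA)
la_image_params <- function() {
  list(
    markers = list(
      cd68 = list(rate_per_1e5_um3 = 5, vol_median_um3 = 500,
                  vol_log_sd = 0.35, axis_ratio_mean = 1.7,
                  axis_ratio_log_sd = 0.20, marker_int_mean = 120,
                  marker_int_sd = 20, dapi_int_mean = 80, dapi_int_sd = 12),
      cd163 = list(rate_per_1e5_um3 = 3.5, vol_median_um3 = 350,
                   vol_log_sd = 0.35, axis_ratio_mean = 2.0,
                   axis_ratio_log_sd = 0.20, marker_int_mean = 110,
                   marker_int_sd = 18, dapi_int_mean = 80, dapi_int_sd = 12)),
    spatial = list(process = "matern", parent_rate_per_1e5_um3 = 3,
                   cluster_radius_um = 25),
    noise = list(background = 10, sd = 4))
}

# one unit of effect_scale shifts a coded profile feature by this many
# within-entity standard deviations on its transformed scale
PRESET_SHIFT_SD <- 0.6

#' Construct a diagnosis-specific synthetic preset
#'
#' Returns the generative parameters for one diagnostic entity at both
#' simulation levels: the per-image voxel simulator (cell rates, size,
#' shape, intensity and spatial-clustering parameters) and the direct
#' profile-table sampler (shifted feature distributions). All parameters
#' are the reactive LA baseline shifted in the direction of the entity's
#' [direction_codes()], with the shift magnitude scaled by `effect_scale`
#' (`0` reproduces LA exactly; `1` is a moderate shift of 0.6 within-entity
#' SD per coded feature).
#'
#' @param entity one of [pathomic_entities()].
#' @param effect_scale non-negative multiplier of all programmed shifts.
#' @return An object of class `entity_preset`.
#' @export
make_entity_preset <- function(entity, effect_scale = 1.0) {
  if (!is.character(entity) || length(entity) != 1 ||
      !entity %in% pathomic_entities()) {
    stopf("unknown entity label: '%s' (expected one of %s)",
          paste(entity, collapse = ","), paste(pathomic_entities(), collapse = ", "))
  }
  if (!is.numeric(effect_scale) || length(effect_scale) != 1 ||
      !is.finite(effect_scale) || effect_scale < 0) {
    stopf("effect_scale must be a single non-negative number")
  }
  code <- direction_codes(entity)
  s <- effect_scale

  # profile-level model: shift coded locations by 0.6 sd per unit scale
  model <- la_profile_model()
  model$direction <- code[model$feature]
  model$location <- model$location + model$direction * PRESET_SHIFT_SD * model$sd * s

  # image-level parameters derived from the same codes
  img <- la_image_params()
  for (m in pathomic_markers()) {
    p <- img$markers[[m]]
    cd <- function(feat) code[[paste0(m, "_", feat)]]
    vol_mult <- exp(cd("volume") * 0.25 * s)
    p$vol_median_um3 <- p$vol_median_um3 * vol_mult
    # density ~ rate x volume: compensate so density follows its own code
    p$rate_per_1e5_um3 <- p$rate_per_1e5_um3 * exp(code[[paste0(m, "_density")]] * 0.35 * s) / vol_mult
    # sphericity down <=> axis ratio up (excess ratio scaled to stay >= 1)
    q_mult <- exp(-cd("sphericity") * 0.20 * s)
    p$axis_ratio_mean <- 1 + (p$axis_ratio_mean - 1) * q_mult
    p$marker_int_mean <- p$marker_int_mean * exp(cd("intensity_mean_marker") * 0.25 * s)
    p$dapi_int_mean <- p$dapi_int_mean * exp(cd("intensity_mean_dapi") * 0.20 * s)
    img$markers[[m]] <- p
  }
  gamma <- code[["average_connections"]]
  img$spatial$cluster_radius_um <- img$spatial$cluster_radius_um * exp(-gamma * 0.25 * s)
  img$spatial$parent_rate_per_1e5_um3 <- img$spatial$parent_rate_per_1e5_um3 * exp(-gamma * 0.10 * s)

  preset <- structure(list(entity = entity, effect_scale = effect_scale,
                           direction_code = code, profile_model = model,
                           image_params = img),
                      class = "entity_preset")
  validate_entity_preset(preset)
  preset
}

validate_entity_preset <- function(preset) {
  img <- preset$image_params
  for (m in pathomic_markers()) {
    p <- img$markers[[m]]
    stopifnot(p$rate_per_1e5_um3 > 0, p$vol_median_um3 > 0, p$vol_log_sd > 0,
              p$axis_ratio_mean >= 1, p$marker_int_mean > 0, p$dapi_int_mean > 0)
  }
  stopifnot(img$spatial$cluster_radius_um > 0,
            img$spatial$parent_rate_per_1e5_um3 > 0)
  if (preset$entity == "LA" && any(preset$direction_code != 0L)) {
    stopf("reference entity LA must have all-zero direction codes")
  }
  invisible(preset)
}

#' @export
print.entity_preset <- function(x, ...) {
  nz <- x$direction_code[x$direction_code != 0]
  cat(sprintf("<entity_preset> %s (effect_scale = %g)\n", x$entity, x$effect_scale))
  if (length(nz)) {
    cat("altered features:\n")
    for (i in seq_along(nz)) {
      cat(sprintf("  %-34s %s\n", names(nz)[i], ifelse(nz[i] > 0, "increased", "decreased")))
    }
  } else cat("reference preset: no programmed alterations\n")
  invisible(x)
}
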