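#' Default pipeline configuration
#'
#' A single nested list drives the end-to-end run: which stages execute,
#' the synthetic-cohort layout and simulation level (`"profile"` draws
#' profile tables directly; `"image"` rasterizes voxel images and runs
#' segmentation, morphometry and graph construction per image), the
#' segmentation/graph/prototyping/diversity options, one global seed and
#' the output directory. Serializes to/from a single JSON document;
#' unknown keys are rejected.
#'
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = NULL,
    verbose = FALSE,
    stages = c("simulate", "prototype", "classify"),
    synthetic = list(level = "profile", effect_scale = 1.0, cohort = "default",
                     image = list(size_um = c(60, 60, 15),
                                  spacing_um = c(0.5, 0.5, 0.5))),
    segmentation = list(method = "otsu", min_volume_um3 = 65, connectivity = 26),
    graph = list(efficiency = "local", estrada_scope = "full"),
    prototyping = list(reactive = "LA", alpha = 0.05, p_adjust = "none"),
    diversity = list(n_iterations = 1000L, train_fraction = 0.75,
                     n_trees = 100L, downscale = TRUE, stratified = TRUE)),
    class = "run_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @param cfg a `run_config` list.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_run_config(), cfg, path = "config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# overlay user values onto the default template; unknown keys rejected
merge_config <- function(template, user, path = "config") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) {
    stopf("unknown %s key(s): %s", path, paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      template[[k]] <- merge_config(template[[k]], as.list(user[[k]]),
                                    paste0(path, "$", k))
    } else {
      template[[k]] <- user[[k]]
    }
  }
  template
}

#' Run the pathomic pipeline end to end
#'
#' Executes the selected stages — simulate (profile- or image-level),
#' prototype, classify — writing every intermediate artifact (profile
#' table, prototype grids, confusion/ROC/AUC/attribution tables) plus a
#' JSON manifest with the configuration, effective seeds, artifact MD5
#' hashes and stage timings into `cfg$out_dir`. Idempotent given seed
#' and inputs; any stage failure aborts with the stage name.
#'
#' @param cfg a [default_run_config()]-style configuration.
#' @param profiles optional pre-existing profile tibble (used when the
#'   simulate stage is not selected).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = default_run_config(), profiles = NULL) {
  out_dir <- cfg$out_dir %||% tempfile("macropath_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "macropath",
                   version = as.character(utils::packageVersion("macropath")),
                   config = unclass(cfg), seed = cfg$seed,
                   stages = list(), artifacts = character(0))
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    say("stage %s ...", name)
    res <- tryCatch(fun(), error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      seed = child_seed(cfg$seed, name))
    res
  }
  add_artifact <- function(path) {
    manifest$artifacts <<- c(manifest$artifacts, path)
    path
  }

  if ("simulate" %in% cfg$stages) {
    profiles <- run_stage("simulate", function() {
      spec <- if (identical(cfg$synthetic$cohort, "fast")) fast_cohort_spec()
              else if (identical(cfg$synthetic$cohort, "default")) default_cohort_spec()
              else tibble::as_tibble(cfg$synthetic$cohort)
      if (identical(cfg$synthetic$level, "image")) {
        simulate_cohort_images(spec, cfg)
      } else {
        simulate_cohort_profiles(cfg$synthetic$effect_scale, spec,
                                 seed = child_seed(cfg$seed, "simulate"))
      }
    })
    write_profile_table(profiles, add_artifact(file.path(out_dir, "profiles.csv")))
  } else if (is.null(profiles)) {
    stopf("no profiles: select the simulate stage or pass `profiles`")
  }

  if ("prototype" %in% cfg$stages) {
    pm <- run_stage("prototype", function() {
      prototype_all(profiles, reactive_label = cfg$prototyping$reactive,
                    alpha = cfg$prototyping$alpha,
                    p_adjust = cfg$prototyping$p_adjust)
    })
    for (p in write_prototype(pm, out_dir)) add_artifact(p)
  }

  if ("classify" %in% cfg$stages) {
    dr <- run_stage("classify", function() {
      dcfg <- diversity_config(
        n_iterations = cfg$diversity$n_iterations,
        train_fraction = cfg$diversity$train_fraction,
        n_trees = cfg$diversity$n_trees,
        seed = child_seed(cfg$seed, "classify"),
        downscale = cfg$diversity$downscale,
        stratified = cfg$diversity$stratified)
      run_diversity(profiles, dcfg)
    })
    utils::write.csv(as.data.frame(dr$confusion_counts),
                     add_artifact(file.path(out_dir, "confusion_counts.csv")))
    utils::write.csv(as.data.frame(round(dr$confusion_pct, 4)),
                     add_artifact(file.path(out_dir, "confusion_pct.csv")))
    utils::write.csv(dr$roc, add_artifact(file.path(out_dir, "roc_curves.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(class = names(dr$auc), auc = as.numeric(dr$auc)),
                     add_artifact(file.path(out_dir, "auc.csv")), row.names = FALSE)
  }

  manifest$artifact_md5 <- as.list(tools::md5sum(manifest$artifacts))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$out_dir <- out_dir
  invisible(manifest)
}

# image-level cohort: simulate -> segment -> measure -> graph -> profile
simulate_cohort_images <- function(spec, cfg) {
  geom <- image_geometry(cfg$synthetic$image$size_um,
                         cfg$synthetic$image$spacing_um)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    ent <- spec$entity[i]
    preset <- make_entity_preset(ent, cfg$synthetic$effect_scale)
    counts <- images_per_case_counts(spec$n_cases[i], spec$n_images[i])
    for (ci in seq_along(counts)) {
      for (ii in seq_len(counts[ci])) {
        sim <- simulate_image(preset, geom,
                              seed = child_seed(cfg$seed, ent, ci, ii))
        rows[[length(rows) + 1L]] <- image_to_profile(
          sim$image,
          meta = list(case_id = sprintf("%s_c%02d", ent, ci),
                      image_id = sprintf("s%d", ii), diagnosis = ent),
          segmentation = cfg$segmentation, graph = cfg$graph)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Compute the pathomic profile of one voxel image
#'
#' The per-image pipeline: segment both marker channels, measure all
#' cells, compute per-marker densities, build the pooled unit-disk cell
#' graph with the median-major-axis threshold, extract graph features
#' and assemble the 24-feature profile row.
#'
#' @param image a [voxel_image()].
#' @param meta list with `case_id`, `image_id`, `diagnosis`.
#' @param segmentation,graph option lists as in [default_run_config()].
#' @return One-row profile tibble.
#' @export
image_to_profile <- function(image, meta,
                             segmentation = default_run_config()$segmentation,
                             graph = default_run_config()$graph) {
  cells <- list()
  for (m in pathomic_markers()) {
    lv <- segment_channel(image, m, method = segmentation$method,
                          min_volume_um3 = segmentation$min_volume_um3,
                          connectivity = segmentation$connectivity)
    cells[[m]] <- measure_cells(lv, image)
  }
  all_cells <- dplyr::bind_rows(cells)
  v_img <- image_volume_um3(image)
  densities <- vapply(pathomic_markers(), function(m) {
    compute_cell_density(all_cells, m, v_img)
  }, numeric(1))
  gf <- if (nrow(all_cells) == 0) {
    graph_features(build_cell_graph(empty_cell_table(), 1))
  } else {
    thr <- compute_edge_threshold(all_cells)
    g <- build_cell_graph(all_cells, thr)
    graph_features(g, efficiency = graph$efficiency,
                   estrada_scope = graph$estrada_scope)
  }
  assemble_profile(cells$cd68, cells$cd163, gf, densities, meta)
}

#' Validate pipeline inputs
#'
#' Schema and geometry checks for the three input kinds: `"profiles"`
#' (24-feature table), `"cells"` (per-cell feature table) and `"image"`
#' (a [voxel_image()] or the path prefix of a written one). Returns a
#' human-readable report; a non-empty issue list means failure.
#'
#' @param x object or file path.
#' @param kind one of `"image"`, `"cells"`, `"profiles"`.
#' @return Object of class `validation_report` with `kind`, `issues`, `ok`.
#' @export
validate_inputs <- function(x, kind = c("profiles", "cells", "image")) {
  kind <- match.arg(kind)
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (kind == "profiles") {
    df <- if (is.character(x)) {
      if (!file.exists(x)) stopf("unreadable file: %s", x)
      utils::read.csv(x, check.names = FALSE)
    } else x
    missing <- setdiff(profile_columns(), names(df))
    for (m in missing) add(sprintf("missing required column '%s'", m))
    for (f in intersect(feature_registry(), names(df))) {
      if (!is.numeric(df[[f]]) && !all(is.na(df[[f]]))) {
        add(sprintf("feature column '%s' is not numeric", f))
      }
    }
  } else if (kind == "cells") {
    df <- if (is.character(x)) {
      if (!file.exists(x)) stopf("unreadable file: %s", x)
      utils::read.csv(x, check.names = FALSE)
    } else x
    req <- names(empty_cell_table())
    for (m in setdiff(req, names(df))) add(sprintf("missing cell column '%s'", m))
    if ("volume_um3" %in% names(df) && any(df$volume_um3 <= 0, na.rm = TRUE)) {
      add("non-positive cell volumes")
    }
    if ("marker" %in% names(df) &&
        !all(df$marker %in% pathomic_markers())) {
      add("unknown marker labels")
    }
  } else {
    img <- if (is.character(x)) read_voxel_image(x) else x
    if (!inherits(img, "voxel_image")) {
      add("not a voxel_image")
    } else {
      dims <- lapply(img$channels, dim)
      if (length(unique(lapply(dims, as.integer))) != 1L) {
        add("channels have non-uniform shapes")
      }
      if (any(img$spacing_um <= 0)) add("non-positive voxel spacing")
      for (ch in names(img$channels)) {
        if (any(!is.finite(img$channels[[ch]]))) {
          add(sprintf("channel '%s' has non-finite intensities", ch))
        }
      }
      if (!all(c("cd68", "cd163", "dapi") %in% names(img$channels))) {
        add("expected channels cd68, cd163, dapi")
      }
    }
  }
  structure(list(kind = kind, issues = issues, ok = length(issues) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> kind '%s': %s\n", x$kind,
              if (x$ok) "OK" else sprintf("%d issue(s)", length(x$issues))))
  for (i in x$issues) cat(" -", i, "\n")
  invisible(x)
}
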