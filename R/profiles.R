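# mapping registry morphology feature -> per-cell table column
cell_feature_columns <- function() {
  c(volume = "volume_um3", surface = "surface_um2",
    sphericity = "sphericity", ellipticity_prolate = "ellipticity_prolate",
    ellipticity_oblate = "ellipticity_oblate",
    major_axis_length = "major_axis_length_um",
    intensity_mean_dapi = "intensity_mean_dapi",
    intensity_mean_marker = "intensity_mean_marker",
    antigen_density = "antigen_density")
}

#' Assemble one per-image pathomic profile
#'
#' Combines the per-cell tables of both markers, the graph feature set
#' and the two cell densities into the 24-feature profile row. Per-marker
#' morphology features are the medians over that marker's cells; non-
#' finite per-cell values are excluded from the median (with the excluded
#' count reported via attribute `n_excluded`); a marker without any cells
#' yields missing morphology medians (never zeros) with a density of 0.
#'
#' @param cells_cd68,cells_cd163 tibbles from [measure_cells()]; may be empty.
#' @param gf one-row graph feature tibble from [graph_features()].
#' @param densities named numeric `c(cd68 = ..., cd163 = ...)`.
#' @param meta list with `case_id`, `image_id`, `diagnosis`.
#' @return One-row tibble in [profile_columns()] order.
#' @export
assemble_profile <- function(cells_cd68, cells_cd163, gf, densities, meta) {
  stopifnot(is.list(meta), all(c("case_id", "image_id", "diagnosis") %in% names(meta)))
  if (!all(pathomic_markers() %in% names(densities))) {
    stopf("densities must be named for both markers")
  }
  row <- stats::setNames(as.list(rep(NA_real_, length(feature_registry()))),
                         feature_registry())
  row[["cd68_density"]] <- as.numeric(densities[["cd68"]])
  row[["cd163_density"]] <- as.numeric(densities[["cd163"]])
  for (f in shared_feature_names()) row[[f]] <- as.numeric(gf[[f]])
  cells <- list(cd68 = cells_cd68, cd163 = cells_cd163)
  n_excluded <- 0L
  cols <- cell_feature_columns()
  for (m in pathomic_markers()) {
    tab <- cells[[m]]
    for (f in names(cols)) {
      key <- paste0(m, "_", f)
      if (is.null(tab) || nrow(tab) == 0) next  # stays missing
      v <- median_finite(tab[[cols[[f]]]])
      n_excluded <- n_excluded + attr(v, "n_excluded")
      row[[key]] <- as.numeric(v)
    }
  }
  out <- tibble::tibble(case_id = meta$case_id, image_id = meta$image_id,
                        diagnosis = meta$diagnosis, !!!row)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a profile table as CSV
#'
#' Serialization uses the frozen registry header: `case_id`, `image_id`,
#' `diagnosis`, then the 24 features in [feature_registry()] order.
#'
#' @param profiles tibble of profiles.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  validate_profile_table(profiles)
  utils::write.csv(profiles[, profile_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Read a profile table from CSV or XLSX
#'
#' External headers can be renamed to registry names with `column_map`
#' (named character vector: external name -> registry name). After
#' mapping, all 24 registry features plus the id columns must be present;
#' extra columns are dropped with a report. Non-numeric feature cells are
#' an error with row/column coordinates.
#'
#' @param path CSV or XLSX file.
#' @param column_map optional named character vector renaming columns.
#' @return Tibble in [profile_columns()] order; attribute
#'   `extra_columns` lists dropped columns.
#' @export
read_profile_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stopf("reading XLSX requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  missing <- setdiff(profile_columns(), names(df))
  if (length(missing)) {
    stopf("profile table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), profile_columns())
  for (f in feature_registry()) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA" & v != "")
      if (length(bad)) {
        stopf("non-numeric value '%s' at row %d, column '%s'", v[bad[1]], bad[1], f)
      }
      df[[f]] <- conv
    }
  }
  out <- tibble::as_tibble(df[, profile_columns()])
  out$case_id <- as.character(out$case_id)
  out$image_id <- as.character(out$image_id)
  out$diagnosis <- as.character(out$diagnosis)
  attr(out, "extra_columns") <- extra
  out
}

#' Suggest a column map for an external profile table
#'
#' Best-effort fuzzy matcher from external headers to registry names
#' (normalized lowercase alphanumerics, then approximate matching). The
#' result is a suggestion to be reviewed and passed explicitly to
#' [read_profile_table()]; it is never applied silently.
#'
#' @param headers character vector of external column names.
#' @return Named character vector (external -> registry) of suggestions.
#' @export
suggest_column_map <- function(headers) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  reg <- feature_registry()
  reg_n <- norm(reg)
  out <- character(0)
  for (h in headers) {
    hn <- norm(h)
    hit <- which(reg_n == hn)
    if (!length(hit)) {
      d <- utils::adist(hn, reg_n, partial = TRUE)
      if (min(d) <= max(2, nchar(hn) %/% 4)) hit <- which.min(d)
    }
    if (length(hit)) out[h] <- reg[hit[1]]
  }
  out
}

# shared schema check used by write_profile_table and validate_inputs
validate_profile_table <- function(df) {
  missing <- setdiff(profile_columns(), names(df))
  if (length(missing)) {
    stopf("profile table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  for (f in feature_registry()) {
    if (!is.numeric(df[[f]]) && !all(is.na(df[[f]]))) {
      stopf("profile feature '%s' is not numeric", f)
    }
  }
  invisible(df)
}
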