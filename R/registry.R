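#' Diagnostic entities covered by the pipeline
#'
#' Six lymph node diagnoses: reactive lymphadenitis (LA, the baseline) and
#' five neoplastic entities — chronic lymphocytic leukemia (CLL), diffuse
#' large B-cell lymphoma (DLBCL), follicular lymphoma (FL), and
#' mixed-cellularity / nodular-sclerosis classical Hodgkin lymphoma
#' (MCcHL, NScHL).
#'
#' @return Character vector of the six entity labels, reference class first.
#' @export
pathomic_entities <- function() {
  c("LA", "CLL", "DLBCL", "FL", "MCcHL", "NScHL")
}

#' Macrophage markers
#'
#' @return Character vector `c("cd68", "cd163")`. CD68 is a pan-macrophage
#'   marker (M1 proxy), CD163 marks alternatively activated (M2) macrophages.
#' @export
pathomic_markers <- function() {
  c("cd68", "cd163")
}

# per-cell morphology features whose per-image medians enter the profile
morphology_feature_names <- function() {
  c("volume", "surface", "sphericity", "ellipticity_prolate",
    "ellipticity_oblate", "major_axis_length", "intensity_mean_dapi",
    "intensity_mean_marker", "antigen_density")
}

shared_feature_names <- function() {
  c("average_connections", "local_communication_efficiency",
    "estrada_index", "isolated_count")
}

#' The frozen 24-feature pathomic profile registry
#'
#' The per-image pathomic profile consists of exactly 24 named features:
#' one cell density per marker (summed cell volume / image volume), four
#' spatial-distribution features shared by both markers (mean degree,
#' local communication efficiency, Estrada index, isolated-cell count of
#' the combined unit-disk cell graph), and per-marker medians of nine
#' per-cell morphology/intensity features.
#'
#' The order returned here is the canonical serialization order; every
#' profile table written by the package uses this header.
#'
#' @return Character vector of the 24 feature names, in registry order.
#' @export
feature_registry <- function() {
  c(paste0(pathomic_markers(), "_density"),
    shared_feature_names(),
    as.vector(t(outer(pathomic_markers(), morphology_feature_names(),
                      paste, sep = "_"))))
}

#' Column header of a serialized profile table
#'
#' @return Character vector: `case_id`, `image_id`, `diagnosis`, then the
#'   24 registry features in order.
#' @export
profile_columns <- function() {
  c("case_id", "image_id", "diagnosis", feature_registry())
}
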