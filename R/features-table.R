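#' The canonical 109-feature name list
#'
#' 19 first-order + 15 shape + 75 texture (24 GLCM, 16 GLRLM, 16 GLSZM,
#' 14 GLDM, 5 NGTDM), in a fixed deterministic order. Names are prefixed by
#' family to keep them unique across families.
#'
#' @return Named character vector mapping feature name to family.
#' @export
feature_families <- function() {
  fam <- c(
    stats::setNames(rep("first_order", 19),
                    paste0("firstorder_", first_order_names())),
    stats::setNames(rep("shape", 15), paste0("shape_", shape_names())),
    stats::setNames(rep("glcm", 24), paste0("glcm_", c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
      "SumEntropy", "SumSquares"))),
    stats::setNames(rep("glrlm", 16), paste0("glrlm_", c(
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))),
    stats::setNames(rep("glszm", 16), paste0("glszm_", c(
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))),
    stats::setNames(rep("gldm", 14), paste0("gldm_", c(
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis"))),
    stats::setNames(rep("ngtdm", 5), paste0("ngtdm_", c(
      "Busyness", "Coarseness", "Complexity", "Contrast", "Strength")))
  )
  fam
}

#' Extract the full 109-feature vector for one (volume, mask) pair
#'
#' @param volume 3-D numeric array (one MRI sequence).
#' @param mask a `subregion_mask` with at least 2 voxels.
#' @param disc [discretization_settings()].
#' @param shape optional precomputed result of [extract_shape()] for this
#'   mask; shape features depend only on the mask, so callers extracting
#'   several sequences of the same subregion can reuse them.
#' @return Named numeric vector of length 109 in the canonical order of
#'   [feature_families()].
#' @export
extract_features <- function(volume, mask, disc = discretization_settings(),
                             shape = NULL) {
  fo <- extract_first_order(volume, mask, disc)
  if (is.null(shape)) shape <- extract_shape(mask)
  tx <- extract_texture(volume, mask, disc)
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(shape, paste0("shape_", names(shape))),
           tx)
  canon <- names(feature_families())
  stopifnot(setequal(names(out), canon))
  out[canon]
}

#' Extract a subjects-by-features table for one subregion and sequence
#'
#' Rows are subjects, columns the 109 features in canonical order plus a
#' `label` column. Subjects whose subregion mask is empty (or has a single
#' voxel, where texture is undefined) are dropped with a logged exclusion.
#'
#' @param cohort list of subjects as from [generate_cohort()].
#' @param masks list (parallel to `cohort`) of `subregion_mask` objects, one
#'   per subject, all for the same named subregion.
#' @param sequence sequence name (`"T1WI"`, `"T1WIC"`, `"T2WI"`, `"T2FLAIR"`).
#' @param disc [discretization_settings()].
#' @param shapes optional list of precomputed shape vectors per subject.
#' @return A `feature_table`: data frame with `subject_id`, `label` and 109
#'   feature columns; attribute `excluded` lists dropped subject ids.
#' @export
extract_feature_table <- function(cohort, masks, sequence,
                                  disc = discretization_settings(),
                                  shapes = NULL) {
  rows <- list()
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    vs <- cohort[[i]]$volume_set
    mk <- masks[[i]]
    if (is.null(mk) || sum(mk$voxels) < 2) {
      excluded <- c(excluded, vs$subject_id)
      next
    }
    fv <- extract_features(vs$volumes[[sequence]], mk, disc,
                           shape = shapes[[i]] %||% NULL)
    rows[[length(rows) + 1L]] <-
      c(list(subject_id = vs$subject_id, label = vs$label), as.list(fv))
  }
  if (length(rows) == 0) stop_hab("all subjects excluded from feature table")
  tab <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- tab$subject_id
  attr(tab, "excluded") <- excluded
  attr(tab, "sequence") <- sequence
  attr(tab, "disc") <- disc
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Extract feature tables for all four sequences of one subregion
#'
#' Shape features are computed once per subject and shared across sequences.
#'
#' @inheritParams extract_feature_table
#' @param sequences sequence names to extract (default all four).
#' @return Named list of `feature_table`, one per sequence.
#' @export
extract_sequence_tables <- function(cohort, masks,
                                    sequences = phantom_sequences(),
                                    disc = discretization_settings()) {
  shapes <- lapply(masks, function(mk) {
    if (is.null(mk) || sum(mk$voxels) < 2) NULL else extract_shape(mk)
  })
  out <- lapply(sequences, function(sq) {
    extract_feature_table(cohort, masks, sq, disc, shapes = shapes)
  })
  names(out) <- sequences
  out
}

feature_columns <- function(tab) {
  setdiff(colnames(tab), c("subject_id", "label"))
}

#' Write / read a feature table as CSV with a JSON settings sidecar
#'
#' @param tab a `feature_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.settings.json`.
#' @param subregion subregion name recorded in the sidecar.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(tab, path, subregion = NA_character_) {
  utils::write.csv(tab, path, row.names = FALSE)
  disc <- attr(tab, "disc")
  meta <- list(sequence = attr(tab, "sequence"), subregion = subregion,
               bin_mode = disc$mode %||% NA, bin_value = disc$value %||% NA)
  jsonlite::write_json(meta, paste0(path, ".settings.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- tab$subject_id
  class(tab) <- c("feature_table", class(tab))
  tab
}
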