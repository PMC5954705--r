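#' The radiomic feature bank
#'
#' Names and families of every feature computed by [extract_features], in
#' fixed column order: 8 conventional SUV metrics, 4 intensity-histogram
#' features, 2 shape features, 6 GLCM, 2 NGLDM and 11 + 11 run-/zone-length
#' features.
#'
#' @return A tibble with columns `feature` and `family`; the `gated` column
#'   marks families that require at least 64 ROI voxels (shape and all
#'   texture-matrix families).
#' @export
feature_catalog <- function() {
  fam <- function(nms, family, gated) {
    tibble::tibble(feature = nms, family = family, gated = gated)
  }
  dplyr::bind_rows(
    fam(c("suv_min", "suv_max", "suv_mean", "suv_std",
          "suv_peak_0.5ml", "suv_peak_1ml", "mtv_ml", "tlg_ml"),
        "conventional", FALSE),
    fam(c("skewness", "kurtosis", "entropy_hist", "energy_hist"),
        "histogram", FALSE),
    fam(c("sphericity", "compacity"), "shape", TRUE),
    fam(glcm_feature_names, "glcm", TRUE),
    fam(c("ngtdm_contrast", "ngtdm_coarseness"), "ngldm", TRUE),
    fam(paste0("glrlm_", rl_feature_suffixes), "glrlm", TRUE),
    fam(paste0("glzlm_", zl_feature_suffixes), "glzlm", TRUE)
  )
}

#' Extract the full radiomic feature vector of one lesion
#'
#' Runs every feature family on a segmented lesion: conventional SUV metrics
#' on the raw values, histogram and texture-matrix families on the 64-level
#' absolute quantization, and mesh-based shape features. Shape and
#' texture-matrix features are `NaN` whenever the ROI holds fewer than
#' `min_voxels` voxels (the 64-voxel gate); conventional and histogram
#' features are always present.
#'
#' @param grid a [voxel_grid].
#' @param mask a [roi_mask] of the lesion on the same grid.
#' @param n_bins,bounds quantization settings (default 64 levels over
#'   0-20 SUV).
#' @param min_voxels texture/shape gating threshold (default 64).
#' @return A one-row tibble: `roi_voxel_count` followed by the features of
#'   [feature_catalog] in order, plus the `peak_truncated` flag.
#' @export
extract_features <- function(grid, mask, n_bins = 64L, bounds = c(0, 20),
                             min_voxels = 64L) {
  qroi <- quantize_roi(grid, mask, n_bins = n_bins, bounds = bounds)
  out <- dplyr::bind_cols(
    tibble::tibble(roi_voxel_count = mask$voxel_count),
    conventional_features(grid, mask),
    histogram_features(qroi),
    shape_features(mask, min_voxels = min_voxels),
    glcm_features(qroi, min_voxels = min_voxels),
    ngldm_features(qroi, min_voxels = min_voxels),
    glrlm_features(qroi, min_voxels = min_voxels),
    glzlm_features(qroi, min_voxels = min_voxels)
  )
  dplyr::relocate(out, "peak_truncated", .after = dplyr::last_col())
}

#' Segment and extract features for a whole cohort
#'
#' Convenience wrapper running [segment_nodule] (seeded at each phantom's
#' hottest true-nodule voxel, or at a supplied seed table) and
#' [extract_features] over a list of volumes, returning one rectangular
#' feature table joined with the cohort labels.
#'
#' @param phantoms a list as returned by [make_cohort] (`$phantoms`), or a
#'   list of lists with elements `grid` and `seed` (voxel index).
#' @param cohort cohort tibble with `subject_id`, `label` and `tir` columns,
#'   one row per phantom.
#' @param threshold_fraction,search_radius_mm segmentation settings.
#' @param n_bins,bounds,min_voxels feature settings; see [extract_features].
#' @return The cohort tibble with the feature columns appended.
#' @export
extract_cohort_features <- function(phantoms, cohort,
                                    threshold_fraction = 0.40,
                                    search_radius_mm = 15,
                                    n_bins = 64L, bounds = c(0, 20),
                                    min_voxels = 64L) {
  stopifnot(length(phantoms) == nrow(cohort))
  rows <- purrr::map(phantoms, function(ph) {
    seed <- if (!is.null(ph$seed)) {
      as.integer(ph$seed)
    } else {
      # hottest voxel of the true nodule as the click point
      lin <- which(ph$nodule$mask)
      arrayInd(lin[which.max(ph$grid$values[lin])], dim(ph$grid$values))[1L, ]
    }
    mask <- segment_nodule(ph$grid, seed,
                           search_radius_mm = search_radius_mm,
                           threshold_fraction = threshold_fraction)
    extract_features(ph$grid, mask, n_bins = n_bins, bounds = bounds,
                     min_voxels = min_voxels)
  })
  dplyr::bind_cols(cohort, dplyr::bind_rows(rows))
}

#' Write a cohort feature table with its settings sidecar
#'
#' The table goes to CSV (NaN kept as `NaN`) and the extraction settings to
#' a JSON sidecar next to it.
#'
#' @param features feature table from [extract_cohort_features].
#' @param path output CSV path.
#' @param settings named list of extraction settings recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path,
                                settings = list(n_bins = 64L, bounds = c(0, 20),
                                                threshold_fraction = 0.40,
                                                min_voxels = 64L)) {
  write.csv(features, path, row.names = FALSE)
  jsonlite::write_json(
    settings, sub("\\.csv$", "_settings.json", path),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
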