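#' Conventional SUV features
#'
#' Computes the conventional PET parameters over the ROI: SUVmin, SUVmax,
#' SUVmean, SUVstd (population form, divisor N), SUVpeak in 0.5 mL and 1 mL
#' spheres, MTV and TLG.
#'
#' SUVpeak_x is the mean SUV over all grid voxels whose centers lie within a
#' sphere of volume x mL centered on the SUVmax voxel's center; the sphere is
#' not restricted to the ROI, and parts falling outside the grid are dropped
#' (with a `peak_truncated` flag). MTV is the ROI volume in mL; TLG is
#' `SUVmean * MTV` (mL, since SUV is unitless).
#'
#' @param grid a [voxel_grid].
#' @param mask a [roi_mask] on the same grid.
#' @return A one-row tibble with columns `suv_min`, `suv_max`, `suv_mean`,
#'   `suv_std`, `suv_peak_0.5ml`, `suv_peak_1ml`, `mtv_ml`, `tlg_ml` and the
#'   logical `peak_truncated`.
#' @export
conventional_features <- function(grid, mask) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "roi_mask"))
  if (mask$voxel_count == 0L) stopf("empty ROI mask")
  suv <- grid$values[mask$mask]
  m <- mean(suv)
  peak <- function(vol_ml) {
    r <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3) # sphere radius in mm
    dm <- dim(grid$values)
    cand <- which(mask$mask & grid$values == max(suv))
    ctr <- arrayInd(cand[1L], dm)[1L, ]
    ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - ctr[a]) * grid$spacing[a])^2)
    d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
    inside <- d2 <= r^2
    # would any sphere voxel fall outside the grid? check by extent
    truncated <- any(ctr * grid$spacing - r < 0) ||
      any((dm - ctr) * grid$spacing < r)
    list(value = mean(grid$values[inside]), truncated = truncated)
  }
  p05 <- peak(0.5)
  p1 <- peak(1.0)
  if (p05$truncated || p1$truncated) {
    warning("SUVpeak sphere extends beyond the grid; computed over in-grid voxels",
            call. = FALSE)
  }
  tibble::tibble(
    suv_min = min(suv), suv_max = max(suv), suv_mean = m,
    suv_std = sqrt(pop_moment(suv, 2)),
    `suv_peak_0.5ml` = p05$value, suv_peak_1ml = p1$value,
    mtv_ml = mask$volume_ml, tlg_ml = m * mask$volume_ml,
    peak_truncated = p05$truncated || p1$truncated
  )
}

#' Intensity-histogram features
#'
#' First-order statistics of the quantized gray-level distribution over the
#' ROI: skewness and kurtosis as population moment ratios over the per-voxel
#' levels (`a = 1/N`), and entropy/energy of the 64-bin level probability
#' distribution. Kurtosis is non-excess (a normal distribution gives ~3).
#' With zero variance, skewness and kurtosis are `NaN`.
#'
#' @param qroi a [quantize_roi] result.
#' @return One-row tibble: `skewness`, `kurtosis`, `entropy_hist`,
#'   `energy_hist`.
#' @export
histogram_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  x <- as.numeric(qroi$levels)
  m2 <- pop_moment(x, 2)
  skew <- if (m2 == 0) NaN else pop_moment(x, 3) / m2^1.5
  kurt <- if (m2 == 0) NaN else pop_moment(x, 4) / m2^2
  p <- tabulate(qroi$levels, nbins = qroi$n_bins) / length(qroi$levels)
  p <- p[p > 0]
  tibble::tibble(
    skewness = skew, kurtosis = kurt,
    entropy_hist = -sum(p * log2(p)),
    energy_hist = sum(p^2)
  )
}
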