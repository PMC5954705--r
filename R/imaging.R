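#' Construct a PET voxel grid
#'
#' A `voxel_grid` holds a 3D scalar field of standardized uptake values (SUV,
#' unitless) together with the physical voxel spacing in mm. Voxel centers sit
#' at `(i - 0.5) * spacing` along each axis, with `origin` (mm) added at the
#' interface.
#'
#' @param values 3D numeric array of SUV values (all `>= 0`).
#' @param spacing numeric length-3, mm per voxel along each axis (all `> 0`).
#' @param origin numeric length-3 physical origin in mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) {
    stopf("`values` must be a 3D array, got %d dimensions", length(dim(values)))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be 3 positive values (mm)")
  }
  if (any(values < 0, na.rm = TRUE)) stopf("SUV values must be non-negative")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask 3D logical array congruent with its `voxel_grid`.
#' @param spacing voxel spacing in mm (same as the grid's).
#' @return An object of class `roi_mask` with fields `mask`, `spacing`,
#'   `voxel_count` and `volume_ml` (`voxel_count * prod(spacing) / 1000`).
#' @export
roi_mask <- function(mask, spacing) {
  if (length(dim(mask)) != 3L) stopf("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  spacing <- as.numeric(spacing)
  n <- sum(mask)
  structure(
    list(
      mask = mask, spacing = spacing, voxel_count = n,
      volume_ml = n * prod(spacing) / 1000
    ),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> %d voxels, %.3f mL on a %s grid\n",
    x$voxel_count, x$volume_ml, paste(dim(x$mask), collapse = "x")
  ))
  invisible(x)
}

#' Read a 3D PET volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D volume in SUV
#'   units.
#' @return A [voxel_grid].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) {
    stopf("expected a 3D volume, got %d dimensions in %s", length(dm), path)
  }
  spacing <- attr(img, "pixdim")[seq_len(3L)]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("non-positive voxel spacing in %s", path)
  }
  voxel_grid(array(as.numeric(img), dim = dm), spacing = spacing)
}

#' Write a voxel grid or ROI mask as NIfTI
#'
#' Masks are stored as uint8 0/1.
#'
#' @param x a [voxel_grid] or [roi_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    img <- RNifti::asNifti(array(as.integer(x$mask), dim = dim(x$mask)))
    dtype <- "uint8"
  } else if (inherits(x, "voxel_grid")) {
    img <- RNifti::asNifti(x$values)
    dtype <- "double"
  } else {
    stopf("`x` must be a voxel_grid or roi_mask")
  }
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# 26-connected component (of `mask`) containing linear index `start`.
connected_component <- function(mask, start) {
  idx <- which(mask)
  vid <- match(seq_len(length(mask)), idx) # linear index -> vertex id
  dm <- dim(mask)
  edges <- lapply(seq_len(13L), function(k) {
    p <- neighbor_pairs(dm, half_directions()[k, ])
    on <- mask[p$from] & mask[p$to]
    cbind(vid[p$from[on]], vid[p$to[on]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  members <- idx[comp$membership == comp$membership[vid[start]]]
  out <- array(FALSE, dim = dm)
  out[members] <- TRUE
  out
}

#' Segment a nodule at 40% of SUVmax
#'
#' Finds the maximum SUV `M` within `search_radius_mm` of the seed voxel, then
#' returns the 26-connected component, containing the voxel achieving `M`, of
#' all voxels with `SUV >= threshold_fraction * M`. The threshold comparison
#' is inclusive.
#'
#' @param grid a [voxel_grid].
#' @param seed integer length-3 voxel index (1-based) near the lesion.
#' @param search_radius_mm radius (mm) around the seed voxel center searched
#'   for the lesion maximum. Default 15 mm.
#' @param threshold_fraction fraction of the local maximum defining the
#'   contour; the study setting is 0.40.
#' @return A [roi_mask].
#' @export
segment_nodule <- function(grid, seed, search_radius_mm = 15,
                           threshold_fraction = 0.40) {
  stopifnot(inherits(grid, "voxel_grid"))
  dm <- dim(grid$values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dm)) {
    stopf("`seed` must be a voxel index inside the grid")
  }
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stopf("`threshold_fraction` must be in (0, 1)")
  }
  # physical distance of every voxel center from the seed's center
  ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - seed[a]) * grid$spacing[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  near <- d2 <= search_radius_mm^2
  M <- max(grid$values[near])
  if (M <= 0) stopf("no uptake within %.1f mm of the seed (max SUV = 0)", search_radius_mm)
  peak_candidates <- which(near & grid$values == M)
  peak <- peak_candidates[1L]
  supra <- grid$values >= threshold_fraction * M
  roi_mask(connected_component(supra, peak), grid$spacing)
}

#' Quantize ROI intensities to absolute gray levels
#'
#' Maps each ROI voxel's SUV to a discrete gray level in `1..n_bins` using
#' fixed absolute bounds (the study setting: 64 levels over 0-20 SUV, bin
#' width 0.3125). Bins are left-closed, right-open; values at or above the
#' upper bound clip to the top level: `level = 1 + floor((suv - lo) / width)`,
#' clipped to `[1, n_bins]`.
#'
#' @param grid a [voxel_grid].
#' @param mask a [roi_mask] on the same grid.
#' @param n_bins number of gray levels (default 64).
#' @param bounds absolute SUV bounds, default `c(0, 20)`.
#' @return An object of class `quantized_roi`: integer gray levels with voxel
#'   coordinates, plus the grid geometry needed by the texture features.
#' @export
quantize_roi <- function(grid, mask, n_bins = 64L, bounds = c(0, 20)) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "roi_mask"))
  if (!all(dim(grid$values) == dim(mask$mask))) {
    stopf("grid and mask dimensions differ")
  }
  if (mask$voxel_count == 0L) stopf("empty ROI mask")
  width <- (bounds[2] - bounds[1]) / n_bins
  lin <- which(mask$mask)
  suv <- grid$values[lin]
  lev <- 1L + as.integer(floor((suv - bounds[1]) / width))
  lev <- pmin(pmax(lev, 1L), as.integer(n_bins))
  structure(
    list(
      levels = lev,
      linear_index = lin,
      coords = arrayInd(lin, dim(mask$mask)),
      dim = dim(mask$mask),
      spacing = mask$spacing,
      n_bins = as.integer(n_bins),
      bounds = as.numeric(bounds)
    ),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf(
    "<quantized_roi> %d voxels, %d levels over SUV [%g, %g], observed levels %d..%d\n",
    length(x$levels), x$n_bins, x$bounds[1], x$bounds[2],
    min(x$levels), max(x$levels)
  ))
  invisible(x)
}

# Rebuild a dense level array (NA outside the ROI) from a quantized_roi.
level_array <- function(qroi) {
  arr <- array(NA_integer_, dim = qroi$dim)
  arr[qroi$linear_index] <- qroi$levels
  arr
}
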