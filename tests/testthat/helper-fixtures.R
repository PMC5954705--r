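# Fixture builders used across the suite. Everything is generated in code;
# no stored volumes.

# Rasterized sphere mask of radius r_vox (in voxels) on an isotropic grid.
sphere_mask <- function(r_vox, spacing = 1) {
  n <- as.integer(ceiling(2 * r_vox) + 7)
  ctr <- n / 2
  ax <- ((seq_len(n) - 0.5) - ctr)^2
  inside <- outer(outer(ax, ax, "+"), ax, "+") <= r_vox^2
  roi_mask(inside, rep(spacing, 3))
}

# A grid + mask pair holding exactly the given SUV values in a compact block.
block_roi <- function(values, spacing = c(4, 4, 4), pad = 2L) {
  nv <- length(values)
  side <- max(2L, ceiling(nv^(1 / 3)))
  dm <- rep(side + 2L * pad, 3L)
  arr <- array(0, dim = dm)
  mask <- array(FALSE, dim = dm)
  coords <- as.matrix(expand.grid(
    seq_len(side) + pad, seq_len(side) + pad, seq_len(side) + pad
  ))[seq_len(nv), , drop = FALSE]
  arr[coords] <- values
  mask[coords] <- TRUE
  list(grid = voxel_grid(arr, spacing), mask = roi_mask(mask, spacing))
}

# Random quantized ROI on a small grid: random SUV field and random holes.
random_qroi <- function(seed, dim_side = 5L, density = 0.8, suv_max = 6) {
  set.seed(seed)
  dm <- rep(dim_side, 3L)
  vals <- array(runif(prod(dm), 0, suv_max), dim = dm)
  m <- array(runif(prod(dm)) < density, dim = dm)
  if (sum(m) < 2L) m[c(1L, 2L)] <- TRUE
  grid <- voxel_grid(vals, c(1, 1, 1))
  mask <- roi_mask(m, c(1, 1, 1))
  quantize_roi(grid, mask)
}

# A phantom-like object list for extract_cohort_features from a grid+mask.
as_phantom <- function(grid, nodule) list(grid = grid, nodule = nodule)
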