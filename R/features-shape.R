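# Surface mesh of a binary mask by marching tetrahedra.
#
# The mask (values 0/1 at voxel centers) is zero-padded, lightly smoothed
# with a separable Gaussian, and the 0.5 iso-surface of the resulting scalar
# field is triangulated: each grid cell is split into 6 tetrahedra and the
# linear iso-surface within each tetrahedron is emitted. Smoothing gives the
# facets sub-voxel orientation so mesh area converges to the true surface
# area with resolution (a raw binary field yields axis-aligned facets whose
# total area does not converge). Returns total area (mm^2) and the enclosed
# volume (mm^3) via the divergence theorem with outward-oriented normals.
mesh_mask_surface <- function(mask, spacing, iso = 0.5, smooth_sigma = 1.0) {
  # crop to the bounding box of the mask; padding below restores closure
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  hi <- apply(idx, 2L, max)
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dm0 <- dim(mask)
  pad <- 4L
  dm <- dm0 + 2L * pad
  base <- array(0, dim = dm)
  base[pad + seq_len(dm0[1]), pad + seq_len(dm0[2]), pad + seq_len(dm0[3])] <-
    as.numeric(mask)
  # ragged thin masks can smooth entirely below the iso level; back off the
  # kernel until the surface exists (sigma 0 = raw binary, always valid)
  for (s in c(smooth_sigma, smooth_sigma / 2, 0)) {
    f <- if (s > 0) smooth_gaussian(base, rep(s, 3L)) else base
    if (max(f) > iso) break
  }

  nx <- dm[1L]; nxy <- dm[1L] * dm[2L]
  off <- function(dx, dy, dz) dx + dy * nx + dz * nxy
  corner_off <- c(
    off(0L, 0L, 0L), off(1L, 0L, 0L), off(0L, 1L, 0L), off(1L, 1L, 0L),
    off(0L, 0L, 1L), off(1L, 0L, 1L), off(0L, 1L, 1L), off(1L, 1L, 1L)
  )
  base <- subcube_linear(dm, seq_len(dm[1] - 1L), seq_len(dm[2] - 1L),
                         seq_len(dm[3] - 1L))
  # 6-tetrahedra decomposition of the cell around the c1-c8 diagonal
  tets <- rbind(
    c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
    c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L)
  )
  area <- 0
  volume <- 0
  cross3 <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  coords_of <- function(lin) {
    ind <- arrayInd(lin, dm)
    cbind((ind[, 1] - 0.5) * spacing[1],
          (ind[, 2] - 0.5) * spacing[2],
          (ind[, 3] - 0.5) * spacing[3])
  }
  interp <- function(ia, ib, va, vb) {
    t <- (iso - va) / (vb - va)
    pa <- coords_of(ia)
    pa + t * (coords_of(ib) - pa)
  }
  # accumulate one oriented triangle set; `out_dir` points outward
  add_tris <- function(p1, p2, p3, out_dir) {
    n <- cross3(p2 - p1, p3 - p1)
    s <- sign(rowSums(n * out_dir))
    avec <- 0.5 * s * n
    centroid <- (p1 + p2 + p3) / 3
    area <<- area + sum(sqrt(rowSums(avec^2)))
    volume <<- volume + sum(rowSums(centroid * avec)) / 3
  }

  for (t in seq_len(nrow(tets))) {
    ti <- vapply(tets[t, ], function(k) base + corner_off[k], numeric(length(base)))
    tv <- matrix(f[ti], ncol = 4L)
    inside <- tv > iso
    k <- rowSums(inside)
    act <- which(k > 0L & k < 4L)
    if (length(act) == 0L) next
    ti <- ti[act, , drop = FALSE]; tv <- tv[act, , drop = FALSE]
    inside <- inside[act, , drop = FALSE]; k <- k[act]
    for (lone in 1:4) {
      others <- setdiff(1:4, lone)
      # one vertex on its own side (inside if k==1, outside if k==3)
      for (kk in c(1L, 3L)) {
        sel <- which(k == kk & (inside[, lone] == (kk == 1L)))
        if (length(sel) == 0L) next
        ia <- ti[sel, lone]; va <- tv[sel, lone]
        ps <- lapply(others, function(o) {
          interp(ia, ti[sel, o], va, tv[sel, o])
        })
        centroid <- (ps[[1]] + ps[[2]] + ps[[3]]) / 3
        dir <- centroid - coords_of(ia)
        if (kk == 3L) dir <- -dir
        add_tris(ps[[1]], ps[[2]], ps[[3]], dir)
      }
    }
    if (any(k == 2L)) {
      pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
      for (pi in seq_len(nrow(pairs))) {
        ins <- pairs[pi, ]
        outs <- setdiff(1:4, ins)
        sel <- which(k == 2L & inside[, ins[1]] & inside[, ins[2]])
        if (length(sel) == 0L) next
        q1 <- interp(ti[sel, ins[1]], ti[sel, outs[1]], tv[sel, ins[1]], tv[sel, outs[1]])
        q2 <- interp(ti[sel, ins[1]], ti[sel, outs[2]], tv[sel, ins[1]], tv[sel, outs[2]])
        q3 <- interp(ti[sel, ins[2]], ti[sel, outs[2]], tv[sel, ins[2]], tv[sel, outs[2]])
        q4 <- interp(ti[sel, ins[2]], ti[sel, outs[1]], tv[sel, ins[2]], tv[sel, outs[1]])
        m_in <- (coords_of(ti[sel, ins[1]]) + coords_of(ti[sel, ins[2]])) / 2
        add_tris(q1, q2, q3, (q1 + q2 + q3) / 3 - m_in)
        add_tris(q1, q3, q4, (q1 + q3 + q4) / 3 - m_in)
      }
    }
  }
  list(area_mm2 = area, volume_mm3 = volume)
}

#' Shape features: sphericity and compacity
#'
#' Builds a closed triangulated surface of the ROI mask and derives
#' `sphericity = pi^(1/3) (6V)^(2/3) / A` (1 for a perfect sphere) and
#' `compacity = A^(3/2) / V` (`6 sqrt(pi) ~ 10.63` for a sphere), where `A`
#' is the mesh area in mm^2 and `V` the enclosed volume in mm^3. Masks
#' touching the grid boundary are closed by zero padding. ROIs below
#' `min_voxels` return `NaN` for both features.
#'
#' @param mask a [roi_mask].
#' @param min_voxels minimum ROI size for which shape is computed
#'   (default 64).
#' @return One-row tibble: `sphericity`, `compacity`.
#' @export
shape_features <- function(mask, min_voxels = 64L) {
  stopifnot(inherits(mask, "roi_mask"))
  if (mask$voxel_count < min_voxels) {
    return(tibble::tibble(sphericity = NaN, compacity = NaN))
  }
  m <- mesh_mask_surface(mask$mask, mask$spacing)
  if (m$volume_mm3 <= 0 || m$area_mm2 <= 0) {
    return(tibble::tibble(sphericity = NaN, compacity = NaN))
  }
  tibble::tibble(
    sphericity = pi^(1 / 3) * (6 * m$volume_mm3)^(2 / 3) / m$area_mm2,
    compacity = m$area_mm2^1.5 / m$volume_mm3
  )
}
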