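# Texture-matrix feature families on the quantized ROI.
#
# All four families operate on the discrete gray levels 1..64 of a
# quantized_roi and are gated at 64 ROI voxels: below that they return NaN.
# Runs/pairs/zones are restricted to in-ROI voxels; leaving the ROI breaks a
# run and ends a co-occurrence pair.

nan_tbl <- function(nms) {
  tibble::as_tibble(as.list(stats::setNames(rep(NaN, length(nms)), nms)))
}

glcm_feature_names <- c(
  "glcm_homogeneity", "glcm_energy", "glcm_contrast", "glcm_correlation",
  "glcm_entropy", "glcm_dissimilarity"
)

rl_feature_suffixes <- c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "rlnu", "rp"
)

zl_feature_suffixes <- c(
  "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
  "glnu", "zlnu", "zp"
)

# Scalar features of one symmetric normalized co-occurrence matrix, given as
# parallel vectors of row index i, column index j and probability cvals.
glcm_scalars <- function(i, j, cvals, K) {
  pm <- vapply(seq_len(K), function(g) sum(cvals[i == g]), numeric(1)) # marginal
  mu <- sum(seq_len(K) * pm)
  sig2 <- sum((seq_len(K) - mu)^2 * pm)
  corr <- if (sig2 == 0) NaN else sum((i - mu) * (j - mu) * cvals) / sig2
  c(
    homogeneity = sum(cvals / (1 + abs(i - j))),
    energy = sum(cvals^2),
    contrast = sum((i - j)^2 * cvals),
    correlation = corr,
    entropy = -sum(cvals * log2(cvals)),
    dissimilarity = sum(abs(i - j) * cvals)
  )
}

#' Gray-level co-occurrence (GLCM) features
#'
#' One symmetric normalized co-occurrence matrix is built for each of the 13
#' unique displacement directions at a 1-voxel distance (each voxel pair is
#' counted in both orders); homogeneity, energy, contrast, correlation,
#' entropy and dissimilarity are computed per direction and averaged over
#' directions. Directions with no valid in-ROI voxel pair are skipped from
#' the average; the correlation of a direction with zero gray-level variance
#' is skipped likewise (a fully constant ROI yields `NaN` correlation).
#'
#' @param qroi a [quantize_roi] result.
#' @param min_voxels gating threshold; ROIs smaller than this return `NaN`
#'   for every feature (default 64).
#' @return One-row tibble with the six `glcm_*` features.
#' @export
glcm_features <- function(qroi, min_voxels = 64L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  if (length(qroi$levels) < min_voxels) return(nan_tbl(glcm_feature_names))
  larr <- level_array(qroi)
  K <- qroi$n_bins
  dirs <- half_directions()
  per_dir <- vector("list", nrow(dirs))
  for (d in seq_len(nrow(dirs))) {
    p <- neighbor_pairs(qroi$dim, dirs[d, ])
    a <- larr[p$from]; b <- larr[p$to]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    counts <- tabulate(c((a - 1L) * K + b, (b - 1L) * K + a), nbins = K * K)
    nz <- which(counts > 0L)
    cvals <- counts[nz] / sum(counts)
    i <- ((nz - 1L) %/% K) + 1L
    j <- ((nz - 1L) %% K) + 1L
    per_dir[[d]] <- glcm_scalars(i, j, cvals, K)
  }
  per_dir <- do.call(rbind, per_dir)
  if (is.null(per_dir)) return(nan_tbl(glcm_feature_names))
  avg <- apply(per_dir, 2L, function(v) {
    v <- v[!is.nan(v)]
    if (length(v) == 0L) NaN else mean(v)
  })
  tibble::as_tibble(as.list(stats::setNames(avg, glcm_feature_names)))
}

#' Neighborhood gray-level difference (NGLDM/NGTDM) features
#'
#' For each ROI voxel the mean gray level of its in-ROI 26-neighbors is
#' computed; voxels without any in-ROI neighbor are not counted. With
#' `s(g) = sum over counted voxels of level g of |g - neighbor mean|` and
#' `p(g)` the level probabilities over counted voxels, coarseness is
#' `1 / sum_g p(g) s(g)` (capped at 1e6 when the total difference is 0, e.g.
#' a constant ROI) and contrast is
#' `[sum_{g1,g2} p(g1) p(g2) (g1-g2)^2 / (Ng (Ng-1))] * [sum_g s(g) / Nv]`
#' with `Ng` the number of occupied levels and `Nv` the counted voxels
#' (0 when `Ng = 1`).
#'
#' @inheritParams glcm_features
#' @return One-row tibble: `ngtdm_contrast`, `ngtdm_coarseness`.
#' @export
ngldm_features <- function(qroi, min_voxels = 64L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  nms <- c("ngtdm_contrast", "ngtdm_coarseness")
  if (length(qroi$levels) < min_voxels) return(nan_tbl(nms))
  larr <- level_array(qroi)
  nvox <- prod(qroi$dim)
  nbr_sum <- numeric(nvox)
  nbr_cnt <- integer(nvox)
  dirs <- all_directions()
  for (d in seq_len(nrow(dirs))) {
    p <- neighbor_pairs(qroi$dim, dirs[d, ])
    ok <- !is.na(larr[p$from]) & !is.na(larr[p$to])
    fr <- p$from[ok]
    nbr_sum[fr] <- nbr_sum[fr] + larr[p$to[ok]]
    nbr_cnt[fr] <- nbr_cnt[fr] + 1L
  }
  counted <- qroi$linear_index[nbr_cnt[qroi$linear_index] > 0L]
  if (length(counted) == 0L) return(nan_tbl(nms))
  g <- larr[counted]
  abar <- nbr_sum[counted] / nbr_cnt[counted]
  K <- qroi$n_bins
  s_g <- vapply(seq_len(K), function(k) sum(abs(g[g == k] - abar[g == k])), numeric(1))
  n_g <- tabulate(g, nbins = K)
  nv <- length(counted)
  p_g <- n_g / nv
  occ <- which(n_g > 0L)
  ng <- length(occ)
  total_diff <- sum(p_g * s_g)
  coarseness <- if (total_diff <= 0) 1e6 else min(1e6, 1 / total_diff)
  contrast <- if (ng < 2L) 0 else {
    cross <- outer(p_g[occ], p_g[occ]) * outer(occ, occ, function(a, b) (a - b)^2)
    sum(cross) / (ng * (ng - 1)) * sum(s_g) / nv
  }
  tibble::tibble(ngtdm_contrast = contrast, ngtdm_coarseness = coarseness)
}

# The 11 standard run/zone functional forms evaluated on (g, l) pairs, one
# per run (or zone, with l the zone size), over n_vox ROI voxels.
run_zone_scalars <- function(g, l, n_vox) {
  nr <- length(g)
  c(
    mean(1 / l^2),            # short emphasis
    mean(l^2),                # long emphasis
    mean(1 / g^2),            # low gray-level
    mean(g^2),                # high gray-level
    mean(1 / (g^2 * l^2)),    # short + low
    mean(g^2 / l^2),          # short + high
    mean(l^2 / g^2),          # long + low
    mean(g^2 * l^2),          # long + high
    sum(table(g)^2) / nr,     # gray-level non-uniformity
    sum(table(l)^2) / nr,     # length non-uniformity
    nr / n_vox                # run/zone percentage
  )
}

# Orthogonal line invariants identifying the 1D lattice line through a voxel
# along direction d (components in {-1,0,1}).
line_keys <- function(coords, d) {
  nz <- which(d != 0L)
  if (length(nz) == 1L) {
    oth <- setdiff(1:3, nz)
    cbind(coords[, oth[1]], coords[, oth[2]])
  } else if (length(nz) == 2L) {
    zero_ax <- setdiff(1:3, nz)
    cbind(coords[, zero_ax],
          d[nz[2]] * coords[, nz[1]] - d[nz[1]] * coords[, nz[2]])
  } else {
    cbind(d[2] * coords[, 1] - d[1] * coords[, 2],
          d[3] * coords[, 1] - d[1] * coords[, 3])
  }
}

#' Gray-level run-length (GLRLM) features
#'
#' For each of the 13 unique directions, maximal runs of collinear in-ROI
#' voxels sharing a gray level are enumerated (runs break where the line
#' leaves the ROI); the 11 standard run-length features (SRE, LRE, LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLNU, RLNU, RP) are computed per
#' direction and averaged over the 13 directions.
#'
#' @inheritParams glcm_features
#' @return One-row tibble with the 11 `glrlm_*` features.
#' @export
glrlm_features <- function(qroi, min_voxels = 64L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  nms <- paste0("glrlm_", rl_feature_suffixes)
  if (length(qroi$levels) < min_voxels) return(nan_tbl(nms))
  coords <- qroi$coords
  n_vox <- length(qroi$levels)
  dirs <- half_directions()
  per_dir <- matrix(NA_real_, nrow = nrow(dirs), ncol = 11L)
  for (di in seq_len(nrow(dirs))) {
    d <- dirs[di, ]
    keys <- line_keys(coords, d)
    pos <- as.vector(coords %*% d)
    ord <- order(keys[, 1], keys[, 2], pos)
    lv <- qroi$levels[ord]
    k1 <- keys[ord, 1]; k2 <- keys[ord, 2]; po <- pos[ord]
    step <- sum(d * d)
    n <- length(lv)
    new_run <- c(TRUE, !(k1[-1] == k1[-n] & k2[-1] == k2[-n] &
                           po[-1] - po[-n] == step & lv[-1] == lv[-n]))
    run_id <- cumsum(new_run)
    run_len <- tabulate(run_id)
    run_lev <- lv[new_run]
    per_dir[di, ] <- run_zone_scalars(run_lev, run_len, n_vox)
  }
  avg <- colMeans(per_dir)
  tibble::as_tibble(as.list(stats::setNames(avg, nms)))
}

#' Gray-level zone-length (GLZLM) features
#'
#' Zones are 26-connected components of equal-level ROI voxels in 3D; the
#' same 11 functional forms as [glrlm_features] are applied to the zone
#' sizes (a single zone matrix, no direction averaging).
#'
#' @inheritParams glcm_features
#' @return One-row tibble with the 11 `glzlm_*` features.
#' @export
glzlm_features <- function(qroi, min_voxels = 64L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  nms <- paste0("glzlm_", zl_feature_suffixes)
  if (length(qroi$levels) < min_voxels) return(nan_tbl(nms))
  larr <- level_array(qroi)
  lin <- qroi$linear_index
  vid <- integer(prod(qroi$dim))
  vid[lin] <- seq_along(lin)
  dirs <- half_directions()
  edges <- lapply(seq_len(nrow(dirs)), function(di) {
    p <- neighbor_pairs(qroi$dim, dirs[di, ])
    a <- larr[p$from]; b <- larr[p$to]
    ok <- !is.na(a) & !is.na(b) & a == b
    cbind(vid[p$from[ok]], vid[p$to[ok]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  zone_size <- as.integer(comp$csize)
  zone_level <- qroi$levels[match(seq_len(comp$no), comp$membership)]
  vals <- run_zone_scalars(zone_level, zone_size, length(lin))
  tibble::as_tibble(as.list(stats::setNames(vals, nms)))
}
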