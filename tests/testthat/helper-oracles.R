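# Brute-force oracles, deliberately written as naive enumerations independent
# of the package's vectorized implementations.

.oracle_dirs13 <- local({
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  d[apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  }), ]
})
.oracle_dirs26 <- rbind(.oracle_dirs13, -.oracle_dirs13)

.in_bounds <- function(v, dm) all(v >= 1 & v <= dm)

# Dense level array with NA outside the ROI, from a quantized_roi.
oracle_level_array <- function(qroi) {
  arr <- array(NA_integer_, dim = qroi$dim)
  arr[qroi$linear_index] <- qroi$levels
  arr
}

oracle_glcm <- function(qroi) {
  larr <- oracle_level_array(qroi)
  dm <- qroi$dim
  K <- qroi$n_bins
  acc <- NULL
  for (di in seq_len(nrow(.oracle_dirs13))) {
    d <- .oracle_dirs13[di, ]
    C <- matrix(0, K, K)
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      b <- c(x, y, z) + d
      if (!.in_bounds(b, dm)) next
      la <- larr[x, y, z]
      lb <- larr[b[1], b[2], b[3]]
      if (is.na(la) || is.na(lb)) next
      C[la, lb] <- C[la, lb] + 1
      C[lb, la] <- C[lb, la] + 1
    }
    if (sum(C) == 0) next
    C <- C / sum(C)
    i <- row(C); j <- col(C)
    nz <- C > 0
    pm <- rowSums(C)
    mu <- sum(seq_len(K) * pm)
    s2 <- sum((seq_len(K) - mu)^2 * pm)
    acc <- rbind(acc, c(
      homogeneity = sum(C / (1 + abs(i - j))),
      energy = sum(C^2),
      contrast = sum((i - j)^2 * C),
      correlation = if (s2 == 0) NaN else sum((i - mu) * (j - mu) * C) / s2,
      entropy = -sum(C[nz] * log2(C[nz])),
      dissimilarity = sum(abs(i - j) * C)
    ))
  }
  apply(acc, 2, function(v) mean(v[!is.nan(v)]))
}

.oracle_run_zone <- function(g, l, n_vox) {
  nr <- length(g)
  c(mean(1 / l^2), mean(l^2), mean(1 / g^2), mean(g^2),
    mean(1 / (g^2 * l^2)), mean(g^2 / l^2), mean(l^2 / g^2), mean(g^2 * l^2),
    sum(table(g)^2) / nr, sum(table(l)^2) / nr, nr / n_vox)
}

oracle_glrlm <- function(qroi) {
  larr <- oracle_level_array(qroi)
  dm <- qroi$dim
  lv <- function(v) larr[v[1], v[2], v[3]]
  n_vox <- length(qroi$levels)
  per <- NULL
  for (di in seq_len(nrow(.oracle_dirs13))) {
    d <- .oracle_dirs13[di, ]
    runs_g <- integer(0)
    runs_l <- integer(0)
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      v <- c(x, y, z)
      if (is.na(lv(v))) next
      prev <- v - d
      if (.in_bounds(prev, dm) && !is.na(lv(prev)) && lv(prev) == lv(v)) next
      len <- 1L
      nxt <- v + d
      while (.in_bounds(nxt, dm) && !is.na(lv(nxt)) && lv(nxt) == lv(v)) {
        len <- len + 1L
        nxt <- nxt + d
      }
      runs_g <- c(runs_g, lv(v))
      runs_l <- c(runs_l, len)
    }
    per <- rbind(per, .oracle_run_zone(runs_g, runs_l, n_vox))
  }
  colMeans(per)
}

oracle_glzlm <- function(qroi) {
  larr <- oracle_level_array(qroi)
  dm <- qroi$dim
  lv <- function(v) larr[v[1], v[2], v[3]]
  seen <- array(FALSE, dm)
  zg <- integer(0)
  zs <- integer(0)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    v <- c(x, y, z)
    if (is.na(lv(v)) || seen[x, y, z]) next
    queue <- list(v)
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(26)) {
        nb <- cur + .oracle_dirs26[k, ]
        if (.in_bounds(nb, dm) && !seen[nb[1], nb[2], nb[3]] &&
            !is.na(lv(nb)) && lv(nb) == lv(v)) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- c(queue, list(nb))
        }
      }
    }
    zg <- c(zg, lv(v))
    zs <- c(zs, size)
  }
  list(scalars = .oracle_run_zone(zg, zs, length(qroi$levels)),
       levels = zg, sizes = zs)
}

oracle_ngtdm <- function(qroi) {
  larr <- oracle_level_array(qroi)
  dm <- qroi$dim
  K <- qroi$n_bins
  lv <- function(v) larr[v[1], v[2], v[3]]
  cnt <- 0L
  ssum <- numeric(K)
  ng_count <- integer(K)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    v <- c(x, y, z)
    if (is.na(lv(v))) next
    nbrs <- integer(0)
    for (k in seq_len(26)) {
      nb <- v + .oracle_dirs26[k, ]
      if (.in_bounds(nb, dm) && !is.na(lv(nb))) nbrs <- c(nbrs, lv(nb))
    }
    if (!length(nbrs)) next
    cnt <- cnt + 1L
    g <- lv(v)
    ssum[g] <- ssum[g] + abs(g - mean(nbrs))
    ng_count[g] <- ng_count[g] + 1L
  }
  p <- ng_count / cnt
  occ <- which(ng_count > 0)
  ng <- length(occ)
  total <- sum(p * ssum)
  coarseness <- if (total <= 0) 1e6 else min(1e6, 1 / total)
  contrast <- if (ng < 2) 0 else {
    sum(outer(p[occ], p[occ]) * outer(occ, occ, function(a, b) (a - b)^2)) /
      (ng * (ng - 1)) * sum(ssum) / cnt
  }
  c(contrast = contrast, coarseness = coarseness)
}

# AUC by exhaustive positive-negative pair comparison (ties count 1/2).
oracle_auc_paircount <- function(values, labels, positive) {
  vp <- values[labels == positive]
  vn <- values[labels != positive]
  total <- 0
  for (a in vp) for (b in vn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(vp) * length(vn))
}

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, probabilities from choose() arithmetic.
oracle_fisher_two_sided <- function(tp, fp, fn, tn) {
  c1 <- tp + fn
  c2 <- fp + tn
  r1 <- tp + fp
  n <- c1 + c2
  if (min(c1, c2, r1, fn + tn) == 0) return(1)
  ks <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(c2, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[ks == tp]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(1e-12, abs(b)))
}
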