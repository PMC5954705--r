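#' @importFrom rlang .data
#' @importFrom stats aov dhyper pf pnorm pt quantile rnorm rlnorm sd var
#' @importFrom utils modifyList write.csv
NULL

# The 13 unique half-space displacement directions of the 26-neighborhood
# (one per axis/diagonal family); their negations give the other 13.
half_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(d, 1L, function(v) {
    nz <- v[v != 0]
    nz[1L] > 0
  })
  unname(d[keep, , drop = FALSE])
}

all_directions <- function() {
  h <- half_directions()
  rbind(h, -h)
}

# Linear indices of the subcube xs x ys x zs of an array with dimensions `dm`.
subcube_linear <- function(dm, xs, ys, zs) {
  nx <- dm[1L]
  nxy <- dm[1L] * dm[2L]
  as.vector(outer(outer(xs, (ys - 1L) * nx, "+"), (zs - 1L) * nxy, "+"))
}

# For displacement d, linear indices of all voxels v with v + d in bounds
# (`from`) and of v + d itself (`to`).
neighbor_pairs <- function(dm, d) {
  rng <- function(n, s) if (s >= 0L) seq_len(n - s) else seq.int(1L - s, n)
  xs <- rng(dm[1L], d[1L]); ys <- rng(dm[2L], d[2L]); zs <- rng(dm[3L], d[3L])
  list(
    from = subcube_linear(dm, xs, ys, zs),
    to = subcube_linear(dm, xs + d[1L], ys + d[2L], zs + d[3L])
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Population (divisor-N) central moments of a numeric vector.
pop_moment <- function(x, k) {
  m <- mean(x)
  mean((x - m)^k)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
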