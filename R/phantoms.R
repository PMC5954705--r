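#' Specify a single synthetic PET phantom
#'
#' A phantom is an ellipsoidal "nodule" of elevated tracer uptake embedded in
#' low-uptake background noise, on a regular voxel grid in SUV units. A voxel
#' belongs to the nodule when its center lies inside the ellipsoid.
#'
#' Intensity models for in-nodule voxels:
#' * `"constant"`: every nodule voxel equals `location` SUV.
#' * `"gaussian"`: `Normal(location, scale)` draws, clipped at 0 (symmetric
#'   uptake distribution).
#' * `"lognormal"`: `Lognormal(meanlog = log(location), sdlog = scale)` draws,
#'   i.e. `location` is the median SUV; right-skewed uptake.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per axis.
#' @param background_mean,background_sd background SUV noise parameters;
#'   negative draws are clipped to 0.
#' @param nodule_center physical center in mm; default is the grid center.
#' @param nodule_radii ellipsoid semi-axes in mm (all `> 0`).
#' @param intensity_model one of `"constant"`, `"gaussian"`, `"lognormal"`.
#' @param location,scale location/scale of the intensity model in SUV (for
#'   the lognormal, `scale` is the log-scale sd).
#' @param class_label `"benign"` or `"malignant"`.
#' @param smooth_fwhm_mm optional Gaussian smoothing FWHM (mm) applied to the
#'   whole volume to emulate scanner point-spread blur; 0 (default) disables
#'   it.
#' @param rng_seed integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(28L, 28L, 28L),
                         voxel_spacing = c(3, 3, 3),
                         background_mean = 0.5, background_sd = 0.2,
                         nodule_center = NULL,
                         nodule_radii = c(9, 9, 9),
                         intensity_model = c("gaussian", "constant", "lognormal"),
                         location = 6, scale = 1,
                         class_label = c("benign", "malignant"),
                         smooth_fwhm_mm = 0,
                         rng_seed = 1L) {
  intensity_model <- match.arg(intensity_model)
  class_label <- match.arg(class_label)
  grid_shape <- as.integer(grid_shape)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (is.null(nodule_center)) nodule_center <- grid_shape * voxel_spacing / 2
  if (any(nodule_radii <= 0)) stopf("nodule radii must be positive")
  if (background_mean < 0) stopf("background_mean must be >= 0")
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stopf("grid_shape must be 3 integers >= 4")
  }
  # the nodule plus a 2-voxel margin must fit inside the grid
  lo <- nodule_center - nodule_radii
  hi <- nodule_center + nodule_radii
  if (any(lo < 2 * voxel_spacing) || any(hi > (grid_shape - 2) * voxel_spacing)) {
    stopf("nodule (center %s mm, radii %s mm) does not fit the grid with a 2-voxel margin",
          paste(round(nodule_center, 1), collapse = ","),
          paste(round(nodule_radii, 1), collapse = ","))
  }
  structure(
    list(
      grid_shape = grid_shape, voxel_spacing = voxel_spacing,
      background_mean = background_mean, background_sd = background_sd,
      nodule_center = as.numeric(nodule_center),
      nodule_radii = as.numeric(nodule_radii),
      intensity_model = intensity_model, location = location, scale = scale,
      class_label = class_label, smooth_fwhm_mm = smooth_fwhm_mm,
      rng_seed = as.integer(rng_seed)
    ),
    class = "phantom_spec"
  )
}

# Analytic moments of the in-nodule intensity model (before clipping).
model_moments <- function(model, location, scale) {
  switch(model,
    constant = list(mean = location, sd = 0, skewness = 0),
    gaussian = list(mean = location, sd = scale, skewness = 0),
    lognormal = {
      s2 <- scale^2
      list(
        mean = location * exp(s2 / 2),
        sd = location * exp(s2 / 2) * sqrt(exp(s2) - 1),
        skewness = (exp(s2) + 2) * sqrt(exp(s2) - 1)
      )
    }
  )
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
# Normalized convolution: the zero-extended convolution is divided by the
# in-bounds kernel mass, so edge values are unbiased.
smooth_gaussian <- function(arr, sigma_vox) {
  dm <- dim(arr)
  shift_axis <- function(x, a, k) {
    # x shifted by k voxels along axis a, zero-filled
    out <- array(0, dim = dm)
    src <- lapply(dm, seq_len)
    dst <- src
    n <- dm[a]
    if (abs(k) >= n) return(out)
    if (k >= 0) {
      src[[a]] <- seq_len(n - k); dst[[a]] <- seq.int(k + 1L, n)
    } else {
      src[[a]] <- seq.int(1L - k, n); dst[[a]] <- seq_len(n + k)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    w <- exp(-((-half:half)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim = dm)
    mass <- array(0, dim = dm)
    ones <- array(1, dim = dm)
    for (kk in seq_along(w)) {
      k <- kk - half - 1L
      acc <- acc + w[kk] * shift_axis(arr, a, k)
      mass <- mass + w[kk] * shift_axis(ones, a, k)
    }
    arr <- acc / mass
  }
  arr
}

#' Generate a phantom volume from its specification
#'
#' @param spec a [phantom_spec].
#' @return A list with elements
#' * `grid`: the simulated [voxel_grid],
#' * `nodule`: the ground-truth nodule [roi_mask] (ellipsoid membership by
#'   voxel center),
#' * `truth`: a one-row tibble with the spec's class label, the analytic
#'   mean/sd/skewness of the intensity model, the exact ellipsoid volume in
#'   mL and the rasterized nodule voxel count.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  sp <- spec$voxel_spacing
  ctr <- spec$nodule_center
  r <- spec$nodule_radii
  ax <- lapply(1:3, function(a) (((seq_len(dm[a]) - 0.5) * sp[a] - ctr[a]) / r[a])^2)
  inside <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= 1
  n_in <- sum(inside)
  vals <- with_seed(spec$rng_seed, {
    bg <- pmax(0, rnorm(prod(dm), spec$background_mean, spec$background_sd))
    v <- array(bg, dim = dm)
    v[inside] <- switch(spec$intensity_model,
      constant = rep(spec$location, n_in),
      gaussian = pmax(0, rnorm(n_in, spec$location, spec$scale)),
      lognormal = rlnorm(n_in, meanlog = log(spec$location), sdlog = spec$scale)
    )
    v
  })
  if (spec$smooth_fwhm_mm > 0) {
    sigma_vox <- (spec$smooth_fwhm_mm / 2.3548) / sp
    vals <- smooth_gaussian(vals, sigma_vox)
  }
  mom <- model_moments(spec$intensity_model, spec$location, spec$scale)
  truth <- tibble::tibble(
    class_label = spec$class_label,
    model = spec$intensity_model,
    true_mean = mom$mean, true_sd = mom$sd, true_skewness = mom$skewness,
    nodule_volume_ml = 4 / 3 * pi * prod(r) / 1000,
    nodule_voxels = n_in,
    rng_seed = spec$rng_seed
  )
  list(grid = voxel_grid(vals, sp), nodule = roi_mask(inside, sp), truth = truth)
}

#' Specify a synthetic phantom cohort
#'
#' Defines the per-class generative settings of a cohort of nodule phantoms.
#' Benign nodules draw their uptake from a symmetric Gaussian model and
#' malignant nodules from a right-skewed lognormal model with higher uptake,
#' so that intensity level (SUVmax), volume (MTV) and intensity-distribution
#' asymmetry (skewness) all separate the classes. A controllable fraction of
#' nodules per class is sized "small", i.e. to segment below 64 voxels at the
#' 40% SUVmax threshold, emulating sub-resolution nodules for which texture
#' matrices are not computed.
#'
#' Default class settings (SUV, mm):
#' * benign: Gaussian, per-subject mean `~ Normal(5, 0.8)` (floored at 2),
#'   in-nodule sd 0.8; large radii `Uniform(8, 9.5)`, small `Uniform(3.5, 5)`.
#' * malignant: lognormal, per-subject median `~ exp(Normal(log 9, 0.25))`,
#'   log-sd 0.3; large radii `Uniform(12.5, 15)`, small `Uniform(5, 6.8)`.
#'
#' Per-axis radii are jittered by `Uniform(0.95, 1.05)` so nodules are true
#' ellipsoids.
#'
#' @param n_subjects cohort size (default 50).
#' @param n_malignant number of malignant subjects (default 18).
#' @param fraction_small_roi probability that a nodule is sized below 64 ROI
#'   voxels; a scalar or a named vector `c(benign = , malignant = )`.
#'   Default `c(benign = 0.5, malignant = 1/3)`.
#' @param grid_shape,voxel_spacing grid geometry shared by all phantoms.
#' @param benign,malignant per-class generative parameter lists; see Details.
#'   Entries replace the defaults listed above.
#' @param rng_seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 50L, n_malignant = 18L,
                        fraction_small_roi = c(benign = 0.5, malignant = 1 / 3),
                        grid_shape = c(28L, 28L, 28L),
                        voxel_spacing = c(3, 3, 3),
                        benign = list(), malignant = list(),
                        rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_malignant <- as.integer(n_malignant)
  if (n_subjects < 0L) stopf("n_subjects must be >= 0")
  if (n_malignant < 0L || n_malignant > n_subjects) {
    stopf("n_malignant must be between 0 and n_subjects")
  }
  fraction_small_roi <- unlist(fraction_small_roi)
  if (length(fraction_small_roi) == 1L) {
    fraction_small_roi <- c(benign = unname(fraction_small_roi),
                            malignant = unname(fraction_small_roi))
  } else if (is.null(names(fraction_small_roi))) {
    names(fraction_small_roi) <- c("benign", "malignant")
  }
  if (any(fraction_small_roi < 0) || any(fraction_small_roi > 1)) {
    stopf("fraction_small_roi must lie in [0, 1]")
  }
  ben <- modifyList(list(
    model = "gaussian",
    location_mean = 5, location_sd = 0.8, location_floor = 2, scale = 0.8,
    radii_large = c(8, 9.5), radii_small = c(3.5, 5)
  ), benign)
  mal <- modifyList(list(
    model = "lognormal", location_meanlog = log(9), location_sdlog = 0.25,
    scale = 0.3,
    radii_large = c(12.5, 15), radii_small = c(5, 6.8)
  ), malignant)
  structure(
    list(
      n_subjects = n_subjects, n_malignant = n_malignant,
      fraction_small_roi = fraction_small_roi[c("benign", "malignant")],
      grid_shape = as.integer(grid_shape),
      voxel_spacing = as.numeric(voxel_spacing),
      benign = ben, malignant = mal,
      rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_spec"
  )
}

# Fixed stochastic map from true class to a simulated 5-level cytology
# category (TIR1..TIR5): benign nodules land mostly in TIR2, malignant ones
# mostly in TIR4/TIR5. Purely a label stream for the ANOVA-by-category stage.
tir_probs <- list(
  benign = c(TIR1 = 0.06, TIR2 = 0.70, TIR3 = 0.18, TIR4 = 0.06, TIR5 = 0.00),
  malignant = c(TIR1 = 0.00, TIR2 = 0.05, TIR3 = 0.17, TIR4 = 0.17, TIR5 = 0.61)
)

#' Generate a phantom cohort
#'
#' Draws one phantom per subject according to a [cohort_spec]. Exactly
#' `n_malignant` subjects are malignant; each subject's nodule is sized
#' "small" (below 64 ROI voxels at the 40% threshold) with its class's
#' `fraction_small_roi` probability. Each phantom gets its own child seed
#' derived from the master seed, so the cohort is reproducible as a whole and
#' per subject.
#'
#' @param spec a [cohort_spec].
#' @return A list with
#' * `phantoms`: list of [make_phantom] results (one per subject),
#' * `cohort`: tibble with `subject_id`, `label`, `tir`, `small_roi`,
#'   `seed`, and the ground-truth columns of each phantom.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (n == 0L) {
    return(list(phantoms = list(), cohort = tibble::tibble(
      subject_id = character(), label = character(), tir = character(),
      small_roi = logical(), seed = integer()
    )))
  }
  labels <- rep(c("malignant", "benign"), c(spec$n_malignant, n - spec$n_malignant))
  draws <- with_seed(spec$rng_seed, {
    list(
      small = stats::runif(n) < spec$fraction_small_roi[labels],
      tir = vapply(labels, function(lb) {
        sample(names(tir_probs[[lb]]), 1L, prob = tir_probs[[lb]])
      }, character(1)),
      subseed = sample.int(.Machine$integer.max - 1L, n),
      u_loc = rnorm(n),
      u_radii = matrix(stats::runif(3L * n, 0.95, 1.05), ncol = 3L),
      u_size = stats::runif(n)
    )
  })
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- spec[[labels[i]]]
    rng <- if (draws$small[i]) cls$radii_small else cls$radii_large
    base_r <- rng[1] + draws$u_size[i] * (rng[2] - rng[1])
    radii <- base_r * draws$u_radii[i, ]
    loc <- if (labels[i] == "benign") {
      max(cls$location_floor, cls$location_mean + cls$location_sd * draws$u_loc[i])
    } else {
      exp(cls$location_meanlog + cls$location_sdlog * draws$u_loc[i])
    }
    ps <- phantom_spec(
      grid_shape = spec$grid_shape, voxel_spacing = spec$voxel_spacing,
      nodule_radii = radii,
      intensity_model = cls$model, location = loc, scale = cls$scale,
      class_label = labels[i], rng_seed = draws$subseed[i]
    )
    phantoms[[i]] <- make_phantom(ps)
    rows[[i]] <- dplyr::mutate(
      phantoms[[i]]$truth,
      subject_id = sprintf("S%03d", i),
      label = labels[i], tir = draws$tir[[i]],
      small_roi = draws$small[i], seed = draws$subseed[i],
      .before = 1L
    )
  }
  list(phantoms = phantoms, cohort = dplyr::bind_rows(rows))
}

#' Write a generated cohort to disk
#'
#' Volumes and ground-truth nodule masks go to NIfTI (`.nii.gz`), the cohort
#' table to CSV, and the generation parameters to a JSON sidecar.
#'
#' @param cohort result of [make_cohort].
#' @param spec the [cohort_spec] that produced it.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$cohort$subject_id
  for (i in seq_along(cohort$phantoms)) {
    write_volume(cohort$phantoms[[i]]$grid, file.path(dir, paste0(ids[i], "_suv.nii.gz")))
    write_volume(cohort$phantoms[[i]]$nodule, file.path(dir, paste0(ids[i], "_nodule.nii.gz")))
  }
  write.csv(cohort$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(
    unclass(spec), file.path(dir, "cohort_spec.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
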