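#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: simulation or analysis mode,
#' segmentation (threshold fraction, search radius), quantization (levels,
#' absolute SUV bounds), screening gates and the master seed. All settings
#' are logged; there are no silent defaults at run time.
#'
#' @param mode `"simulate"` (generate a phantom cohort, then analyze it) or
#'   `"analyze"` (read volumes + cohort table from `input_dir`).
#' @param outdir output directory.
#' @param cohort a [cohort_spec] (simulate mode).
#' @param input_dir directory with `cohort.csv` (columns `subject_id`,
#'   `label`, `tir`, `volume`, `seed_x`, `seed_y`, `seed_z`) and the NIfTI
#'   volumes it references (analyze mode).
#' @param rng_seed master seed; mandatory in simulate mode.
#' @param threshold_fraction segmentation threshold as a fraction of the
#'   local SUVmax (study setting 0.40).
#' @param search_radius_mm SUVmax search radius around the seed voxel.
#' @param n_bins,bounds quantization settings (64 levels over 0-20 SUV).
#' @param min_voxels texture/shape gate (64 voxels).
#' @param auc_min,fisher_alpha,anova_alpha,cor_alpha screening gates.
#' @param n_boot bootstrap resamples for AUC CIs.
#' @param write_volumes write simulated volumes/masks as NIfTI (simulate
#'   mode; default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "analyze"), outdir,
                            cohort = cohort_spec(), input_dir = NULL,
                            rng_seed = NULL,
                            threshold_fraction = 0.40, search_radius_mm = 15,
                            n_bins = 64L, bounds = c(0, 20), min_voxels = 64L,
                            auc_min = 0.55, fisher_alpha = 0.08,
                            anova_alpha = 0.05, cor_alpha = 0.01,
                            n_boot = 2000L, write_volumes = TRUE) {
  mode <- match.arg(mode)
  for (nm in c("auc_min", "fisher_alpha", "anova_alpha", "cor_alpha",
               "threshold_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) stopf("`%s` must lie in (0, 1)", nm)
  }
  if (mode == "simulate") {
    if (is.null(rng_seed)) stopf("`rng_seed` is mandatory in simulate mode")
    cohort$rng_seed <- as.integer(rng_seed)
  }
  if (mode == "analyze" && is.null(input_dir)) {
    stopf("`input_dir` is required in analyze mode")
  }
  structure(
    list(
      mode = mode, outdir = outdir, cohort = cohort, input_dir = input_dir,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
      threshold_fraction = threshold_fraction,
      search_radius_mm = search_radius_mm,
      n_bins = as.integer(n_bins), bounds = as.numeric(bounds),
      min_voxels = as.integer(min_voxels),
      auc_min = auc_min, fisher_alpha = fisher_alpha,
      anova_alpha = anova_alpha, cor_alpha = cor_alpha,
      n_boot = as.integer(n_boot), write_volumes = isTRUE(write_volumes)
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' The logged effective configuration re-parses to an equal configuration
#' (round-trip property).
#'
#' @param config a [pipeline_config].
#' @param path JSON path.
#' @return [write_pipeline_config]: `path` invisibly;
#'   [read_pipeline_config]: a [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- x$cohort
  cohort <- cohort_spec(
    n_subjects = co$n_subjects, n_malignant = co$n_malignant,
    fraction_small_roi = unlist(co$fraction_small_roi),
    grid_shape = co$grid_shape, voxel_spacing = co$voxel_spacing,
    benign = co$benign, malignant = co$malignant, rng_seed = co$rng_seed
  )
  pipeline_config(
    mode = x$mode, outdir = x$outdir, cohort = cohort,
    input_dir = x$input_dir, rng_seed = x$rng_seed,
    threshold_fraction = x$threshold_fraction,
    search_radius_mm = x$search_radius_mm,
    n_bins = x$n_bins, bounds = x$bounds, min_voxels = x$min_voxels,
    auc_min = x$auc_min, fisher_alpha = x$fisher_alpha,
    anova_alpha = x$anova_alpha, cor_alpha = x$cor_alpha,
    n_boot = x$n_boot, write_volumes = x$write_volumes
  )
}

load_analysis_inputs <- function(input_dir) {
  cohort_path <- file.path(input_dir, "cohort.csv")
  if (!file.exists(cohort_path)) stopf("[input] cohort table not found: %s", cohort_path)
  cohort <- tibble::as_tibble(utils::read.csv(cohort_path, stringsAsFactors = FALSE))
  need <- c("subject_id", "label", "volume", "seed_x", "seed_y", "seed_z")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("[input] cohort.csv lacks columns: %s", paste(miss, collapse = ", "))
  paths <- file.path(input_dir, cohort$volume)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) stopf("[input] missing volumes: %s", paste(absent, collapse = ", "))
  phantoms <- purrr::pmap(
    list(paths, cohort$seed_x, cohort$seed_y, cohort$seed_z),
    function(p, sx, sy, sz) list(grid = load_volume(p), seed = c(sx, sy, sz))
  )
  list(phantoms = phantoms, cohort = cohort)
}

#' Run the full pipeline
#'
#' Simulate (or load) a cohort, segment each lesion, extract the radiomic
#' feature bank, screen the predictors, and write every artifact under
#' `config$outdir`: the cohort table, the feature table with its settings
#' sidecar, the screening report (JSON + CSVs), the effective configuration
#' and a run log. Identical configuration + seed give identical artifacts.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with `features` (the feature table), `report`
#'   (the `screening_report`) and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- if (config$mode == "simulate") {
    make_cohort(config$cohort)
  } else {
    load_analysis_inputs(config$input_dir)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (config$mode == "simulate" && config$write_volumes) {
    write_cohort(inputs, config$cohort, file.path(config$outdir, "volumes"))
  }
  features <- extract_cohort_features(
    inputs$phantoms, inputs$cohort,
    threshold_fraction = config$threshold_fraction,
    search_radius_mm = config$search_radius_mm,
    n_bins = config$n_bins, bounds = config$bounds,
    min_voxels = config$min_voxels
  )
  write.csv(inputs$cohort, file.path(config$outdir, "cohort.csv"), row.names = FALSE)
  write_feature_table(
    features, file.path(config$outdir, "features.csv"),
    settings = list(
      n_bins = config$n_bins, bounds = config$bounds,
      threshold_fraction = config$threshold_fraction,
      min_voxels = config$min_voxels
    )
  )
  report <- screen_features(
    features,
    outcome = "label", tir = "tir",
    auc_min = config$auc_min, fisher_alpha = config$fisher_alpha,
    anova_alpha = config$anova_alpha, cor_alpha = config$cor_alpha,
    n_boot = config$n_boot,
    seed = if (is.null(config$rng_seed)) 1L else config$rng_seed
  )
  write_screening_report(report, file.path(config$outdir, "screening"))
  write_pipeline_config(config, file.path(config$outdir, "run_config.json"))
  log_lines <- c(
    sprintf("petrad version: %s", as.character(utils::packageVersion("petrad"))),
    sprintf("mode: %s", config$mode),
    sprintf("rng_seed: %s", ifelse(is.null(config$rng_seed), "NA", config$rng_seed)),
    sprintf("threshold_fraction: %g", config$threshold_fraction),
    sprintf("search_radius_mm: %g", config$search_radius_mm),
    sprintf("n_bins: %d", config$n_bins),
    sprintf("bounds_suv: [%g, %g]", config$bounds[1], config$bounds[2]),
    sprintf("min_voxels: %d", config$min_voxels),
    sprintf("auc_min: %g", config$auc_min),
    sprintf("fisher_alpha: %g", config$fisher_alpha),
    sprintf("anova_alpha: %g", config$anova_alpha),
    sprintf("cor_alpha: %g", config$cor_alpha),
    sprintf("n_boot: %d", config$n_boot),
    sprintf("n_subjects: %d", nrow(features)),
    sprintf("n_final_predictors: %d", length(report$final))
  )
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(list(features = features, report = report, outdir = config$outdir))
}
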