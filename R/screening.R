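#' One-way ANOVA of a feature across groups
#'
#' Classical one-way fixed-effects ANOVA (F statistic and upper-tail p from
#' the F distribution), with `NaN`/`NA` observations dropped first. When the
#' between-group sum of squares is exactly zero (identical group means, e.g.
#' fully degenerate data), `F = 0` and `p = 1` are returned rather than the
#' indeterminate 0/0.
#'
#' @param values numeric observations.
#' @param groups group membership (factor or coercible).
#' @param drop_empty drop groups emptied by the NaN filter instead of
#'   erroring (default `FALSE`, matching the strict contract).
#' @return A list with `statistic` (F), `p_value`, `df` (between, within).
#' @export
anova_oneway <- function(values, groups, drop_empty = FALSE) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- groups[ok]
  if (any(tabulate(g, nbins = nlevels(g)) == 0L)) {
    if (!drop_empty) stopf("a group has no observations after dropping NaN")
    g <- droplevels(g)
  }
  k <- nlevels(g)
  if (k < 2L) stopf("need at least 2 non-empty groups")
  if (length(values) <= k) stopf("need more observations than groups")
  fit <- aov(values ~ g)
  ss <- summary(fit)[[1L]]
  ssb <- ss[["Sum Sq"]][1L]
  if (ssb == 0) {
    return(list(statistic = 0, p_value = 1, df = ss[["Df"]]))
  }
  list(
    statistic = ss[["F value"]][1L],
    p_value = ss[["Pr(>F)"]][1L],
    df = ss[["Df"]]
  )
}

#' ROC area under the curve with orientation and bootstrap CI
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted 1/2: the
#' probability that a randomly chosen positive case scores above a randomly
#' chosen negative one. When the raw AUC is below 0.5 the feature's sign is
#' flipped: the reported AUC is `1 - raw` with `orientation = -1`, so
#' "higher oriented value" always points toward the positive class. The 95%
#' confidence interval comes from a seeded stratified bootstrap (resampling
#' within each class).
#'
#' @param values numeric feature values.
#' @param labels class labels; `positive` names the positive class.
#' @param positive the positive-class label (default `"malignant"`).
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 skips the
#'   CI).
#' @param conf_level CI coverage (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A list: `auc` (oriented), `orientation` (+1/-1), `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(values, labels, positive = "malignant",
                    n_boot = 2000L, conf_level = 0.95, seed = 1L) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  y <- labels[ok] == positive
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  raw_auc <- function(v, yy) {
    r <- rank(v)
    (sum(r[yy]) - sum(yy) * (sum(yy) + 1) / 2) / (sum(yy) * sum(!yy))
  }
  raw <- raw_auc(values, y)
  orientation <- if (raw < 0.5) -1L else 1L
  auc <- if (orientation < 0L) 1 - raw else raw
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    ip <- which(y)
    ineg <- which(!y)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(ip, n1, replace = TRUE), sample(ineg, n0, replace = TRUE))
        raw_auc(values[idx], c(rep(TRUE, n1), rep(FALSE, n0)))
      }, numeric(1))
    })
    if (orientation < 0L) boots <- 1 - boots
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(a, 1 - a), names = FALSE))
  }
  list(auc = auc, orientation = orientation,
       ci_low = ci[1L], ci_high = ci[2L], n_pos = n1, n_neg = n0)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' The table is `[[TP, FP], [FN, TN]]` (predicted by actual). The two-sided
#' p-value sums the hypergeometric probabilities, over all tables with the
#' observed margins, that do not exceed the observed table's probability
#' (within a 1e-7 relative slack). Any zero margin gives p = 1.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(tp, fp, fn, tn) {
  cells <- c(tp, fp, fn, tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stopf("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stopf("the table must have a positive grand total")
  c1 <- tp + fn  # actual positives
  c2 <- fp + tn  # actual negatives
  r1 <- tp + fp  # predicted positives
  r2 <- fn + tn
  if (min(c1, c2, r1, r2) == 0L) return(1)
  k <- max(0L, r1 - c2):min(r1, c1)
  d <- dhyper(k, c1, c2, r1)
  p_obs <- dhyper(tp, c1, c2, r1)
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Fisher-optimal dichotomization of a continuous predictor
#'
#' Scans every candidate threshold (midpoints between consecutive sorted
#' distinct values) and returns the one minimizing the two-sided Fisher
#' exact p of the resulting 2x2 truth table. Cases are called positive when
#' the oriented value lies at or above the threshold (`orientation = -1`
#' flips the comparison to "at or below"), so a positive call always points
#' toward the positive class. Fisher-p ties are broken toward the candidate
#' maximizing Youden's J (sensitivity + specificity - 1), then toward the
#' smaller threshold.
#'
#' @param values numeric feature values (at least 2 distinct).
#' @param labels class labels.
#' @param positive the positive-class label.
#' @param orientation +1 or -1; see [roc_auc].
#' @return A list: `threshold` (original scale), `direction` (`">="` or
#'   `"<="`), `fisher_p`, and the truth table `tp`, `fp`, `fn`, `tn`.
#' @export
optimal_dichotomization <- function(values, labels, positive = "malignant",
                                    orientation = 1L) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  y <- labels[ok] == positive
  if (!any(y) || all(y)) stopf("both classes must be present")
  v <- orientation * values
  dv <- sort(unique(v))
  if (length(dv) < 2L) stopf("need at least 2 distinct values to dichotomize")
  cand <- (dv[-1L] + dv[-length(dv)]) / 2
  n_pos <- sum(y)
  n_neg <- sum(!y)
  res <- vapply(cand, function(t) {
    pred <- v >= t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- n_pos - tp; tn <- n_neg - fp
    c(p = fisher_exact_p(tp, fp, fn, tn),
      j = tp / n_pos + tn / n_neg - 1,
      tp = tp, fp = fp, fn = fn, tn = tn)
  }, numeric(6))
  p <- res["p", ]
  best_p <- min(p)
  sel <- which(p <= best_p * (1 + 1e-12))
  sel <- sel[order(-res["j", sel], orientation * cand[sel])]
  b <- sel[1L]
  list(
    threshold = orientation * cand[b],
    direction = if (orientation >= 0) ">=" else "<=",
    fisher_p = unname(p[b]),
    tp = unname(res["tp", b]), fp = unname(res["fp", b]),
    fn = unname(res["fn", b]), tn = unname(res["tn", b])
  )
}

#' Predictive scores of a truth table
#'
#' Sensitivity, specificity, PPV and NPV of a 2x2 truth table, in percent at
#' full precision. Ratios with a zero denominator are `NaN`.
#'
#' @param tp,fp,fn,tn truth-table counts.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv` (%).
#' @export
predictive_scores <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b == 0) NaN else 100 * a / b
  tibble::tibble(
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn)
  )
}

#' Reconstruct an integer truth table from rounded predictive scores
#'
#' Given a sensitivity and specificity printed as integer percents and the
#' class sizes, recovers the integer confusion matrix: TP is the count in
#' `0..n_pos` whose rounded sensitivity percent matches (ties resolved
#' toward the unrounded value), and TN likewise. Used to audit published
#' per-predictor score tables.
#'
#' @param sensitivity_pct,specificity_pct printed integer percents.
#' @param n_pos,n_neg class sizes.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn` and the recomputed
#'   full-precision scores of [predictive_scores].
#' @export
reconstruct_truth_table <- function(sensitivity_pct, specificity_pct,
                                    n_pos, n_neg) {
  pick <- function(target_pct, n) {
    k <- 0:n
    pct <- round(100 * k / n)
    hit <- which(pct == target_pct)
    if (length(hit) == 0L) {
      stopf("no integer count out of %d reproduces %d%%", n, target_pct)
    }
    k[hit[which.min(abs(k[hit] - target_pct * n / 100))]]
  }
  tp <- pick(sensitivity_pct, n_pos)
  tn <- pick(specificity_pct, n_neg)
  dplyr::bind_cols(
    tibble::tibble(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn),
    predictive_scores(tp, n_neg - tn, n_pos - tp, tn)
  )
}

#' Mutual-correlation audit of a feature subset
#'
#' Pairwise Pearson correlations on pairwise-complete rows, with a two-sided
#' t-test significance flag at the given level. No feature is removed on the
#' basis of correlation; the audit only documents redundancy.
#'
#' @param data data frame holding the features.
#' @param features character vector of feature columns to audit.
#' @param alpha significance level for the flag (default 0.01).
#' @return A list: `r` (correlation matrix), `p` (t-test p-values),
#'   `significant` (logical flags, `r` diagonal excluded), and `pairs`, a
#'   long tibble of the upper-triangle pairs.
#' @export
correlation_audit <- function(data, features, alpha = 0.01) {
  m <- as.matrix(data[features])
  k <- length(features)
  r <- matrix(NA_real_, k, k, dimnames = list(features, features))
  p <- matrix(NA_real_, k, k, dimnames = list(features, features))
  diag(r) <- 1
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (b <= a) next
      ok <- is.finite(m[, a]) & is.finite(m[, b])
      n <- sum(ok)
      if (n < 3L) next
      if (sd(m[ok, a]) == 0 || sd(m[ok, b]) == 0) next # undefined for constants
      rr <- stats::cor(m[ok, a], m[ok, b])
      r[a, b] <- r[b, a] <- rr
      tt <- rr * sqrt((n - 2) / max(1e-300, 1 - rr^2))
      p[a, b] <- p[b, a] <- 2 * pt(-abs(tt), df = n - 2)
    }
  }
  sig <- !is.na(p) & p < alpha
  pairs <- tidyr::expand_grid(feature_a = features, feature_b = features)
  pairs <- dplyr::filter(pairs, match(.data$feature_a, features) <
                           match(.data$feature_b, features))
  pairs$r <- r[cbind(pairs$feature_a, pairs$feature_b)]
  pairs$p <- p[cbind(pairs$feature_a, pairs$feature_b)]
  pairs$significant <- sig[cbind(pairs$feature_a, pairs$feature_b)]
  list(r = r, p = p, significant = sig, pairs = pairs, alpha = alpha)
}

#' Univariate predictor screening of a cohort feature table
#'
#' The full screening workflow on a per-subject feature table with a binary
#' outcome: per feature, one-way ANOVA against the cytology category and
#' against the final diagnosis, ROC/AUC with orientation; pre-selection at
#' `auc >= auc_min`; mutual-correlation audit of the pre-selected set;
#' Fisher-optimal dichotomization of each pre-selected feature; the final
#' predictor set keeps features with Fisher `p < fisher_alpha`; average PPV
#' and NPV are reported over the final set (averaging the integer-rounded
#' percents, as score tables print them). No multiple-testing correction is
#' applied; the report records this as a caveat.
#'
#' @param data data frame, one row per subject, holding the feature columns
#'   and the label columns.
#' @param outcome name of the binary outcome column (default `"label"`).
#' @param tir name of the cytology-category column, or `NULL` to skip the
#'   category ANOVA (default `"tir"`).
#' @param features character vector of feature columns; default: every
#'   [feature_catalog] feature present in `data`.
#' @param positive positive-class label (default `"malignant"`).
#' @param auc_min AUC pre-selection gate (default 0.55, kept when equal).
#' @param fisher_alpha final-selection gate on the Fisher p (default 0.08).
#' @param anova_alpha significance level annotated on the ANOVA results
#'   (default 0.05).
#' @param cor_alpha significance level of the correlation audit flags
#'   (default 0.01).
#' @param n_boot bootstrap resamples for AUC CIs (default 2000; 0 skips
#'   CIs, which speeds up large simulation studies).
#' @param seed integer seed for the bootstrap.
#' @return An object of class `screening_report`; see [tidy.screening_report]
#'   and [glance.screening_report].
#' @export
screen_features <- function(data, outcome = "label", tir = "tir",
                            features = NULL, positive = "malignant",
                            auc_min = 0.55, fisher_alpha = 0.08,
                            anova_alpha = 0.05, cor_alpha = 0.01,
                            n_boot = 2000L, seed = 1L) {
  if (is.null(features)) {
    features <- intersect(feature_catalog()$feature, names(data))
  }
  if (length(features) == 0L) stopf("no feature columns found in `data`")
  if (!outcome %in% names(data)) stopf("outcome column `%s` not found", outcome)
  y <- data[[outcome]]
  if (!positive %in% y) stopf("no `%s` cases in the outcome column", positive)
  tirv <- if (!is.null(tir) && tir %in% names(data)) data[[tir]] else NULL
  cat_tbl <- feature_catalog()
  rows <- purrr::map(features, function(f) {
    x <- data[[f]]
    fin <- is.finite(x)
    base <- tibble::tibble(
      feature = f,
      family = cat_tbl$family[match(f, cat_tbl$feature)],
      n_used = sum(fin & !is.na(y)),
      n_pos = sum(fin & y == positive, na.rm = TRUE),
      n_neg = sum(fin & y != positive, na.rm = TRUE),
      evaluable = FALSE,
      anova_f_tir = NA_real_, anova_p_tir = NA_real_,
      anova_f_diagnosis = NA_real_, anova_p_diagnosis = NA_real_,
      auc = NA_real_, orientation = NA_integer_,
      auc_ci_low = NA_real_, auc_ci_high = NA_real_,
      preselected = FALSE,
      best_threshold = NA_real_, direction = NA_character_,
      fisher_p = NA_real_,
      tp = NA_real_, fp = NA_real_, fn = NA_real_, tn = NA_real_,
      sensitivity = NA_real_, specificity = NA_real_,
      ppv = NA_real_, npv = NA_real_,
      final = FALSE
    )
    yy <- y[fin]
    if (sum(fin) < 3L || sum(yy == positive) == 0L ||
        sum(yy != positive) == 0L || length(unique(x[fin])) < 2L) {
      return(base) # not evaluable (e.g. all NaN under the 64-voxel gate)
    }
    base$evaluable <- TRUE
    if (!is.null(tirv)) {
      at <- try(anova_oneway(x, tirv, drop_empty = TRUE), silent = TRUE)
      if (!inherits(at, "try-error")) {
        base$anova_f_tir <- at$statistic
        base$anova_p_tir <- at$p_value
      }
    }
    ad <- anova_oneway(x, y, drop_empty = TRUE)
    base$anova_f_diagnosis <- ad$statistic
    base$anova_p_diagnosis <- ad$p_value
    rc <- roc_auc(x, y, positive = positive, n_boot = n_boot, seed = seed)
    base$auc <- rc$auc
    base$orientation <- rc$orientation
    base$auc_ci_low <- rc$ci_low
    base$auc_ci_high <- rc$ci_high
    base$preselected <- rc$auc >= auc_min
    if (base$preselected) {
      od <- optimal_dichotomization(x, y, positive = positive,
                                    orientation = rc$orientation)
      sc <- predictive_scores(od$tp, od$fp, od$fn, od$tn)
      base$best_threshold <- od$threshold
      base$direction <- od$direction
      base$fisher_p <- od$fisher_p
      base$tp <- od$tp; base$fp <- od$fp; base$fn <- od$fn; base$tn <- od$tn
      base$sensitivity <- sc$sensitivity
      base$specificity <- sc$specificity
      base$ppv <- sc$ppv
      base$npv <- sc$npv
      base$final <- od$fisher_p < fisher_alpha
    }
    base
  })
  results <- dplyr::bind_rows(rows)
  presel <- results$feature[results$preselected]
  correlation <- if (length(presel) >= 2L) {
    correlation_audit(data, presel, alpha = cor_alpha)
  } else {
    NULL
  }
  fin <- dplyr::filter(results, .data$final)
  summary_tbl <- tibble::tibble(
    n_features = nrow(results),
    n_evaluable = sum(results$evaluable),
    n_preselected = length(presel),
    n_final = nrow(fin),
    avg_ppv_pct = if (nrow(fin)) mean(round(fin$ppv)) else NA_real_,
    avg_npv_pct = if (nrow(fin)) mean(round(fin$npv)) else NA_real_,
    n_pos = sum(y == positive, na.rm = TRUE),
    n_neg = sum(y != positive, na.rm = TRUE)
  )
  structure(
    list(
      results = results,
      correlation = correlation,
      preselected = presel,
      final = fin$feature,
      summary = summary_tbl,
      settings = list(
        outcome = outcome, tir = tir, positive = positive,
        auc_min = auc_min, fisher_alpha = fisher_alpha,
        anova_alpha = anova_alpha, cor_alpha = cor_alpha,
        n_boot = n_boot, seed = seed,
        multiple_testing_correction = "none (univariate screen; interpret p-values as exploratory)"
      )
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<screening_report> %d features (%d evaluable), %d pre-selected (AUC >= %.2f), %d final (Fisher p < %.2f)\n",
    s$n_features, s$n_evaluable, s$n_preselected,
    x$settings$auc_min, s$n_final, x$settings$fisher_alpha
  ))
  if (s$n_final > 0) {
    cat("final predictors:", paste(x$final, collapse = ", "), "\n")
    cat(sprintf("average PPV %.0f%%, average NPV %.0f%%\n",
                s$avg_ppv_pct, s$avg_npv_pct))
  }
  cat("note:", x$settings$multiple_testing_correction, "\n")
  invisible(x)
}

#' Tidy a screening report
#'
#' @param x a `screening_report`.
#' @param ... unused.
#' @return The per-feature results tibble (one row per screened feature:
#'   ANOVA, AUC and CI, orientation, pre-selection flag, optimal threshold,
#'   Fisher p, truth table and predictive scores, final flag).
#' @export
tidy.screening_report <- function(x, ...) x$results

#' One-row summary of a screening report
#'
#' @param x a `screening_report`.
#' @param ... unused.
#' @return A one-row tibble: feature counts at each screening stage, average
#'   PPV/NPV over the final set, class sizes.
#' @export
glance.screening_report <- function(x, ...) x$summary

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a screening report to disk
#'
#' Emits `screening_report.json` (the full report), and three CSVs:
#' `predictors.csv` (per-feature screening results), `correlation.csv` (the
#' audit matrix of the pre-selected set) and `predictive_scores.csv`
#' (integer-rounded scores of the final predictors).
#'
#' @param report a `screening_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    summary = report$summary,
    settings = report$settings,
    preselected = report$preselected,
    final = report$final,
    results = report$results,
    correlation_pairs = if (!is.null(report$correlation)) report$correlation$pairs
  )
  jsonlite::write_json(out, file.path(dir, "screening_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  write.csv(report$results, file.path(dir, "predictors.csv"), row.names = FALSE)
  if (!is.null(report$correlation)) {
    write.csv(as.data.frame(report$correlation$r),
              file.path(dir, "correlation.csv"), row.names = TRUE)
  }
  fin <- dplyr::filter(report$results, .data$final)
  scores <- dplyr::transmute(
    fin, feature = .data$feature,
    specificity_pct = round(.data$specificity),
    sensitivity_pct = round(.data$sensitivity),
    ppv_pct = round(.data$ppv), npv_pct = round(.data$npv)
  )
  write.csv(scores, file.path(dir, "predictive_scores.csv"), row.names = FALSE)
  invisible(dir)
}

#' Published predictive scores of the seven thyroid-incidentaloma predictors
#'
#' Reference table of the predictive power reported for the seven final PET
#' predictors in the thyroid-incidentaloma cohort this pipeline re-implements
#' (32 benign / 18 malignant subjects; the GLCM correlation row comes from
#' the 16/12 subgroup with at least 64 ROI voxels). Scores are integer
#' percents as printed. Used to audit truth-table arithmetic: see
#' [reconstruct_truth_table].
#'
#' @return A tibble with `feature`, `specificity_pct`, `sensitivity_pct`,
#'   `ppv_pct`, `npv_pct`, `n_pos`, `n_neg`.
#' @export
reference_predictor_scores <- function() {
  tibble::tribble(
    ~feature, ~specificity_pct, ~sensitivity_pct, ~ppv_pct, ~npv_pct, ~n_pos, ~n_neg,
    "suv_std", 88, 44, 67, 74, 18L, 32L,
    "suv_max", 81, 50, 60, 74, 18L, 32L,
    "mtv_ml", 44, 89, 47, 88, 18L, 32L,
    "tlg_ml", 66, 72, 54, 81, 18L, 32L,
    "skewness", 69, 72, 57, 81, 18L, 32L,
    "kurtosis", 19, 100, 41, 100, 18L, 32L,
    "glcm_correlation", 31, 100, 52, 100, 12L, 16L
  )
}

#' Reference cohort counts of the source study
#'
#' The screening-study denominators used for printed-count arithmetic:
#' 17,104 PET scans of which 453 showed incidental thyroid uptake; a final
#' analysis cohort of 50 subjects with 18 malignant nodules, of whom 28 had
#' at least 64 ROI voxels (12 malignant / 16 benign).
#'
#' @return A named list of integer counts.
#' @export
reference_cohort_counts <- function() {
  list(
    n_scans = 17104L, n_thyroid_uptake = 453L,
    n_cohort = 50L, n_malignant = 18L,
    n_texture_evaluable = 28L, n_texture_malignant = 12L
  )
}
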