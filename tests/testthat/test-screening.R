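test_that("one-way ANOVA matches hand computation and classical identities", {
  # identical groups: no between-group variation
  r <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # {1,2} vs {3,4}: SSB = 4, SSW = 1, df = (1, 2) -> F = 8
  r2 <- anova_oneway(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r2$statistic, 8)
  expect_equal(r2$df, c(1, 2))
  expect_equal(r2$p_value, pf(8, 1, 2, lower.tail = FALSE))
  # two groups: F equals the squared pooled t statistic
  set.seed(3)
  x <- rnorm(30)
  g <- rep(c("a", "b"), 15)
  tt <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
  r3 <- anova_oneway(x, g)
  expect_equal(r3$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(r3$p_value, tt$p.value, tolerance = 1e-12)
  # agreement with stats::oneway.test across 5 groups with NaN dropped
  x5 <- c(rnorm(40), NaN, NaN)
  g5 <- sample(paste0("TIR", 1:5), 42, replace = TRUE)
  r5 <- anova_oneway(x5, g5, drop_empty = TRUE)
  ow <- oneway.test(x5[1:40] ~ factor(g5[1:40]), var.equal = TRUE)
  expect_equal(r5$p_value, unname(ow$p.value), tolerance = 1e-12)
})

test_that("ANOVA degenerate and error contracts hold", {
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "a")), "2 non-empty groups")
  expect_error(anova_oneway(c(NaN, 2, 3, 4), c("a", "b", "b", "b")), "no observations")
  r <- anova_oneway(c(NaN, 2, 3, 4, 5), c("a", "b", "b", "c", "c"),
                    drop_empty = TRUE)
  expect_true(is.finite(r$p_value))
})

test_that("AUC handles perfect separation, pure ties, and orientation", {
  r <- roc_auc(c(1, 2, 3, 4), c("b", "b", "m", "m"), positive = "m", n_boot = 0)
  expect_equal(r$auc, 1)
  expect_equal(r$orientation, 1L)
  r2 <- roc_auc(rep(2, 10), rep(c("b", "m"), 5), positive = "m", n_boot = 0)
  expect_equal(r2$auc, 0.5)
  # reversed feature: flipped orientation, same oriented AUC
  r3 <- roc_auc(-c(1, 2, 3, 4), c("b", "b", "m", "m"), positive = "m", n_boot = 0)
  expect_equal(r3$auc, 1)
  expect_equal(r3$orientation, -1L)
  expect_error(roc_auc(1:4, rep("b", 4), positive = "m", n_boot = 0),
               "both classes")
})

test_that("AUC equals exhaustive pair counting and pROC on random data", {
  set.seed(12)
  v <- round(rnorm(200), 1) # rounding forces ties
  lab <- sample(c("benign", "malignant"), 200, replace = TRUE, prob = c(0.6, 0.4))
  r <- roc_auc(v, lab, n_boot = 0)
  oracle <- oracle_auc_paircount(v, lab, "malignant")
  expect_equal(max(oracle, 1 - oracle), r$auc, tolerance = 1e-12)
  p <- as.numeric(pROC::auc(pROC::roc(lab, v, levels = c("benign", "malignant"),
                                      direction = "auto", quiet = TRUE)))
  expect_equal(r$auc, p, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(21)
  v <- rnorm(80)
  lab <- sample(c("benign", "malignant"), 80, replace = TRUE)
  a1 <- roc_auc(v, lab, n_boot = 0)$auc
  expect_equal(roc_auc(exp(v), lab, n_boot = 0)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_auc(atan(3 * v + 1), lab, n_boot = 0)$auc, a1, tolerance = 1e-12)
})

test_that("the bootstrap CI is seeded, ordered, and brackets the point estimate", {
  set.seed(4)
  v <- rnorm(50) + rep(c(0, 1), c(30, 20))
  lab <- rep(c("benign", "malignant"), c(30, 20))
  r1 <- roc_auc(v, lab, n_boot = 500, seed = 9)
  r2 <- roc_auc(v, lab, n_boot = 500, seed = 9)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, r1$auc)
  expect_gte(r1$ci_high, r1$auc)
})

test_that("Fisher exact p matches closed forms and full enumeration", {
  expect_equal(fisher_exact_p(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_p(0, 0, 3, 4), 1) # zero margin
  # every table with grand total <= 8 against the enumeration oracle and
  # against stats::fisher.test
  for (n in 1:8) {
    parts <- expand.grid(tp = 0:n, fp = 0:n, fn = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    parts$tn <- n - rowSums(parts)
    for (i in seq_len(nrow(parts))) {
      tb <- as.integer(parts[i, c("tp", "fp", "fn", "tn")])
      p <- fisher_exact_p(tb[1], tb[2], tb[3], tb[4])
      expect_equal(p, oracle_fisher_two_sided(tb[1], tb[2], tb[3], tb[4]),
                   tolerance = 1e-10)
      ft <- fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
      expect_equal(p, ft, tolerance = 1e-7)
    }
  }
})

test_that("optimal dichotomization achieves the exhaustive-split minimum", {
  set.seed(30)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    v <- round(rnorm(n), 1)
    lab <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(lab)) < 2 || length(unique(v)) < 2) next
    od <- optimal_dichotomization(v, lab)
    # oracle: evaluate every split position by brute force
    dv <- sort(unique(v))
    ps <- vapply((dv[-1] + dv[-length(dv)]) / 2, function(t) {
      pred <- v >= t
      y <- lab == "malignant"
      oracle_fisher_two_sided(sum(pred & y), sum(pred & !y),
                              sum(!pred & y), sum(!pred & !y))
    }, numeric(1))
    expect_equal(od$fisher_p, min(ps), tolerance = 1e-10)
    # the reported truth table reproduces the reported p
    expect_equal(fisher_exact_p(od$tp, od$fp, od$fn, od$tn), od$fisher_p,
                 tolerance = 1e-12)
  }
})

test_that("a separable predictor reaches the diagonal-table Fisher p", {
  v <- c(1, 2, 3, 10, 11, 12)
  lab <- rep(c("benign", "malignant"), each = 3)
  od <- optimal_dichotomization(v, lab)
  expect_equal(od$fp + od$fn, 0)
  expect_equal(od$fisher_p, fisher_exact_p(3, 0, 0, 3), tolerance = 1e-12)
  expect_error(optimal_dichotomization(rep(1, 6), lab), "distinct")
})

test_that("threshold optimization is optimistic relative to a fixed threshold under the null", {
  set.seed(14)
  n <- 40
  v <- rnorm(n)
  reps <- 200
  min_p <- numeric(reps)
  fixed_p <- numeric(reps)
  for (i in seq_len(reps)) {
    lab <- sample(rep(c("benign", "malignant"), each = n / 2))
    min_p[i] <- optimal_dichotomization(v, lab)$fisher_p
    pred <- v >= median(v)
    y <- lab == "malignant"
    fixed_p[i] <- fisher_exact_p(sum(pred & y), sum(pred & !y),
                                 sum(!pred & y), sum(!pred & !y))
  }
  expect_lt(mean(min_p), mean(fixed_p))
  expect_lt(median(min_p), median(fixed_p))
})

test_that("predictive scores reproduce published rows and handle zero denominators", {
  r1 <- predictive_scores(18, 26, 0, 6)
  expect_equal(round(unlist(r1)), c(sensitivity = 100, specificity = 19,
                                    ppv = 41, npv = 100))
  r2 <- predictive_scores(12, 11, 0, 5)
  expect_equal(round(unlist(r2)), c(sensitivity = 100, specificity = 31,
                                    ppv = 52, npv = 100))
  r3 <- predictive_scores(0, 0, 5, 5)
  expect_true(is.nan(r3$ppv))
  expect_equal(r3$specificity, 100)
})

test_that("truth tables reconstructed from printed percents are consistent", {
  tt <- reconstruct_truth_table(44, 88, 18, 32)
  expect_equal(tt$tp + tt$fn, 18)
  expect_equal(tt$tn + tt$fp, 32)
  expect_equal(round(tt$sensitivity), 44)
  expect_equal(round(tt$specificity), 88)
  expect_error(reconstruct_truth_table(37, 50, 4, 4), "no integer")
})

test_that("correlation audit matches a hand oracle and flags exact dependence", {
  set.seed(8)
  d <- tibble::tibble(x = rnorm(10))
  d$y <- 2 * d$x + 3
  d$z <- rnorm(10)
  d$const <- 1
  au <- correlation_audit(d, c("x", "y", "z", "const"))
  expect_equal(diag(au$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(au$r["x", "y"], 1, tolerance = 1e-12)
  expect_true(au$significant["x", "y"])
  expect_true(is.na(au$r["x", "const"])) # undefined for a constant feature
  # hand oracle for r(x, z)
  rx <- sum((d$x - mean(d$x)) * (d$z - mean(d$z))) /
    sqrt(sum((d$x - mean(d$x))^2) * sum((d$z - mean(d$z))^2))
  expect_equal(au$r["x", "z"], rx, tolerance = 1e-12)
  expect_equal(au$p["x", "z"], cor.test(d$x, d$z)$p.value, tolerance = 1e-10)
})

test_that("screen_features applies the AUC pre-selection gate inclusively at the boundary", {
  # crafted features with pair-count AUC exactly 0.55 and 0.54 (n1=5, n0=10)
  lab <- rep(c("malignant", "benign"), c(5, 10))
  at_gate <- c(10.5, 9.5, 5.5, 4, 0.5, 1:10)      # U = 27.5 -> 0.55
  below <- c(10.5, 9.5, 5.5, 3.5, 0.5, 1:10)      # U = 27   -> 0.54
  expect_equal(oracle_auc_paircount(at_gate, lab, "malignant"), 0.55)
  expect_equal(oracle_auc_paircount(below, lab, "malignant"), 0.54)
  d <- tibble::tibble(label = lab, suv_max = at_gate, suv_min = below)
  rep <- screen_features(d, tir = NULL, n_boot = 0)
  res <- tidy(rep)
  expect_true(res$preselected[res$feature == "suv_max"])
  expect_false(res$preselected[res$feature == "suv_min"])
})

test_that("screening a cohort yields consistent truth-table identities and tidiers", {
  co <- make_cohort(cohort_spec(rng_seed = 77))
  feats <- extract_cohort_features(co$phantoms, co$cohort)
  rep <- screen_features(feats, n_boot = 200, seed = 7)
  res <- tidy(rep)
  sel <- dplyr::filter(res, .data$preselected)
  expect_gt(nrow(sel), 0)
  # truth-table identities hold within each feature's evaluable subset
  # (texture features screen on the >= 64-voxel subgroup only)
  expect_true(all(sel$tp + sel$fn == sel$n_pos))
  expect_true(all(sel$tn + sel$fp == sel$n_neg))
  expect_true(all(sel$auc >= 0.55))
  expect_true(all(res$auc[res$evaluable] >= 0.5 - 1e-12))
  expect_true(all(res$final[res$final] & res$preselected[res$final]))
  # all-NaN features (none here) would be flagged not evaluable; check the
  # gating instead: features NaN for small ROIs still screen on the subset
  expect_true(all(res$n_used[res$family == "glcm"] ==
                    sum(feats$roi_voxel_count >= 64)))
  g <- glance(rep)
  expect_equal(g$n_pos, 18)
  expect_equal(g$n_neg, 32)
  expect_equal(g$n_final, length(rep$final))
  # determinism under the seed
  rep2 <- screen_features(feats, n_boot = 200, seed = 7)
  expect_identical(tidy(rep2), res)
  # a feature with no finite values is reported not evaluable
  feats$glcm_energy <- NaN
  rep3 <- screen_features(feats, n_boot = 0)
  expect_false(tidy(rep3)$evaluable[tidy(rep3)$feature == "glcm_energy"])
})

test_that("an injected effect is screened in while pure noise is screened in less often", {
  set.seed(42)
  n_runs <- 20
  hits_eff <- 0
  hits_noise <- 0
  for (i in seq_len(n_runs)) {
    lab <- rep(c("malignant", "benign"), c(18, 32))
    d <- tibble::tibble(
      label = lab,
      skewness = rnorm(50, ifelse(lab == "malignant", 1.3, 0), 0.6), # AUC ~ .94
      suv_min = rnorm(50) # pure noise
    )
    rep <- screen_features(d, tir = NULL, n_boot = 0)
    hits_eff <- hits_eff + ("skewness" %in% rep$final)
    hits_noise <- hits_noise + ("suv_min" %in% rep$final)
  }
  expect_gte(hits_eff, 18) # >= 90% recovery of a strong effect
  expect_lt(hits_noise, hits_eff)
})
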