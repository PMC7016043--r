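test_that("a constant target is predicted exactly with zero error", {
  ds <- toy_dataset(n_term = 6, n_preterm = 6, seed = 4)
  ds$subjects$pma_scan <- rep(40, 12)
  ds$subjects$pma_birth <- pmin(ds$subjects$pma_birth, 39)
  edges <- cohort_edges(ds)
  cv <- age_regression_cv(edges, ds$subjects, fast_reg_cfg(), "loocv")
  expect_equal(unname(cv$predicted), rep(40, 12), tolerance = 1e-12)
  expect_equal(cv$summary$mae, 0)
})

test_that("planted age signal is recovered better than the baselines", {
  ds <- generate_cohort(synthetic_config(n_term = 20, n_preterm = 20,
                                         atlas = toy_atlas(), seed = 7,
                                         noise_sd = 0.3))
  edges <- cohort_edges(ds)
  cv <- age_regression_cv(edges, ds$subjects, fast_reg_cfg(7), "loocv")
  mean_mae <- mean(abs(ds$subjects$pma_scan - mean(ds$subjects$pma_scan)))
  expect_lt(cv$summary$mae, mean_mae)
  confounds <- baseline_confounds_only(ds$subjects, "regression", "loocv")
  expect_lt(cv$summary$mae, confounds$summary$mae)
  # an OLS oracle on the single generative latent (scan age itself drives
  # the drift) bounds how well any edge model can do: the elastic net on
  # thousands of derived features should land within 3x of it
  expect_lt(cv$summary$mae, 3 * mean(abs(
    stats::residuals(stats::lm(pma_scan ~ ., data.frame(
      pma_scan = ds$subjects$pma_scan,
      x = rowMeans(edges[, partition_edges(toy_atlas())$left]))))))
    + 0.5)
  expect_gt(cv$summary$r, 0.5)
})

test_that("LOOCV predictions are invariant to subject ordering", {
  ds <- toy_dataset(n_term = 7, n_preterm = 7, seed = 9)
  edges <- cohort_edges(ds)
  cfg <- fast_reg_cfg(9)
  cv1 <- age_regression_cv(edges, ds$subjects, cfg, "loocv")
  set.seed(1)
  perm <- sample(nrow(edges))
  cv2 <- age_regression_cv(edges[perm, ], ds$subjects[perm, ], cfg, "loocv")
  ord <- match(cv1$subject_id, cv2$subject_id)
  expect_equal(unname(cv2$predicted[ord]), unname(cv1$predicted),
               tolerance = 1e-8)
})

test_that("held-out subjects do not leak into fitting (duplication probe)", {
  ds <- toy_dataset(n_term = 7, n_preterm = 7, seed = 13)
  edges <- cohort_edges(ds)
  cfg <- fast_reg_cfg(13)
  cv <- age_regression_cv(edges, ds$subjects, cfg, "loocv")
  # refit with subject 1 present in training: its prediction must move
  X <- cbind(edges, as.matrix(ds$subjects[, cfg$confounds]))
  fit_with <- neomsn:::fit_enet_fold(X, ds$subjects$pma_scan,
                                     ds$subjects$subject_id, cfg)
  pred_with <- fit_with$predict(X[1, , drop = FALSE])
  expect_false(isTRUE(all.equal(pred_with, cv$predicted[1], tolerance = 1e-10)))
  # and including it brings the prediction closer to its true value
  expect_lte(abs(pred_with - ds$subjects$pma_scan[1]),
             abs(cv$predicted[1] - ds$subjects$pma_scan[1]) + 1e-8)
})

test_that("repeated k-fold summary MAE lies within per-repeat range", {
  ds <- toy_dataset(n_term = 8, n_preterm = 8, seed = 21)
  edges <- cohort_edges(ds)
  cfg <- fast_reg_cfg(21)
  cfg$repeats <- 3
  cv <- age_regression_cv(edges, ds$subjects, cfg, "repeated_kfold")
  expect_gte(cv$summary$mae, min(cv$per_repeat) - 1e-12)
  expect_lte(cv$summary$mae, max(cv$per_repeat) + 1e-12)
  expect_equal(nrow(cv$fold_masks), 3 * cfg$k)
})

test_that("separable groups are classified nearly perfectly", {
  # the planted group effect hits fronto-temporal/subcortical regions, so
  # the atlas needs enough of them for clean separation
  ds <- generate_cohort(synthetic_config(n_term = 20, n_preterm = 20,
                                         atlas = synthetic_atlas(4, 4, 2),
                                         group_effect = 1.5, seed = 5))
  edges <- cohort_edges(ds)
  cv <- classification_cv(edges, ds$subjects, fast_cls_cfg(5), "loocv")
  expect_gte(cv$summary$accuracy, 0.95)
  # separability oracle: linear discriminant on the strongest mean contrast
  contrast <- colMeans(edges[ds$subjects$group == "preterm", , drop = FALSE]) -
    colMeans(edges[ds$subjects$group == "term", , drop = FALSE])
  proj <- edges %*% contrast
  oracle_acc <- max(mean((proj > stats::median(proj)) ==
                           (ds$subjects$group == "preterm")),
                    mean((proj < stats::median(proj)) ==
                           (ds$subjects$group == "preterm")))
  expect_gte(oracle_acc, 0.95)
})

test_that("identical group feature distributions stay near chance", {
  ds <- generate_null_cohort(synthetic_config(n_term = 20, n_preterm = 20,
                                              atlas = toy_atlas(), seed = 3))
  edges <- cohort_edges(ds)
  cv <- classification_cv(edges, ds$subjects, fast_cls_cfg(3), "loocv")
  prior <- max(table(ds$subjects$group)) / nrow(edges)
  band <- 2.58 * sqrt(prior * (1 - prior) / nrow(edges))
  expect_lte(cv$summary$accuracy, prior + band)
})

test_that("degenerate class counts are rejected", {
  ds <- toy_dataset(n_term = 11, n_preterm = 1, seed = 6)
  edges <- cohort_edges(ds)
  expect_error(classification_cv(edges, ds$subjects, fast_cls_cfg(), "loocv"),
               "insufficient class counts")
})

test_that("global-metric baselines compute their feature correctly", {
  ds <- toy_dataset(n_term = 6, n_preterm = 6, seed = 8)
  # hand-summed total brain volume for the first three subjects
  for (sid in ds$subjects$subject_id[1:3]) {
    expect_equal(sum(ds$tables[[sid]][, "Volume"]),
                 sum(ds$tables[[sid]][seq_len(nrow(ds$atlas)), "Volume"]))
  }
  # volume proportional to the target is recovered nearly exactly
  for (i in seq_len(12)) {
    ds$tables[[i]][, "Volume"] <- ds$subjects$pma_scan[i] * 100 *
      seq_len(nrow(ds$atlas))
  }
  cv <- baseline_global_metric(ds, "total_brain_volume", "regression",
                               "loocv", fast_reg_cfg())
  expect_lt(cv$summary$mae, 0.15)
  # atlas without WM ROIs cannot provide a median WM FA
  ds_nowm <- ds
  ds_nowm$atlas$tissue_class[ds_nowm$atlas$tissue_class == "WM"] <- "cGM"
  expect_error(baseline_global_metric(ds_nowm, "median_wm_fa", "regression"),
               "no WM")
})

test_that("concatenated-metrics baseline has n_roi x n_metric features", {
  ds <- toy_dataset(n_term = 6, n_preterm = 6, seed = 10)
  cv <- baseline_concatenated_metrics(ds, metric_names()[1:4], "regression",
                                      "loocv", fast_reg_cfg())
  expect_equal(cv$n_edge_features, nrow(ds$atlas) * 4)
  # constant columns are dropped with a warning
  for (sid in ds$subjects$subject_id) ds$tables[[sid]][, "ISO"] <- 0.08
  expect_warning(
    baseline_concatenated_metrics(ds, c("FA", "MD", "ISO"), "regression",
                                  "loocv", fast_reg_cfg()),
    "constant")
})

test_that("confounds-only baselines behave at the extremes", {
  ds <- toy_dataset(n_term = 8, n_preterm = 8, seed = 13)
  meta <- ds$subjects
  # covariate equal to the target: zero error
  meta$pma_birth <- meta$pma_scan
  cv <- baseline_confounds_only(meta, "regression", "loocv")
  expect_lt(cv$summary$mae, 1e-8)
  # covariate equal to the group label: perfect accuracy
  meta2 <- ds$subjects
  meta2$motion_abs <- as.numeric(meta2$group == "preterm")
  cv2 <- baseline_confounds_only(meta2, "classification", "loocv",
                                 covariates = "motion_abs")
  expect_equal(cv2$summary$accuracy, 1)
  # target independent of covariates: no better than mean prediction
  meta3 <- ds$subjects
  set.seed(13)
  meta3$pma_scan <- pmax(40 + stats::rnorm(16), meta3$pma_birth + 0.5)
  cv3 <- baseline_confounds_only(meta3, "regression", "loocv")
  mean_mae <- mean(abs(meta3$pma_scan - mean(meta3$pma_scan)))
  expect_lt(abs(cv3$summary$mae - mean_mae), 0.5 * mean_mae + 0.2)
})

test_that("model comparison uses the paired signed-rank convention", {
  ds <- toy_dataset(n_term = 6, n_preterm = 6, seed = 2)
  cv <- baseline_confounds_only(ds$subjects, "regression", "loocv")
  same <- compare_models(cv, cv)
  expect_equal(same$p_value, 1)
  # a uniformly shifted error vector is detected
  shifted <- cv
  shifted$abs_errors <- cv$abs_errors + 0.5
  res <- compare_models(shifted, cv)
  expect_lt(res$p_value, 0.01)
  short <- cv
  short$abs_errors <- cv$abs_errors[1:5]
  expect_error(compare_models(short, cv), "different numbers")
})
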