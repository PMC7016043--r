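#' @title Baseline models
#' @description The comparison models run through the same cross-validation
#'   machinery as the MSN models: single global brain metrics (total brain
#'   volume, median white-matter FA), concatenated regional metrics, and
#'   confounds-only ordinary linear / logistic regressions.
#' @name baselines
NULL

# Dispatch a feature matrix through the task-appropriate CV model.
.run_task <- function(features, meta, task, scheme, cfg) {
  if (task == "regression") {
    if (is.null(cfg)) cfg <- regression_config()
    age_regression_cv(features, meta, cfg, scheme)
  } else {
    if (is.null(cfg)) cfg <- classification_config()
    classification_cv(features, meta, cfg, scheme)
  }
}

#' Global-metric baseline
#'
#' A single global feature — the sum of all ROI volumes, or the median FA
#' over white-matter ROIs — evaluated through the same cross-validated
#' model as the MSN features.
#'
#' @param ds An \code{msn_dataset}.
#' @param which \code{"total_brain_volume"} or \code{"median_wm_fa"}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param scheme CV scheme.
#' @param cfg Optional model configuration ([regression_config()] or
#'   [classification_config()]).
#' @return An \code{msn_cv}.
#' @export
baseline_global_metric <- function(ds, which = c("total_brain_volume",
                                                 "median_wm_fa"),
                                   task = c("regression", "classification"),
                                   scheme = "loocv", cfg = NULL) {
  which <- match.arg(which)
  task <- match.arg(task)
  sids <- ds$subjects$subject_id
  if (which == "total_brain_volume") {
    x <- vapply(sids, function(s) sum(ds$tables[[s]][, "Volume"]), numeric(1))
  } else {
    wm <- ds$atlas$tissue_class == "WM"
    if (!any(wm)) stop("atlas contains no WM ROIs", call. = FALSE)
    x <- vapply(sids, function(s) stats::median(ds$tables[[s]][wm, "FA"]),
                numeric(1))
  }
  features <- matrix(x, ncol = 1, dimnames = list(sids, which))
  .run_task(features, ds$subjects, task, scheme, cfg)
}

#' Concatenated regional-metrics baseline
#'
#' Instead of similarities, the predictors are the concatenation of all
#' regional values of each metric in the subset (n_roi x |subset| features
#' per subject). Constant columns are dropped with a warning; remaining
#' columns are standardized in-fold by the CV machinery.
#'
#' @param ds An \code{msn_dataset}.
#' @param subset Metric names.
#' @inheritParams baseline_global_metric
#' @return An \code{msn_cv}.
#' @export
baseline_concatenated_metrics <- function(ds, subset = metric_names(),
                                          task = c("regression", "classification"),
                                          scheme = "loocv", cfg = NULL) {
  task <- match.arg(task)
  subset <- canonical_metric_order(subset)
  sids <- ds$subjects$subject_id
  features <- do.call(rbind, lapply(sids, function(s) {
    as.vector(ds$tables[[s]][, subset, drop = FALSE])
  }))
  colnames(features) <- as.vector(outer(ds$atlas$roi_name, subset, paste,
                                        sep = ":"))
  rownames(features) <- sids
  const <- apply(features, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature column(s)")
    features <- features[, !const, drop = FALSE]
  }
  .run_task(features, ds$subjects, task, scheme, cfg)
}

#' Confounds-only baseline
#'
#' Ordinary linear regression (age task) or logistic regression
#' (classification task) on the named covariates only, evaluated under the
#' same cross-validation scheme. This is the demographic reference model:
#' if MSN features only encoded demographics, they could not beat it.
#'
#' @param meta Metadata data.frame.
#' @param task \code{"regression"} (default covariates \code{sex},
#'   \code{pma_birth}) or \code{"classification"} (default \code{pma_scan},
#'   \code{sex}).
#' @param scheme \code{"loocv"} or \code{"repeated_kfold"}.
#' @param covariates Metadata columns used as predictors.
#' @param repeats,k,seed Repeated k-fold parameters.
#' @return An \code{msn_cv}.
#' @export
baseline_confounds_only <- function(meta, task = c("regression", "classification"),
                                    scheme = c("loocv", "repeated_kfold"),
                                    covariates = NULL, repeats = 10, k = 5,
                                    seed = 1) {
  task <- match.arg(task)
  scheme <- match.arg(scheme)
  if (is.null(covariates)) {
    covariates <- if (task == "regression") c("sex", "pma_birth")
                  else c("pma_scan", "sex")
  }
  n <- nrow(meta)
  ids <- meta$subject_id
  X <- as.data.frame(meta[, covariates, drop = FALSE])
  if (task == "regression") {
    y <- meta$pma_scan
    fit_pred <- function(tr) {
      d <- cbind(.y = y[tr], X[tr, , drop = FALSE])
      fit <- stats::lm(.y ~ ., data = d)
      as.vector(stats::predict(fit, newdata = X[!tr, , drop = FALSE]))
    }
  } else {
    y <- factor(meta$group, levels = c("term", "preterm"))
    fit_pred <- function(tr) {
      d <- cbind(.y = y[tr], X[tr, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
      p <- stats::predict(fit, newdata = X[!tr, , drop = FALSE],
                          type = "response")
      ifelse(p >= 0.5, "preterm", "term")
    }
  }
  run <- function(fold) {
    pred <- if (task == "regression") numeric(n) else character(n)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      pred[!tr] <- fit_pred(tr)
    }
    pred
  }
  truth <- if (task == "regression") y else as.character(y)
  if (scheme == "loocv") {
    pred <- run(seq_len(n))
    new_cv_result(task, scheme, ids, truth, pred, NULL, 0L)
  } else {
    per_repeat <- numeric(repeats)
    preds <- NULL
    for (r in seq_len(repeats)) {
      fold <- if (task == "regression") {
        stratified_percentile_folds(y, ids, k, 4, derive_seed(seed, "rep", r))
      } else {
        stratified_class_folds(y, ids, k, derive_seed(seed, "rep", r))
      }
      pred <- run(fold)
      per_repeat[r] <- if (task == "regression") mean(abs(pred - y))
                       else mean(pred == truth)
      preds <- rbind(preds, pred)
    }
    pred <- if (task == "regression") colMeans(preds)
            else apply(preds, 2, function(p) names(sort(-table(p)))[1])
    out <- new_cv_result(task, scheme, ids, truth, pred, NULL, 0L,
                         per_repeat = per_repeat)
    if (task == "regression") out$summary$mae <- mean(per_repeat)
    else out$summary$accuracy <- mean(per_repeat)
    out
  }
}

#' Compare two cross-validated models
#'
#' Paired Wilcoxon signed-rank test on per-subject absolute errors
#' (regression) or per-subject 0/1 losses (classification). Identical error
#' vectors yield p = 1 by convention (all zero differences are dropped, and
#' an empty difference set is treated as no evidence of a difference).
#'
#' @param a,b \code{msn_cv} objects over the same subjects.
#' @param paired Must be \code{TRUE} (only the paired comparison is
#'   meaningful across CV folds of the same cohort).
#' @param alternative Passed to the signed-rank test; \code{"greater"} tests
#'   whether \code{a}'s errors exceed \code{b}'s.
#' @return List with \code{W}, \code{p_value} and the error difference
#'   summary.
#' @export
compare_models <- function(a, b, paired = TRUE, alternative = "two.sided") {
  stopifnot(paired)
  if (length(a$abs_errors) != length(b$abs_errors)) {
    stop("models were evaluated on different numbers of subjects",
         call. = FALSE)
  }
  d <- a$abs_errors - b$abs_errors
  res <- signed_rank_test(d, alternative = alternative)
  c(res, list(mean_difference = mean(d)))
}
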