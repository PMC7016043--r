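#' @title Brain-age regression
#' @description Cross-validated elastic-net regression of postmenstrual age
#'   at scan on MSN edge features. Hyperparameters (penalty mixing alpha and
#'   strength lambda) are re-tuned inside every training fold with a nested
#'   stratified cross-validation; confound covariates (sex and age at birth
#'   by default) are appended to the feature matrix and penalized like any
#'   other feature, and features are standardized inside each training fold
#'   using training statistics only.
#' @name regression
NULL

#' Configuration for the age-regression model
#'
#' @param alpha_grid Elastic-net mixing grid in (0, 1].
#' @param lambda_grid Penalty-strength grid (positive reals); default 20
#'   log-spaced values in [1e-3, 1e1].
#' @param inner_folds Folds of the nested tuning loop (default 3).
#' @param strat_bins Percentile bins used to stratify folds over the age
#'   range (default quartiles).
#' @param confounds Metadata columns appended to the features
#'   (default \code{sex} and \code{pma_birth}).
#' @param repeats,k Repeats and fold count of the \code{repeated_kfold}
#'   scheme (default 10 x 5).
#' @param seed Master seed; all fold assignments derive from it.
#' @return A list of class \code{regression_config}.
#' @export
regression_config <- function(alpha_grid = c(0.1, 0.5, 0.7, 0.9, 0.95, 1.0),
                              lambda_grid = 10^seq(-3, 1, length.out = 20),
                              inner_folds = 3, strat_bins = 4,
                              confounds = c("sex", "pma_birth"),
                              repeats = 10, k = 5, seed = 1) {
  stopifnot(length(alpha_grid) > 0, all(alpha_grid > 0 & alpha_grid <= 1),
            length(lambda_grid) > 0, all(lambda_grid > 0), inner_folds >= 2)
  structure(list(alpha_grid = alpha_grid,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 inner_folds = inner_folds, strat_bins = strat_bins,
                 confounds = confounds, repeats = repeats, k = k, seed = seed),
            class = "regression_config")
}

# Tune (alpha, lambda) by inner stratified CV minimizing MAE, then fit on
# the full training data. Ties broken towards the smallest lambda, then the
# smallest alpha. Returns prediction function and non-zero coefficient mask.
fit_enet_fold <- function(Xtr, ytr, ids, cfg) {
  p <- ncol(Xtr)
  if (stats::sd(ytr) == 0) {
    const <- ytr[1]
    return(list(predict = function(Xnew) rep(const, nrow(Xnew)),
                mask = rep(FALSE, p), alpha = NA_real_, lambda = NA_real_))
  }
  if (length(ytr) < 2 * cfg$inner_folds) {
    stop("fewer training subjects than the inner-fold requirement",
         call. = FALSE)
  }
  lambda <- cfg$lambda_grid
  fold <- stratified_percentile_folds(ytr, ids, cfg$inner_folds,
                                      cfg$strat_bins, cfg$seed)
  err <- matrix(0, length(cfg$alpha_grid), length(lambda))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    std <- std_fit(Xtr[tr, , drop = FALSE])
    Xi <- std_apply(Xtr[tr, , drop = FALSE], std)
    Xv <- std_apply(Xtr[!tr, , drop = FALSE], std)
    for (a in seq_along(cfg$alpha_grid)) {
      fit <- glmnet::glmnet(Xi, ytr[tr], alpha = cfg$alpha_grid[a],
                            lambda = lambda, standardize = FALSE)
      pred <- stats::predict(fit, Xv, s = lambda, exact = FALSE)
      err[a, ] <- err[a, ] + colSums(abs(pred - ytr[!tr]))
    }
  }
  best <- which(err == min(err), arr.ind = TRUE)
  # smallest lambda first (grid stored decreasing -> largest column index),
  # then smallest alpha
  best <- best[order(-best[, 2], best[, 1]), , drop = FALSE][1, ]
  alpha <- cfg$alpha_grid[best[1]]
  lam <- lambda[best[2]]
  std <- std_fit(Xtr)
  fit <- glmnet::glmnet(std_apply(Xtr, std), ytr, alpha = alpha,
                        lambda = lambda, standardize = FALSE)
  beta <- as.vector(stats::coef(fit, s = lam, exact = FALSE))[-1]
  list(predict = function(Xnew) {
    as.vector(stats::predict(fit, std_apply(Xnew, std), s = lam,
                             exact = FALSE))
  }, mask = beta != 0, alpha = alpha, lambda = lam)
}

#' Cross-validated age prediction from MSN edges
#'
#' Runs leave-one-out (or repeated stratified k-fold) cross-validation of an
#' elastic-net regression predicting \code{pma_scan}. Confound columns from
#' the metadata are appended to the feature matrix. Per-fold non-zero
#' coefficient masks are recorded for stability analysis.
#'
#' @param edges Subjects x features matrix (MSN edge vectors, or any feature
#'   matrix for baseline models); rownames are subject ids.
#' @param meta Metadata data.frame aligned with \code{edges} rows.
#' @param cfg A [regression_config()].
#' @param scheme \code{"loocv"} or \code{"repeated_kfold"}.
#' @return An object of class \code{msn_cv} with per-subject predictions,
#'   summary (MAE, SD of absolute errors, Pearson r) and per-fold masks.
#' @export
age_regression_cv <- function(edges, meta, cfg = regression_config(),
                              scheme = c("loocv", "repeated_kfold")) {
  scheme <- match.arg(scheme)
  n <- nrow(edges)
  if (n < 10) stop("need at least 10 subjects", call. = FALSE)
  if (nrow(meta) != n) stop("metadata rows must match edge rows", call. = FALSE)
  y <- meta$pma_scan
  ids <- meta$subject_id
  X <- cbind(edges, as.matrix(meta[, cfg$confounds, drop = FALSE]))
  colnames(X) <- c(paste0("edge_", seq_len(ncol(edges))), cfg$confounds)
  n_edge <- ncol(edges)

  run_folds <- function(fold) {
    pred <- numeric(n)
    masks <- list()
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- fit_enet_fold(X[tr, , drop = FALSE], y[tr], ids[tr], cfg)
      pred[!tr] <- fit$predict(X[!tr, , drop = FALSE])
      masks[[length(masks) + 1L]] <- fit$mask
    }
    list(pred = pred, masks = masks)
  }

  if (scheme == "loocv") {
    res <- run_folds(seq_len(n))
    # reorder masks to subject order used above (folds sorted by index)
    masks <- do.call(rbind, res$masks)
    new_cv_result("regression", scheme, ids, y, res$pred, masks, n_edge,
                  extra = list(feature_names = colnames(X)))
  } else {
    preds <- matrix(NA_real_, cfg$repeats, n)
    masks <- list()
    per_repeat <- numeric(cfg$repeats)
    for (r in seq_len(cfg$repeats)) {
      fold <- stratified_percentile_folds(y, ids, cfg$k, cfg$strat_bins,
                                          derive_seed(cfg$seed, "rep", r))
      res <- run_folds(fold)
      preds[r, ] <- res$pred
      per_repeat[r] <- mean(abs(res$pred - y))
      masks <- c(masks, res$masks)
    }
    pred_mean <- colMeans(preds)
    out <- new_cv_result("regression", scheme, ids, y, pred_mean,
                         do.call(rbind, masks), n_edge,
                         per_repeat = per_repeat,
                         extra = list(feature_names = colnames(X),
                                      predictions_by_repeat = preds))
    # summary MAE over all repeat-level predictions, as in repeated CV
    out$summary$mae <- mean(per_repeat)
    out$summary$mae_sd <- stats::sd(abs(as.vector(t(preds)) - rep(y, cfg$repeats)))
    out
  }
}
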