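#' @title Term/preterm classification
#' @description Cross-validated linear support-vector classification of
#'   term versus preterm birth from MSN edge features, with recursive
#'   feature elimination (SVM-RFE) as the embedded feature-selection step.
#'   Within each training fold, an outer 3-fold loop selects the SVM cost
#'   and an inner 4-fold loop selects the retained feature count for RFE;
#'   folds are stratified by group. Age at scan, sex and absolute motion are
#'   appended as covariates by default.
#' @name classification
NULL

#' Configuration for the classification model
#'
#' @param cost_grid SVM cost grid (positive reals).
#' @param rfe_grid Candidate retained-feature counts for RFE.
#' @param rfe_step Fraction of surviving features eliminated per RFE
#'   iteration (default 0.1).
#' @param outer_folds Folds of the cost-selection loop (default 3).
#' @param inner_folds Folds of the RFE-size selection loop (default 4).
#' @param confounds Metadata columns appended to the features (default
#'   \code{pma_scan}, \code{sex}, \code{motion_abs}).
#' @param repeats,k Repeats and folds of the \code{repeated_kfold} scheme.
#' @param seed Master seed.
#' @return A list of class \code{classification_config}.
#' @export
classification_config <- function(cost_grid = c(0.01, 0.1, 1, 10),
                                  rfe_grid = c(25, 50, 100, 200, 400, 800),
                                  rfe_step = 0.1, outer_folds = 3,
                                  inner_folds = 4,
                                  confounds = c("pma_scan", "sex", "motion_abs"),
                                  repeats = 10, k = 5, seed = 1) {
  stopifnot(length(cost_grid) > 0, all(cost_grid > 0),
            length(rfe_grid) > 0, all(rfe_grid >= 1),
            rfe_step > 0, rfe_step < 1, outer_folds >= 2, inner_folds >= 2)
  structure(list(cost_grid = sort(cost_grid),
                 rfe_grid = sort(unique(as.integer(rfe_grid))),
                 rfe_step = rfe_step, outer_folds = outer_folds,
                 inner_folds = inner_folds, confounds = confounds,
                 repeats = repeats, k = k, seed = seed),
            class = "classification_config")
}

# SVM-RFE importance ordering: iteratively fit a linear SVM, score features
# by squared weight, drop the weakest `step` fraction until `min_keep`
# survive. Returns feature indices ordered most- to least-important.
svm_rfe_order <- function(X, y, cost, step, min_keep) {
  p <- ncol(X)
  surviving <- seq_len(p)
  eliminated <- integer(0)
  min_keep <- max(1L, min(min_keep, p))
  while (length(surviving) > min_keep) {
    fit <- e1071::svm(X[, surviving, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    w2 <- as.vector(crossprod(fit$coefs, fit$SV))^2
    n_drop <- min(max(1L, floor(step * length(surviving))),
                  length(surviving) - min_keep)
    drop_local <- order(w2)[seq_len(n_drop)]
    # eliminated stored worst-first so reversing gives importance order
    eliminated <- c(surviving[drop_local[order(w2[drop_local])]], eliminated)
    surviving <- surviving[-drop_local]
  }
  fit <- e1071::svm(X[, surviving, drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = FALSE)
  w2 <- as.vector(crossprod(fit$coefs, fit$SV))^2
  c(surviving[order(-w2)], eliminated)
}

# Select the RFE retained-feature count by inner stratified CV at a given
# cost; ties prefer fewer features.
select_rfe_size <- function(X, y, ids, cost, cfg, seed) {
  grid <- pmin(cfg$rfe_grid, ncol(X))
  grid <- sort(unique(grid))
  if (length(grid) == 1) return(grid)
  fold <- stratified_class_folds(y, ids, cfg$inner_folds, seed)
  acc <- numeric(length(grid))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    std <- std_fit(X[tr, , drop = FALSE])
    Xi <- std_apply(X[tr, , drop = FALSE], std)
    Xv <- std_apply(X[!tr, , drop = FALSE], std)
    ord <- svm_rfe_order(Xi, y[tr], cost, cfg$rfe_step, min(grid))
    for (g in seq_along(grid)) {
      keep <- ord[seq_len(grid[g])]
      fit <- e1071::svm(Xi[, keep, drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      pred <- stats::predict(fit, Xv[, keep, drop = FALSE])
      acc[g] <- acc[g] + sum(pred == y[!tr])
    }
  }
  grid[which.max(acc)]   # which.max returns the first (fewest) on ties
}

# Full model selection and fit on one training set: outer CV over costs
# (each evaluated with its inner-selected RFE size), then final RFE fit.
fit_svm_fold <- function(Xtr, ytr, ids, cfg) {
  counts <- table(ytr)
  if (length(counts) < 2 || any(counts < max(cfg$outer_folds, cfg$inner_folds))) {
    stop("insufficient class counts for stratified folds", call. = FALSE)
  }
  cost <- cfg$cost_grid
  if (length(cost) > 1) {
    fold <- stratified_class_folds(ytr, ids, cfg$outer_folds,
                                   derive_seed(cfg$seed, "cost"))
    acc <- numeric(length(cost))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      std <- std_fit(Xtr[tr, , drop = FALSE])
      Xi <- std_apply(Xtr[tr, , drop = FALSE], std)
      Xv <- std_apply(Xtr[!tr, , drop = FALSE], std)
      for (ci in seq_along(cost)) {
        size <- select_rfe_size(Xi, ytr[tr], ids[tr], cost[ci], cfg,
                                derive_seed(cfg$seed, "rfe", f, ci))
        ord <- svm_rfe_order(Xi, ytr[tr], cost[ci], cfg$rfe_step, size)
        keep <- ord[seq_len(size)]
        fit <- e1071::svm(Xi[, keep, drop = FALSE], ytr[tr],
                          kernel = "linear", cost = cost[ci], scale = FALSE)
        acc[ci] <- acc[ci] + sum(stats::predict(fit, Xv[, keep, drop = FALSE]) == ytr[!tr])
      }
    }
    cost <- cost[which.max(acc)]   # smallest cost on ties
  }
  std <- std_fit(Xtr)
  Xs <- std_apply(Xtr, std)
  size <- select_rfe_size(Xs, ytr, ids, cost, cfg,
                          derive_seed(cfg$seed, "rfe-final"))
  ord <- svm_rfe_order(Xs, ytr, cost, cfg$rfe_step, size)
  keep <- sort(ord[seq_len(size)])
  fit <- e1071::svm(Xs[, keep, drop = FALSE], ytr, kernel = "linear",
                    cost = cost, scale = FALSE)
  mask <- rep(FALSE, ncol(Xtr))
  mask[keep] <- TRUE
  list(predict = function(Xnew) {
    stats::predict(fit, std_apply(Xnew, std)[, keep, drop = FALSE])
  }, mask = mask, cost = cost, size = size)
}

#' Cross-validated term/preterm classification from MSN edges
#'
#' Leave-one-out (or repeated stratified k-fold) evaluation of a linear SVM
#' with recursive feature elimination, re-tuned inside every training fold.
#' Accuracy is the fraction of correctly classified held-out subjects.
#'
#' @param edges Subjects x features matrix; rownames are subject ids.
#' @param meta Metadata data.frame aligned with \code{edges} rows; the
#'   target is \code{group} (\code{term}/\code{preterm}).
#' @param cfg A [classification_config()].
#' @param scheme \code{"loocv"} or \code{"repeated_kfold"}.
#' @return An object of class \code{msn_cv} with per-subject predicted
#'   classes, accuracy and per-fold RFE-retained feature masks.
#' @export
classification_cv <- function(edges, meta, cfg = classification_config(),
                              scheme = c("loocv", "repeated_kfold")) {
  scheme <- match.arg(scheme)
  n <- nrow(edges)
  if (n < 10) stop("need at least 10 subjects", call. = FALSE)
  y <- factor(meta$group, levels = c("term", "preterm"))
  if (any(table(y) < 2)) {
    stop("insufficient class counts for stratified folds", call. = FALSE)
  }
  ids <- meta$subject_id
  X <- cbind(edges, as.matrix(meta[, cfg$confounds, drop = FALSE]))
  colnames(X) <- c(paste0("edge_", seq_len(ncol(edges))), cfg$confounds)
  n_edge <- ncol(edges)

  run_folds <- function(fold) {
    pred <- character(n)
    masks <- list()
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- fit_svm_fold(X[tr, , drop = FALSE], droplevels(y[tr]), ids[tr], cfg)
      pred[!tr] <- as.character(fit$predict(X[!tr, , drop = FALSE]))
      masks[[length(masks) + 1L]] <- fit$mask
    }
    list(pred = pred, masks = masks)
  }

  if (scheme == "loocv") {
    res <- run_folds(seq_len(n))
    new_cv_result("classification", scheme, ids, as.character(y), res$pred,
                  do.call(rbind, res$masks), n_edge,
                  extra = list(feature_names = colnames(X)))
  } else {
    acc <- numeric(cfg$repeats)
    masks <- list()
    preds <- matrix(NA_character_, cfg$repeats, n)
    for (r in seq_len(cfg$repeats)) {
      fold <- stratified_class_folds(y, ids, cfg$k,
                                     derive_seed(cfg$seed, "rep", r))
      res <- run_folds(fold)
      preds[r, ] <- res$pred
      acc[r] <- mean(res$pred == as.character(y))
      masks <- c(masks, res$masks)
    }
    # majority vote across repeats as the per-subject prediction
    vote <- apply(preds, 2, function(p) names(sort(-table(p)))[1])
    out <- new_cv_result("classification", scheme, ids, as.character(y), vote,
                         do.call(rbind, masks), n_edge, per_repeat = acc,
                         extra = list(feature_names = colnames(X),
                                      predictions_by_repeat = preds))
    out$summary$accuracy <- mean(acc)
    out
  }
}
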