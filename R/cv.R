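#' @title Cross-validation plumbing
#' @description Deterministic, order-invariant fold construction and in-fold
#'   feature standardization shared by the regression and classification
#'   models. Fold assignment is computed from a canonical ordering of the
#'   training subjects (by target value, then subject id) and a seed derived
#'   from the configuration seed, so cross-validated predictions do not
#'   depend on the order in which subjects are supplied.
#' @name cv-plumbing
NULL

# Evaluate expr with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed from a master seed and string tags; stays below 2^31.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(seed) * 7919 + h) %% 2147483647L + 1)
}

# Stratified folds for a continuous target: subjects are ordered canonically
# (target value, then id), cut into percentile bins, shuffled within bins
# with the derived seed and dealt round-robin into k folds. Returns fold
# labels in the input order.
stratified_percentile_folds <- function(y, ids, k, bins = 4, seed = 1) {
  n <- length(y)
  if (k < 2 || n < k) stop("need at least k subjects for k folds", call. = FALSE)
  ord <- order(y, ids)
  bins <- max(1, min(bins, floor(n / k)))
  bin_of <- ceiling(seq_along(ord) / (n / bins))
  fold <- integer(n)
  with_seed(derive_seed(seed, "pctfolds", n, k, paste(sort(ids), collapse = ",")), {
    pos <- 1L
    for (b in unique(bin_of)) {
      members <- ord[bin_of == b]
      members <- members[sample.int(length(members))]
      for (m in members) {
        fold[m] <- ((pos - 1L) %% k) + 1L
        pos <- pos + 1L
      }
    }
  })
  fold
}

# Stratified folds for a class target: same proportions of each class per
# fold. Order-invariant via canonical ordering by (class, id).
stratified_class_folds <- function(y, ids, k, seed = 1) {
  n <- length(y)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < k)) {
    stop("insufficient class counts for stratified folds (need >= ", k,
         " per class)", call. = FALSE)
  }
  fold <- integer(n)
  with_seed(derive_seed(seed, "classfolds", n, k, paste(sort(ids), collapse = ",")), {
    for (cl in sort(unique(y))) {
      members <- which(y == cl)
      members <- members[order(ids[members])]
      members <- members[sample.int(length(members))]
      fold[members] <- ((seq_along(members) - 1L) %% k) + 1L
    }
  })
  fold
}

# In-fold standardization: fit on training rows only. Constant columns get
# unit scale (they become all-zero after centring).
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(X, fit) {
  sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
}

# Shared CVResult constructor.
new_cv_result <- function(task, scheme, subject_id, truth, predicted,
                          fold_masks, n_edge_features, per_repeat = NULL,
                          extra = list()) {
  if (task == "regression") {
    abs_err <- abs(predicted - truth)
    summary <- list(
      mae = mean(abs_err),
      mae_sd = stats::sd(abs_err),
      r = if (stats::sd(predicted) > 0 && stats::sd(truth) > 0) {
        stats::cor(predicted, truth)
      } else NA_real_
    )
  } else {
    correct <- predicted == truth
    summary <- list(accuracy = mean(correct))
    abs_err <- as.numeric(!correct)
  }
  structure(c(list(task = task, scheme = scheme, subject_id = subject_id,
                   truth = truth, predicted = predicted, abs_errors = abs_err,
                   summary = summary, fold_masks = fold_masks,
                   n_edge_features = n_edge_features, per_repeat = per_repeat),
              extra),
            class = "msn_cv")
}

#' @export
#' @method print msn_cv
print.msn_cv <- function(x, ...) {
  cat("<msn_cv> ", x$task, " / ", x$scheme, ", n = ", length(x$subject_id),
      "\n", sep = "")
  if (x$task == "regression") {
    cat(sprintf("  MAE = %.3f +/- %.3f weeks, r = %.3f\n",
                x$summary$mae, x$summary$mae_sd, x$summary$r))
  } else {
    cat(sprintf("  accuracy = %.3f\n", x$summary$accuracy))
  }
  invisible(x)
}
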