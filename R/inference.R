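#' @title Permutation inference, stability selection and classical tests
#' @name inference
NULL

#' Permutation test of a prediction pipeline
#'
#' Re-runs the full pipeline (including any nested tuning it performs) on
#' target permutations and computes a one-sided add-one p-value
#' (Phipson-Smyth convention): p = (1 + number of null scores at least as
#' good as the observed) / (1 + n_perm), which can never be exactly zero.
#' Permutations are drawn in a canonical subject ordering (by id when row
#' names are available), so the p-value is invariant to subject reordering
#' for a fixed seed.
#'
#' @param pipeline Function \code{(X, y) -> numeric score}.
#' @param X Feature matrix (rownames used as subject ids when present).
#' @param y Target vector.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the permutation draws.
#' @param better \code{"lower"} for error-like scores, \code{"higher"} for
#'   accuracy-like scores.
#' @return List of class \code{null_distribution} with \code{observed},
#'   \code{scores}, \code{n_perm}, \code{better}, \code{p_value}.
#' @export
permutation_test <- function(pipeline, X, y, n_perm, seed = 1,
                             better = c("lower", "higher")) {
  better <- match.arg(better)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  observed <- pipeline(X, y)
  ids <- rownames(X)
  ord <- if (is.null(ids)) seq_along(y) else order(ids)
  scores <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, "perm", b), sample.int(length(y)))
    y_perm <- y
    y_perm[ord] <- y[ord][perm]
    scores[b] <- tryCatch(pipeline(X, y_perm), error = function(e) {
      stop("pipeline failed on permutation ", b, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  as_good <- if (better == "lower") sum(scores <= observed)
             else sum(scores >= observed)
  structure(list(observed = observed, scores = scores, n_perm = n_perm,
                 better = better,
                 p_value = (1 + as_good) / (1 + n_perm)),
            class = "null_distribution")
}

#' @export
#' @method print null_distribution
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> observed = %.4g (%s is better), n_perm = %d, p = %.4g\n",
              x$observed, x$better, x$n_perm, x$p_value))
  invisible(x)
}

#' Stability-based edge selection
#'
#' Retains the edges selected (non-zero elastic-net coefficient, or
#' RFE-retained feature) in at least a given fraction of cross-validation
#' folds — 99% by default, the strict stability filter used in place of
#' multiple-testing correction. When the edge matrix and target are
#' supplied, each retained edge is signed by the correlation of its weight
#' with the target across subjects (positive: similarity increases with the
#' target).
#'
#' @param cv An \code{msn_cv} with per-fold feature masks.
#' @param threshold Minimum selection frequency (default 0.99); retention
#'   uses \code{frequency >= threshold}.
#' @param edges Optional subjects x edges matrix for signing.
#' @param target Optional per-subject target for signing.
#' @return List of class \code{stable_edge_set} with \code{frequency} (all
#'   edges), \code{edge_index} (retained), \code{sign} (for retained edges,
#'   if signable) and \code{threshold}.
#' @export
stable_edges <- function(cv, threshold = 0.99, edges = NULL, target = NULL) {
  if (is.null(cv$fold_masks)) {
    stop("CV result carries no per-fold feature masks", call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1)
  n_edge <- cv$n_edge_features
  freq <- colMeans(cv$fold_masks[, seq_len(n_edge), drop = FALSE])
  retained <- which(freq >= threshold)
  sign_vec <- NULL
  if (!is.null(edges) && !is.null(target) && length(retained) > 0) {
    tgt <- if (is.numeric(target)) {
      target
    } else if (all(target %in% c("term", "preterm"))) {
      as.numeric(target == "preterm")   # sign w.r.t. prematurity
    } else {
      as.numeric(factor(target))
    }
    r <- suppressWarnings(as.vector(stats::cor(edges[, retained, drop = FALSE], tgt)))
    r[!is.finite(r)] <- 0
    sign_vec <- sign(r)
  }
  structure(list(frequency = freq, edge_index = retained, sign = sign_vec,
                 threshold = threshold, n_folds = nrow(cv$fold_masks)),
            class = "stable_edge_set")
}

#' Export a stable edge set as an edge list
#'
#' @param se A \code{stable_edge_set}.
#' @param atlas Atlas data.frame fixing node order.
#' @return data.frame with \code{roi_a}, \code{roi_b}, \code{frequency} and
#'   \code{sign} (NA when unsigned), one row per retained edge.
#' @export
stable_edges_table <- function(se, atlas) {
  map <- edge_index_map(nrow(atlas))
  k <- se$edge_index
  data.frame(roi_a = atlas$roi_name[map[k, "i"]],
             roi_b = atlas$roi_name[map[k, "j"]],
             frequency = se$frequency[k],
             sign = if (is.null(se$sign)) NA_real_ else se$sign,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Direct Pearson formula with 1 degree of freedom; the continuity
#' correction is off by default.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @param correction Apply the Yates continuity correction.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
chi2_2x2 <- function(counts, correction = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("both margins must be positive", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  dev <- abs(counts - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum comparison; exact null enumeration when both samples
#' have at most 25 untied observations, tie-corrected normal approximation
#' otherwise.
#'
#' @param a,b Numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"},
#'   \code{"greater"}.
#' @return List with \code{W} and \code{p_value}.
#' @export
rank_sum_test <- function(a, b, alternative = "two.sided") {
  exact <- length(a) <= 25 && length(b) <= 25 &&
    !anyDuplicated(c(a, b))
  res <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                             exact = exact))
  list(W = unname(res$statistic), p_value = res$p.value)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (standard convention); if every difference
#' is zero the test reports W = 0 and p = 1.
#'
#' @param diffs Numeric vector of paired differences.
#' @param alternative \code{"two.sided"} (default), \code{"less"},
#'   \code{"greater"} (differences tend to be positive).
#' @return List with \code{W} and \code{p_value}.
#' @export
signed_rank_test <- function(diffs, alternative = "two.sided") {
  d <- diffs[diffs != 0]
  if (length(d) == 0) return(list(W = 0, p_value = 1))
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  res <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                             exact = exact))
  list(W = unname(res$statistic), p_value = res$p.value)
}

#' Cohort descriptive statistics
#'
#' The confound-structure checks run before modelling: Spearman rank
#' correlation of age at scan with age at birth and with sex, rank-sum
#' comparisons of motion by group, and the group x sex interaction in a
#' linear model of age at scan.
#'
#' @param meta Metadata data.frame.
#' @return List with \code{rho_scan_birth}, \code{rho_scan_sex} (or a flag
#'   when sex is constant), \code{motion_abs_test}, \code{motion_rel_test}
#'   and \code{interaction_p}.
#' @export
cohort_descriptives <- function(meta) {
  ct <- suppressWarnings(stats::cor.test(meta$pma_scan, meta$pma_birth,
                                         method = "spearman", exact = FALSE))
  rho_birth <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  if (stats::sd(meta$sex) == 0) {
    rho_sex <- list(rho = NA_real_, p_value = NA_real_,
                    note = "sex is constant; correlation undefined")
  } else {
    ct <- suppressWarnings(stats::cor.test(meta$pma_scan, meta$sex,
                                           method = "spearman", exact = FALSE))
    rho_sex <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  }
  pre <- meta$group == "preterm"
  motion_abs <- if (any(pre) && any(!pre)) {
    rank_sum_test(meta$motion_abs[pre], meta$motion_abs[!pre])
  } else NULL
  motion_rel <- if (any(pre) && any(!pre)) {
    rank_sum_test(meta$motion_rel[pre], meta$motion_rel[!pre])
  } else NULL
  interaction_p <- NA_real_
  if (any(pre) && any(!pre) && stats::sd(meta$sex) > 0) {
    fit <- stats::lm(pma_scan ~ group * sex, data = meta)
    cf <- summary(fit)$coefficients
    row <- grep(":", rownames(cf))
    if (length(row) == 1) interaction_p <- cf[row, 4]
  }
  list(rho_scan_birth = rho_birth, rho_scan_sex = rho_sex,
       motion_abs_test = motion_abs, motion_rel_test = motion_rel,
       interaction_p = interaction_p)
}
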