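#' @title Morphometric similarity network construction
#' @description An MSN is an individual, per-subject network: each ROI is
#'   described by a vector of regional metrics, metrics are z-scored within
#'   the subject across ROIs, and the edge between two ROIs is the Pearson
#'   correlation of their z-scored metric vectors. The strict upper triangle
#'   of the symmetric matrix, flattened row-major, is the subject's edge
#'   feature vector (3240 features for 81 nodes).
#' @name msn
NULL

#' Z-score metric columns within a subject
#'
#' Each selected metric column is centred and scaled across the ROIs of the
#' single subject, using the population standard deviation (divisor n).
#' Because Pearson correlation is invariant to affine rescaling, the divisor
#' choice does not affect MSN edges; it is fixed for reproducibility of
#' intermediate files.
#'
#' @param table Numeric ROI x metric matrix (rownames = ROIs).
#' @param subset Metric names to retain (default: all columns). Reordered
#'   into canonical order.
#' @return Matrix of z-scored values, ROIs x selected metrics.
#' @export
zscore_within_subject <- function(table, subset = colnames(table)) {
  subset <- canonical_metric_order(subset)
  missing <- setdiff(subset, colnames(table))
  if (length(missing) > 0) {
    stop("metric(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- table[, subset, drop = FALSE]
  n <- nrow(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- which(sd_pop <= 0 | !is.finite(sd_pop))
  if (length(zero) > 0) {
    stop("zero variance across ROIs for metric ", subset[zero[1]],
         call. = FALSE)
  }
  sweep(sweep(x, 2, mu), 2, sd_pop, "/")
}

#' Build a subject's MSN
#'
#' Z-scores the selected metrics within the subject and computes the Pearson
#' correlation between the metric vectors of every pair of ROIs. The
#' diagonal is fixed at 1. At the smallest permitted subset size (3 metrics)
#' correlations are computed over only three points and are necessarily
#' coarse; a subset of fewer than 3 metrics is rejected.
#'
#' @param table Numeric ROI x metric matrix for one subject.
#' @param subset Metric names used as the ROI descriptor (>= 3).
#' @return Symmetric n x n matrix with unit diagonal and attribute
#'   \code{metric_subset}.
#' @export
build_msn <- function(table, subset = colnames(table)) {
  subset <- canonical_metric_order(subset)
  if (length(subset) < 3) {
    stop("metric subset must contain at least 3 metrics (got ",
         length(subset), "): Pearson correlation over fewer points is degenerate",
         call. = FALSE)
  }
  z <- zscore_within_subject(table, subset)
  roi_sd <- apply(z, 1, stats::sd)
  flat <- which(roi_sd <= 0 | !is.finite(roi_sd))
  if (length(flat) > 0) {
    stop("zero variance over the metric subset for ROI ",
         rownames(table)[flat[1]], call. = FALSE)
  }
  m <- stats::cor(t(z))
  m[m > 1] <- 1
  m[m < -1] <- -1
  m <- (m + t(m)) / 2
  diag(m) <- 1
  attr(m, "metric_subset") <- subset
  m
}

# Row-major strict-upper-triangle index pairs for an n-node network:
# (1,2), (1,3), ..., (1,n), (2,3), ... Each edge k maps to ROI pair (i, j),
# i < j.
edge_index_map <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  cbind(i = i, j = j)
}

#' Flatten an MSN to its canonical edge vector
#'
#' Extracts the strict upper triangle in row-major order: edge k corresponds
#' to the ROI pair (i, j), i < j, ordered by i then j. For 81 nodes this
#' yields 3240 edge features.
#'
#' @param msn Symmetric matrix with unit diagonal.
#' @return Numeric vector of length n(n-1)/2 with attribute \code{n_nodes}.
#' @export
vectorize <- function(msn) {
  n <- nrow(msn)
  if (n != ncol(msn)) stop("MSN matrix must be square", call. = FALSE)
  tm <- t(msn)
  v <- tm[lower.tri(tm)]
  attr(v, "n_nodes") <- n
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize()]: places the edge vector back into the strict
#' upper triangle (row-major), mirrors it and sets the diagonal to 1.
#'
#' @param v Edge vector of length n(n-1)/2.
#' @param n Number of nodes; inferred from the vector length if omitted.
#' @param node_names Optional dimnames.
#' @return Symmetric n x n matrix with unit diagonal.
#' @export
devectorize <- function(v, n = NULL, node_names = NULL) {
  if (is.null(n)) {
    n <- attr(v, "n_nodes")
    if (is.null(n)) n <- (1 + sqrt(1 + 8 * length(v))) / 2
  }
  if (n != round(n) || length(v) != n * (n - 1) / 2) {
    stop("edge vector length ", length(v), " does not match n(n-1)/2 for n = ",
         n, call. = FALSE)
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v       # fill lower triangle column-major == row-major upper
  m <- t(m)
  m <- m + t(m)
  diag(m) <- 1
  if (!is.null(node_names)) dimnames(m) <- list(node_names, node_names)
  m
}

#' Element-wise mean of several MSNs
#'
#' @param msns List of symmetric matrices with identical dimensions.
#' @return The element-wise mean matrix.
#' @export
mean_msn <- function(msns) {
  stopifnot(length(msns) >= 1)
  dims <- vapply(msns, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    stop("all MSNs must share the same node set", call. = FALSE)
  }
  Reduce(`+`, msns) / length(msns)
}

#' Per-edge correlation with a subject-level covariate
#'
#' For every edge, the Pearson correlation across subjects between the edge
#' weight and a covariate (e.g. postmenstrual age at scan), reassembled into
#' symmetric matrix form with zero diagonal. This is the edge-wise
#' age-association map that reveals the within-tissue convergence and
#' grey-white divergence of the developing brain.
#'
#' @param edge_matrix Subjects x edges matrix (rows in subject order).
#' @param covariate Numeric vector, one value per subject.
#' @return Symmetric matrix of per-edge correlations (diagonal 0).
#' @export
edgewise_covariate_correlation <- function(edge_matrix, covariate) {
  if (nrow(edge_matrix) != length(covariate)) {
    stop("covariate length must equal the number of subjects", call. = FALSE)
  }
  if (nrow(edge_matrix) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(covariate) == 0) {
    stop("covariate is constant across subjects", call. = FALSE)
  }
  r <- suppressWarnings(as.vector(stats::cor(edge_matrix, covariate)))
  r[!is.finite(r)] <- 0   # constant edges carry no association
  m <- devectorize(r)
  diag(m) <- 0
  m
}

#' Edge feature matrix for a cohort
#'
#' Builds each subject's MSN from the selected metrics and stacks the
#' vectorized edges into a subjects x edges matrix, the input to all
#' predictive models.
#'
#' @param ds An \code{msn_dataset}.
#' @param subset Metric names (>= 3).
#' @return Matrix with one row per subject (named), n(n-1)/2 columns, and
#'   attributes \code{metric_subset} and \code{n_nodes}.
#' @export
cohort_edges <- function(ds, subset = metric_names()) {
  subset <- canonical_metric_order(subset)
  mats <- lapply(ds$subjects$subject_id, function(sid) {
    vectorize(build_msn(ds$tables[[sid]], subset))
  })
  edges <- do.call(rbind, mats)
  rownames(edges) <- ds$subjects$subject_id
  attr(edges, "metric_subset") <- subset
  attr(edges, "n_nodes") <- nrow(ds$atlas)
  edges
}
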