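#' @title Hemispheric asymmetry analysis
#' @description Tests whether the two hemispheres carry different
#'   information: side-restricted models re-run the prediction tasks on
#'   left-only or right-only edges, and a permutation test of hemisphere
#'   "interchangeability" rebuilds the null by randomly swapping homotopic
#'   region pairs between hemispheres and repeating the full analysis.
#' @name asymmetry
NULL

#' Partition edges by hemisphere
#'
#' Splits the canonical edge indexing into left-only edges (both endpoints
#' lateralized L), right-only edges, and everything else (cross-hemisphere
#' edges and edges touching unpaired midline regions).
#'
#' @param atlas Atlas data.frame.
#' @return List with \code{left}, \code{right},
#'   \code{cross_or_unpaired} integer index vectors partitioning
#'   \code{1..n(n-1)/2}.
#' @export
partition_edges <- function(atlas) {
  n <- nrow(atlas)
  map <- edge_index_map(n)
  hi <- atlas$hemisphere[map[, "i"]]
  hj <- atlas$hemisphere[map[, "j"]]
  left <- which(hi == "L" & hj == "L")
  right <- which(hi == "R" & hj == "R")
  list(left = left, right = right,
       cross_or_unpaired = setdiff(seq_len(nrow(map)), c(left, right)))
}

#' Swap homotopic region pairs between hemispheres
#'
#' For each selected homotopic pair, exchanges the two ROIs' metric rows in
#' every subject's table; the atlas itself is unchanged. Applying the same
#' mask twice is the identity.
#'
#' @param ds An \code{msn_dataset}.
#' @param pair_mask Logical vector over the homotopic pairs of the atlas
#'   (ordered by the left member's node index), or integer pair indices.
#' @return The swapped \code{msn_dataset}.
#' @export
homotopic_swap <- function(ds, pair_mask) {
  pairs <- homotopic_pairs(ds$atlas)
  if (is.logical(pair_mask)) {
    if (length(pair_mask) != nrow(pairs)) {
      stop("pair_mask length must equal the number of homotopic pairs (",
           nrow(pairs), ")", call. = FALSE)
    }
    sel <- which(pair_mask)
  } else {
    sel <- as.integer(pair_mask)
    if (any(sel < 1 | sel > nrow(pairs))) {
      stop("pair_mask references a non-existent homotopic pair", call. = FALSE)
    }
  }
  if (length(sel) == 0) return(ds)
  li <- pairs[sel, "L"]
  ri <- pairs[sel, "R"]
  for (sid in names(ds$tables)) {
    mat <- ds$tables[[sid]]
    tmp <- mat[li, , drop = FALSE]
    mat[li, ] <- mat[ri, , drop = FALSE]
    mat[ri, ] <- tmp
    ds$tables[[sid]] <- mat
  }
  ds
}

#' Side-restricted model comparison
#'
#' For each metric subset (typically the candidate subsets evaluated during
#' backward elimination), scores the task model using only left-hemisphere
#' or only right-hemisphere edges, and compares the paired left/right score
#' profiles with a one-sided signed-rank test of the hypothesis that
#' prediction error is higher using left-hemisphere connections only (for
#' accuracy the direction is reversed: right accuracy higher).
#'
#' @param ds An \code{msn_dataset}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param subsets List of metric-name vectors (each of size >= 3).
#' @param scheme CV scheme.
#' @param cfg Optional model configuration.
#' @return List with \code{table} (subset, left and right scores) and
#'   \code{test} (signed-rank W and p).
#' @export
run_side_restricted <- function(ds, task = c("regression", "classification"),
                                subsets, scheme = "loocv", cfg = NULL) {
  task <- match.arg(task)
  parts <- partition_edges(ds$atlas)
  if (length(parts$left) == 0 || length(parts$right) == 0) {
    stop("a hemisphere contributes zero edges", call. = FALSE)
  }
  score_of <- function(cv) {
    if (task == "regression") cv$summary$mae else cv$summary$accuracy
  }
  rows <- lapply(subsets, function(subset) {
    edges <- cohort_edges(ds, subset)
    l <- score_of(.run_task(edges[, parts$left, drop = FALSE], ds$subjects,
                            task, scheme, cfg))
    r <- score_of(.run_task(edges[, parts$right, drop = FALSE], ds$subjects,
                            task, scheme, cfg))
    data.frame(subset = paste(canonical_metric_order(subset), collapse = "+"),
               left = l, right = r, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  d <- if (task == "regression") tab$left - tab$right else tab$right - tab$left
  list(table = tab, test = signed_rank_test(d, alternative = "greater"))
}

#' Hemisphere-interchangeability permutation test
#'
#' The observed statistic is the disproportion of stable predictive edges
#' between hemispheres: (number of stable right-hemisphere edges) minus
#' (number of stable left-hemisphere edges), where stability uses the
#' cross-validation fold masks at the given threshold. The null is built by
#' independently swapping each homotopic pair with probability 1/2
#' (identically across subjects, preserving region identity under the
#' null), re-running the exact same analysis, and recomputing the
#' statistic. One-sided add-one p-value for a right-hemisphere excess at
#' least as large as observed.
#'
#' @param ds An \code{msn_dataset}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the swap draws.
#' @param subset Metric subset used for the MSNs.
#' @param threshold Stability threshold (default 0.99).
#' @param scheme CV scheme.
#' @param cfg Optional model configuration.
#' @return A \code{null_distribution} whose \code{observed} is the real
#'   disproportion statistic.
#' @export
asymmetry_permutation_test <- function(ds, task = c("regression", "classification"),
                                       n_perm = 99, seed = 1,
                                       subset = metric_names(),
                                       threshold = 0.99, scheme = "loocv",
                                       cfg = NULL) {
  task <- match.arg(task)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  parts <- partition_edges(ds$atlas)
  n_pairs <- nrow(homotopic_pairs(ds$atlas))
  statistic <- function(d) {
    cv <- .run_task(cohort_edges(d, subset), d$subjects, task, scheme, cfg)
    se <- stable_edges(cv, threshold)
    sum(se$edge_index %in% parts$right) - sum(se$edge_index %in% parts$left)
  }
  observed <- statistic(ds)
  scores <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    mask <- with_seed(derive_seed(seed, "swap", b),
                      stats::runif(n_pairs) < 0.5)
    scores[b] <- statistic(homotopic_swap(ds, mask))
  }
  structure(list(observed = observed, scores = scores, n_perm = n_perm,
                 better = "higher",
                 p_value = (1 + sum(scores >= observed)) / (1 + n_perm)),
            class = "null_distribution")
}
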