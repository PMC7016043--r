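#' @title Greedy backward elimination over metric subsets
#' @description Starting from the full metric set, each iteration evaluates
#'   all single-metric removals and permanently drops the metric whose
#'   removal degrades the score least, down to a minimum subset size. From
#'   12 metrics down to 3 this evaluates exactly 1 + (12 + 11 + ... + 4) =
#'   73 candidate subsets, a tractable alternative to the 2^12 exhaustive
#'   search.
#' @name elimination
NULL

#' Backward elimination
#'
#' @param evaluator Function mapping a character vector of metric names to a
#'   numeric score; it must be deterministic given its own seeding.
#' @param metrics Starting metric set (canonical order enforced).
#' @param min_size Smallest subset size (>= 3, the smallest set Pearson
#'   similarity is computed over).
#' @param minimize If \code{TRUE} (error-like scores) smaller is better;
#'   if \code{FALSE} (accuracy-like) larger is better.
#' @return List of class \code{elimination_path} with \code{evaluations}
#'   (every candidate subset with its score and level), \code{kept} (the
#'   retained subset at each size from |metrics| down to \code{min_size}),
#'   \code{kept_scores} and \code{total_evaluations}.
#' @details Ties between candidate removals are broken by removing the
#'   metric that comes later in canonical metric order, which is
#'   deterministic and favours retaining the earlier-listed structural
#'   metrics.
#' @export
backward_eliminate <- function(evaluator, metrics = metric_names(),
                               min_size = 3, minimize = TRUE) {
  metrics <- canonical_metric_order(metrics)
  if (min_size < 3) stop("min_size must be at least 3", call. = FALSE)
  if (min_size > length(metrics)) {
    stop("min_size exceeds the number of metrics", call. = FALSE)
  }
  evaluations <- list()
  record <- function(subset, score, level) {
    evaluations[[length(evaluations) + 1L]] <<- data.frame(
      subset = paste(subset, collapse = "+"), score = score,
      size = length(subset), level = level, stringsAsFactors = FALSE)
  }
  current <- metrics
  full_score <- evaluator(current)
  record(current, full_score, 0L)
  kept <- list(current)
  kept_scores <- full_score
  level <- 0L
  while (length(current) > min_size) {
    level <- level + 1L
    cand_scores <- numeric(length(current))
    for (ci in seq_along(current)) {
      cand <- current[-ci]
      cand_scores[ci] <- evaluator(cand)
      record(cand, cand_scores[ci], level)
    }
    best_val <- if (minimize) min(cand_scores) else max(cand_scores)
    ties <- which(cand_scores == best_val)
    # remove the metric latest in canonical order among tied removals
    drop_idx <- ties[which.max(match(current[ties], metric_names()))]
    current <- current[-drop_idx]
    kept[[length(kept) + 1L]] <- current
    kept_scores <- c(kept_scores, best_val)
  }
  structure(list(evaluations = do.call(rbind, evaluations), kept = kept,
                 kept_scores = kept_scores,
                 total_evaluations = length(evaluations),
                 min_size = min_size, minimize = minimize),
            class = "elimination_path")
}

#' @export
#' @method print elimination_path
print.elimination_path <- function(x, ...) {
  cat("<elimination_path> ", x$total_evaluations, " evaluations, ",
      length(x$kept[[1]]), " -> ", x$min_size, " metrics\n", sep = "")
  cat("  final subset: ", paste(x$kept[[length(x$kept)]], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Summarize an elimination path by modality count
#'
#' Annotates every evaluated subset with the number of distinct imaging
#' modalities (structural / DKI / NODDI) it spans, the grouping used to
#' summarize whether multi-modality models outperform single-modality ones.
#'
#' @param path An \code{elimination_path}.
#' @return data.frame with \code{subset}, \code{score}, \code{size} and
#'   \code{n_modalities}.
#' @export
summarize_by_modality <- function(path) {
  ev <- path$evaluations
  ev$n_modalities <- vapply(strsplit(ev$subset, "+", fixed = TRUE),
                            count_modalities, integer(1))
  ev[, c("subset", "score", "size", "n_modalities")]
}

#' Single-modality models
#'
#' Evaluates the task model on each modality's full metric set used as the
#' MSN descriptor. The structural modality has only two metrics (Volume and
#' T1w/T2w), below the 3-metric minimum for Pearson similarity, so it is
#' evaluated as a concatenated-regional-metrics model instead and flagged
#' as such.
#'
#' @param ds An \code{msn_dataset}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param scheme CV scheme.
#' @param cfg Optional model configuration.
#' @return Named list (\code{structural}, \code{dki}, \code{noddi}) of
#'   \code{msn_cv} objects; the structural entry carries attribute
#'   \code{fallback = "concatenated_metrics"}.
#' @export
single_modality_paths <- function(ds, task = c("regression", "classification"),
                                  scheme = "loocv", cfg = NULL) {
  task <- match.arg(task)
  out <- list()
  for (mod in c("structural", "dki", "noddi")) {
    subset <- metric_names(mod)
    if (length(subset) < 3) {
      message("modality '", mod, "' has fewer than 3 metrics; ",
              "evaluating concatenated regional metrics instead of an MSN")
      res <- baseline_concatenated_metrics(ds, subset, task, scheme, cfg)
      attr(res, "fallback") <- "concatenated_metrics"
    } else {
      res <- .run_task(cohort_edges(ds, subset), ds$subjects, task, scheme, cfg)
    }
    out[[mod]] <- res
  }
  out
}
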