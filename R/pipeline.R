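#' @title End-to-end workflow
#' @description A thin orchestrator running the pipeline stages in
#'   dependency order — simulate (or read) a dataset, build MSN edge
#'   features, optionally run backward metric elimination, fit the
#'   prediction task(s), and optionally run permutation and asymmetry
#'   tests — writing JSON/TSV artifacts with the seeds used, so a rerun
#'   with the same configuration reproduces all outputs.
#' @name pipeline
NULL

#' Run the analysis pipeline
#'
#' @param config Named list (or path to a YAML file when the \code{yaml}
#'   package is available) with entries:
#'   \describe{
#'     \item{dataset}{either \code{list(metrics, metadata, atlas)} file
#'       paths, or \code{list(synthetic = list(...))} arguments for
#'       [synthetic_config()].}
#'     \item{tasks}{subset of \code{c("regression", "classification")}.}
#'     \item{subset}{metric names for the MSN (default all 12).}
#'     \item{scheme}{\code{"loocv"} (default) or \code{"repeated_kfold"}.}
#'     \item{seed}{master seed (required; no wall-clock seeding).}
#'     \item{n_perm}{if > 0, permutation test per task.}
#'     \item{asymmetry_n_perm}{if > 0, homotopic-swap test per task.}
#'     \item{select_metrics}{if TRUE, run backward elimination.}
#'     \item{stability_threshold}{stable-edge threshold (default 0.99).}
#'     \item{out_dir}{output directory (optional; no files if omitted).}
#'     \item{regression, classification}{optional argument lists overriding
#'       [regression_config()] / [classification_config()] defaults.}
#'   }
#' @return A run report (named list of stage results), invisibly writing
#'   artifacts when \code{out_dir} is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (is.null(config$tasks)) config$tasks <- "regression"
  scheme <- if (is.null(config$scheme)) "loocv" else config$scheme
  subset <- if (is.null(config$subset)) metric_names() else config$subset
  threshold <- if (is.null(config$stability_threshold)) 0.99
               else config$stability_threshold

  # stage: dataset
  if (!is.null(config$dataset$synthetic)) {
    args <- config$dataset$synthetic
    args$seed <- derive_seed(config$seed, "simulate")
    ds <- generate_cohort(do.call(synthetic_config, args))
  } else if (!is.null(config$dataset$metrics)) {
    for (p in unlist(config$dataset)) {
      if (!file.exists(p)) stop("config error: missing input file ", p,
                                call. = FALSE)
    }
    ds <- read_dataset(config$dataset$metrics, config$dataset$metadata,
                       config$dataset$atlas)
  } else {
    stop("config error: dataset must name input files or synthetic settings",
         call. = FALSE)
  }
  report <- list(seed = config$seed, scheme = scheme, subset = subset,
                 n_subjects = nrow(ds$subjects),
                 descriptives = cohort_descriptives(ds$subjects))

  # stage: edges
  edges <- cohort_edges(ds, subset)
  report$n_edges <- ncol(edges)

  for (task in config$tasks) {
    cfg <- if (task == "regression") {
      do.call(regression_config,
              c(config$regression, list(seed = derive_seed(config$seed, task))))
    } else {
      do.call(classification_config,
              c(config$classification, list(seed = derive_seed(config$seed, task))))
    }
    stage <- list()

    if (isTRUE(config$select_metrics)) {
      evaluator <- function(sub) {
        cv <- .run_task(cohort_edges(ds, sub), ds$subjects, task, scheme, cfg)
        if (task == "regression") cv$summary$mae else cv$summary$accuracy
      }
      path <- backward_eliminate(evaluator, subset,
                                 minimize = (task == "regression"))
      stage$elimination <- summarize_by_modality(path)
      stage$final_subset <- path$kept[[length(path$kept)]]
      use_subset <- stage$final_subset
      task_edges <- cohort_edges(ds, use_subset)
    } else {
      use_subset <- subset
      task_edges <- edges
    }

    stage$subset_used <- use_subset
    cv <- .run_task(task_edges, ds$subjects, task, scheme, cfg)
    stage$cv <- cv
    y <- if (task == "regression") ds$subjects$pma_scan else ds$subjects$group
    stage$stable_edges <- stable_edges(cv, threshold, task_edges, y)

    if (!is.null(config$n_perm) && config$n_perm > 0) {
      meta <- ds$subjects
      target_col <- if (task == "regression") "pma_scan" else "group"
      pipe <- function(X, yy) {
        m <- meta
        m[[target_col]] <- yy
        res <- .run_task(X, m, task, scheme, cfg)
        if (task == "regression") res$summary$mae else res$summary$accuracy
      }
      stage$permutation <- permutation_test(
        pipe, task_edges, y, config$n_perm,
        seed = derive_seed(config$seed, task, "perm"),
        better = if (task == "regression") "lower" else "higher")
    }

    if (!is.null(config$asymmetry_n_perm) && config$asymmetry_n_perm > 0) {
      stage$asymmetry <- asymmetry_permutation_test(
        ds, task, config$asymmetry_n_perm,
        seed = derive_seed(config$seed, task, "asym"),
        subset = use_subset, threshold = threshold, scheme = scheme,
        cfg = cfg)
    }
    report[[task]] <- stage
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(ds, file.path(config$out_dir, "dataset"))
    for (task in config$tasks) {
      st <- report[[task]]
      summ <- list(seed = config$seed, scheme = scheme, task = task,
                   subset = st$subset_used, summary = st$cv$summary,
                   predictions = data.frame(subject_id = st$cv$subject_id,
                                            truth = st$cv$truth,
                                            predicted = st$cv$predicted))
      if (!is.null(st$permutation)) {
        summ$permutation <- list(observed = st$permutation$observed,
                                 p_value = st$permutation$p_value,
                                 n_perm = st$permutation$n_perm)
      }
      if (!is.null(st$asymmetry)) {
        summ$asymmetry <- list(observed = st$asymmetry$observed,
                               p_value = st$asymmetry$p_value,
                               n_perm = st$asymmetry$n_perm)
      }
      jsonlite::write_json(summ, file.path(config$out_dir,
                                           paste0(task, "_summary.json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      utils::write.table(stable_edges_table(st$stable_edges, ds$atlas),
                         file.path(config$out_dir,
                                   paste0(task, "_stable_edges.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(report)
}
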