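#' @title Dataset container and validation
#' @description A dataset couples an atlas, per-subject metadata and one
#'   regional metrics table (ROI x metric matrix) per subject. All tables
#'   share the atlas node order and the canonical metric column order, so
#'   edge/feature indexing is identical across subjects.
#' @name dataset
NULL

#' Assemble a dataset
#'
#' @param atlas Atlas data.frame (see [default_atlas()]).
#' @param subjects Metadata data.frame with columns \code{subject_id},
#'   \code{pma_birth}, \code{pma_scan} (postmenstrual age in weeks),
#'   \code{sex} (0 = female, 1 = male), \code{group} (\code{term} /
#'   \code{preterm}), \code{motion_abs}, \code{motion_rel} (mm).
#' @param tables Named list (by subject id) of numeric ROI x metric matrices;
#'   rows must follow atlas node order, columns the canonical metric order.
#' @return A validated object of class \code{msn_dataset}.
#' @export
msn_dataset <- function(atlas, subjects, tables) {
  ds <- structure(list(atlas = atlas, subjects = subjects, tables = tables),
                  class = "msn_dataset")
  validate_dataset(ds)
  ds
}

#' @export
#' @method print msn_dataset
print.msn_dataset <- function(x, ...) {
  cat("<msn_dataset> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "term"), " term, ",
      sum(x$subjects$group == "preterm"), " preterm), ",
      nrow(x$atlas), " ROIs, ", ncol(x$tables[[1]]), " metrics\n", sep = "")
  invisible(x)
}

# Range checks for one subject's metrics matrix; returns NULL or a message.
.check_metric_ranges <- function(mat, subject_id) {
  rois <- rownames(mat)
  for (m in colnames(mat)) {
    x <- mat[, m]
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      return(sprintf("non-finite value for subject %s, ROI %s, metric %s",
                     subject_id, rois[bad[1]], m))
    }
    if (m %in% c("Volume", "MD", "AD", "RD")) {
      bad <- which(x <= 0)
      if (length(bad) > 0) {
        return(sprintf("non-positive %s for subject %s, ROI %s",
                       m, subject_id, rois[bad[1]]))
      }
    }
    if (m %in% c("FA", "NDI_ic", "ISO", "ODI_P", "ODI_S", "ODI_TOT")) {
      bad <- which(x < 0 | x > 1)
      if (length(bad) > 0) {
        return(sprintf("%s outside [0, 1] for subject %s, ROI %s",
                       m, subject_id, rois[bad[1]]))
      }
    }
  }
  NULL
}

#' Validate a dataset
#'
#' Checks all structural and range invariants: matching subject-id sets
#' between metadata and tables, shared ROI/metric ordering, finite values,
#' metric domains (positive volumes and diffusivities, unit-interval
#' fractions and dispersion indices), postmenstrual-age ranges, the 37-week
#' term/preterm rule and non-negative motion summaries.
#'
#' @param ds An \code{msn_dataset}.
#' @return \code{ds}, invisibly, or an error naming the offending record.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "msn_dataset"))
  validate_atlas(ds$atlas)
  meta <- ds$subjects
  required <- c("subject_id", "pma_birth", "pma_scan", "sex", "group",
                "motion_abs", "motion_rel")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(meta) == 0) stop("empty dataset", call. = FALSE)
  if (anyDuplicated(meta$subject_id)) {
    stop("duplicate subject_id: ",
         meta$subject_id[duplicated(meta$subject_id)][1], call. = FALSE)
  }
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]
    if (!is.finite(meta$pma_birth[i]) || meta$pma_birth[i] < 22 ||
        meta$pma_birth[i] > 43) {
      stop("pma_birth out of [22, 43] for subject ", sid, call. = FALSE)
    }
    if (!is.finite(meta$pma_scan[i]) || meta$pma_scan[i] < 36 ||
        meta$pma_scan[i] > 46) {
      stop("pma_scan out of [36, 46] for subject ", sid, call. = FALSE)
    }
    if (meta$pma_scan[i] <= meta$pma_birth[i]) {
      stop("pma_scan must exceed pma_birth for subject ", sid, call. = FALSE)
    }
    if (!meta$sex[i] %in% c(0, 1)) {
      stop("sex must be 0 (female) or 1 (male) for subject ", sid, call. = FALSE)
    }
    if (!meta$group[i] %in% c("term", "preterm")) {
      stop("group must be term or preterm for subject ", sid, call. = FALSE)
    }
    term <- meta$pma_birth[i] >= 37
    if (term != (meta$group[i] == "term")) {
      stop("group label inconsistent with 37-week rule for subject ", sid,
           " (pma_birth = ", meta$pma_birth[i], ", group = ", meta$group[i],
           ")", call. = FALSE)
    }
    if (meta$motion_abs[i] < 0 || meta$motion_rel[i] < 0) {
      stop("negative motion summary for subject ", sid, call. = FALSE)
    }
  }
  if (!setequal(meta$subject_id, names(ds$tables))) {
    stop("subject ids of metadata and metric tables differ", call. = FALSE)
  }
  metric_order <- colnames(ds$tables[[1]])
  if (!identical(metric_order, canonical_metric_order(metric_order))) {
    stop("metric columns must be in canonical order", call. = FALSE)
  }
  for (sid in meta$subject_id) {
    mat <- ds$tables[[sid]]
    if (!is.matrix(mat) || !is.numeric(mat)) {
      stop("metrics table of subject ", sid, " is not a numeric matrix",
           call. = FALSE)
    }
    if (!identical(rownames(mat), ds$atlas$roi_name)) {
      stop("ROI rows of subject ", sid, " do not match atlas node order",
           call. = FALSE)
    }
    if (!identical(colnames(mat), metric_order)) {
      stop("metric columns of subject ", sid, " differ from the shared order",
           call. = FALSE)
    }
    msg <- .check_metric_ranges(mat, sid)
    if (!is.null(msg)) stop(msg, call. = FALSE)
  }
  invisible(ds)
}

#' Read a dataset from delimited text files
#'
#' Expects a long-format metrics TSV (\code{subject_id}, \code{roi_name},
#' \code{metric}, \code{value}), a metadata TSV and an atlas TSV (see
#' [read_atlas()]). Metric columns are reordered into canonical order and
#' ROI rows into atlas node order regardless of input order.
#'
#' @param metrics_path,metadata_path,atlas_path File paths.
#' @return A validated \code{msn_dataset}.
#' @export
read_dataset <- function(metrics_path, metadata_path, atlas_path) {
  atlas <- read_atlas(atlas_path)
  for (p in c(metrics_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  long <- utils::read.delim(metrics_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "roi_name", "metric", "value")
  missing <- setdiff(required, names(long))
  if (length(missing) > 0) {
    stop("metrics file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metrics <- canonical_metric_order(unique(long$metric))
  tables <- lapply(split(long, long$subject_id), function(d) {
    mat <- matrix(NA_real_, nrow(atlas), length(metrics),
                  dimnames = list(atlas$roi_name, metrics))
    ri <- match(d$roi_name, atlas$roi_name)
    if (anyNA(ri)) {
      stop("unknown ROI '", d$roi_name[which(is.na(ri))[1]],
           "' for subject ", d$subject_id[1], call. = FALSE)
    }
    ci <- match(d$metric, metrics)
    if (any(!is.na(mat[cbind(ri, ci)]))) {
      stop("duplicate (ROI, metric) entry for subject ", d$subject_id[1],
           call. = FALSE)
    }
    mat[cbind(ri, ci)] <- d$value
    if (anyNA(mat)) {
      miss <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stop("missing value for subject ", d$subject_id[1], ", ROI ",
           rownames(mat)[miss[1]], ", metric ", colnames(mat)[miss[2]],
           call. = FALSE)
    }
    mat
  })
  msn_dataset(atlas, meta, tables[meta$subject_id])
}

#' Write a dataset to delimited text files
#'
#' Writes \code{metrics.tsv} (long format), \code{metadata.tsv} and
#' \code{atlas.tsv} into \code{out_dir} at full decimal precision, so that
#' \code{read_dataset()} on the written files reproduces the dataset
#' value-exactly, and repeated writes are byte-identical.
#'
#' @param ds An \code{msn_dataset}.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  validate_dataset(ds)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(metrics = file.path(out_dir, "metrics.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             atlas = file.path(out_dir, "atlas.tsv"))
  rows <- lapply(ds$subjects$subject_id, function(sid) {
    mat <- ds$tables[[sid]]
    data.frame(subject_id = sid,
               roi_name = rep(rownames(mat), times = ncol(mat)),
               metric = rep(colnames(mat), each = nrow(mat)),
               value = sprintf("%.17g", as.vector(mat)),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  utils::write.table(long, paths["metrics"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- ds$subjects
  for (col in c("pma_birth", "pma_scan", "motion_abs", "motion_rel")) {
    meta[[col]] <- sprintf("%.17g", meta[[col]])
  }
  utils::write.table(meta, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_atlas(ds$atlas, paths["atlas"])
  invisible(paths)
}
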