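#' Canonical regional MRI metrics
#'
#' The twelve regional metrics an MSN can be built from, in their fixed
#' canonical order. Two are computed in structural space (ROI volume and the
#' myelin-sensitive T1w/T2w signal ratio), five come from the diffusion
#' kurtosis model (FA, MD, AD, RD, MK) and five from Bingham-NODDI
#' (intracellular and isotropic volume fractions and the orientation
#' dispersion indices along the primary and secondary axes and overall).
#' The canonical order is total and fixed: it defines column order in
#' regional metric tables and the tie-break order used by backward
#' elimination.
#'
#' @return A data.frame with columns \code{name}, \code{modality}
#'   (\code{structural}, \code{dki} or \code{noddi}) and \code{units}.
#' @examples
#' metric_registry()
#' @export
metric_registry <- function() {
  data.frame(
    name = c("Volume", "T1T2", "FA", "MD", "AD", "RD", "MK",
             "NDI_ic", "ISO", "ODI_P", "ODI_S", "ODI_TOT"),
    modality = c("structural", "structural", "dki", "dki", "dki", "dki",
                 "dki", "noddi", "noddi", "noddi", "noddi", "noddi"),
    units = c("mm^3", "dimensionless", "dimensionless", "mm^2/s", "mm^2/s",
              "mm^2/s", "dimensionless", "dimensionless", "dimensionless",
              "dimensionless", "dimensionless", "dimensionless"),
    stringsAsFactors = FALSE
  )
}

#' Canonical metric names
#'
#' @param modality Optional modality filter: \code{"structural"},
#'   \code{"dki"} or \code{"noddi"}.
#' @return Character vector of metric names in canonical order.
#' @export
metric_names <- function(modality = NULL) {
  reg <- metric_registry()
  if (!is.null(modality)) {
    modality <- match.arg(modality, c("structural", "dki", "noddi"))
    reg <- reg[reg$modality == modality, , drop = FALSE]
  }
  reg$name
}

# Sort metric names into canonical order; error on unknown names.
canonical_metric_order <- function(metrics) {
  all <- metric_names()
  bad <- setdiff(metrics, all)
  if (length(bad) > 0) {
    stop("unknown metric name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metrics)) {
    stop("duplicated metric name(s): ",
         paste(unique(metrics[duplicated(metrics)]), collapse = ", "),
         call. = FALSE)
  }
  all[all %in% metrics]
}

# Number of distinct modalities represented in a metric subset (1..3).
count_modalities <- function(metrics) {
  reg <- metric_registry()
  length(unique(reg$modality[match(canonical_metric_order(metrics), reg$name)]))
}
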