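#' @title Atlas definitions
#' @description Helpers around the parcellation table that fixes node order,
#'   hemisphere labels, tissue classes and homotopic (mirror-image) pairing.
#'   The default atlas follows the dHCP neonatal 87-label scheme with the six
#'   non-brain/unreliable labels removed at the atlas level (background,
#'   unlabelled area, CSF, the two lateral ventricles and the corpus
#'   callosum), leaving 81 regions. ROI naming and ordering are
#'   dHCP-compatible rather than guaranteed identical to any specific
#'   published ordering.
#' @name atlas
NULL

ATLAS_TISSUE_CLASSES <- c("cGM", "WM", "subcortical", "brainstem", "cerebellum")

# Region stems for the default atlas, one entry per homotopic pair.
.dhcp_pair_stems <- function() {
  list(
    cGM = c("Anterior_temporal_lobe_medial_GM", "Anterior_temporal_lobe_lateral_GM",
            "Parahippocampal_gyrus_anterior_GM", "Parahippocampal_gyrus_posterior_GM",
            "Superior_temporal_gyrus_anterior_GM", "Superior_temporal_gyrus_posterior_GM",
            "Medial_inferior_temporal_gyri_anterior_GM", "Medial_inferior_temporal_gyri_posterior_GM",
            "Lateral_occipitotemporal_gyrus_anterior_GM", "Lateral_occipitotemporal_gyrus_posterior_GM",
            "Insula_GM", "Occipital_lobe_GM", "Cingulate_gyrus_anterior_GM",
            "Cingulate_gyrus_posterior_GM", "Frontal_lobe_anterior_GM",
            "Frontal_lobe_posterior_GM", "Parietal_lobe_GM"),
    WM = c("Anterior_temporal_lobe_medial_WM", "Anterior_temporal_lobe_lateral_WM",
           "Parahippocampal_gyrus_anterior_WM", "Parahippocampal_gyrus_posterior_WM",
           "Superior_temporal_gyrus_anterior_WM", "Superior_temporal_gyrus_posterior_WM",
           "Medial_inferior_temporal_gyri_anterior_WM", "Medial_inferior_temporal_gyri_posterior_WM",
           "Lateral_occipitotemporal_gyrus_anterior_WM", "Lateral_occipitotemporal_gyrus_posterior_WM",
           "Insula_WM", "Occipital_lobe_WM", "Cingulate_gyrus_WM",
           "Frontal_lobe_anterior_WM", "Frontal_lobe_posterior_WM", "Parietal_lobe_WM"),
    subcortical = c("Hippocampus", "Amygdala", "Caudate_nucleus", "Thalamus",
                    "Subthalamic_nucleus", "Lentiform_nucleus")
  )
}

#' Default 81-region neonatal atlas
#'
#' The dHCP-compatible parcellation used throughout: 87 labels minus the six
#' excluded non-brain or unreliable labels (background, unlabelled brain
#' area, CSF, left and right lateral ventricles, corpus callosum), i.e. 81
#' retained regions: 34 cortical grey matter, 32 white matter, 12 subcortical
#' grey matter regions, left and right cerebellum and the brainstem. Label
#' ids skip the slots of the excluded labels. Row order defines node order.
#'
#' @return A validated atlas data.frame with columns \code{label_id},
#'   \code{roi_name}, \code{hemisphere} (\code{L}/\code{R}/\code{U}),
#'   \code{tissue_class} and \code{homotopic_partner} (\code{NA} for the
#'   unpaired brainstem).
#' @examples
#' atlas <- default_atlas()
#' nrow(atlas)          # 81
#' table(atlas$tissue_class)
#' @export
default_atlas <- function() {
  stems <- .dhcp_pair_stems()
  pair <- function(stem, class) {
    data.frame(roi_name = paste0(stem, c("_L", "_R")),
               hemisphere = c("L", "R"), tissue_class = class,
               homotopic_partner = paste0(stem, c("_R", "_L")),
               stringsAsFactors = FALSE)
  }
  rows <- list(
    pair("Hippocampus", "subcortical"),
    pair("Amygdala", "subcortical"),
    pair(stems$cGM[1], "cGM"), pair(stems$cGM[2], "cGM"),
    pair(stems$cGM[3], "cGM"), pair(stems$cGM[4], "cGM"),
    pair(stems$cGM[5], "cGM"), pair(stems$cGM[6], "cGM"),
    pair("Cerebellum", "cerebellum"),
    data.frame(roi_name = "Brainstem", hemisphere = "U",
               tissue_class = "brainstem", homotopic_partner = NA_character_,
               stringsAsFactors = FALSE)
  )
  for (s in stems$cGM[7:17]) rows <- c(rows, list(pair(s, "cGM")))
  for (s in c("Caudate_nucleus", "Thalamus", "Subthalamic_nucleus")) {
    rows <- c(rows, list(pair(s, "subcortical")))
  }
  rows <- c(rows, list(pair("Lentiform_nucleus", "subcortical")))
  for (s in stems$WM) rows <- c(rows, list(pair(s, "WM")))
  atlas <- do.call(rbind, rows)
  # 87-label id scheme: slots 48-50 (corpus callosum, lateral ventricles) and
  # 83-85 (background, CSF, unlabelled) belong to the excluded labels.
  excluded <- c(48, 49, 50, 83, 84, 85)
  atlas$label_id <- setdiff(seq_len(87), excluded)
  atlas <- atlas[, c("label_id", "roi_name", "hemisphere", "tissue_class",
                     "homotopic_partner")]
  rownames(atlas) <- NULL
  validate_atlas(atlas)
}

#' Small synthetic atlas for simulations
#'
#' Builds a reduced atlas with the same structural features as the default
#' one (L/R homotopic pairs in each tissue class plus an unpaired brainstem),
#' useful for fast simulation studies where the full 81-node parcellation is
#' unnecessarily large.
#'
#' @param n_cgm,n_wm,n_subcortical Number of homotopic pairs per tissue class.
#' @param cerebellum,brainstem Include a cerebellum pair / unpaired brainstem.
#' @return A validated atlas data.frame.
#' @examples
#' synthetic_atlas(4, 4, 2)   # 21 regions
#' @export
synthetic_atlas <- function(n_cgm = 4, n_wm = 4, n_subcortical = 2,
                            cerebellum = TRUE, brainstem = TRUE) {
  stopifnot(n_cgm >= 0, n_wm >= 0, n_subcortical >= 0)
  rows <- list()
  pair <- function(stem, class) {
    data.frame(roi_name = paste0(stem, c("_L", "_R")),
               hemisphere = c("L", "R"), tissue_class = class,
               homotopic_partner = paste0(stem, c("_R", "_L")),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_cgm)) rows <- c(rows, list(pair(sprintf("cGM_%02d", i), "cGM")))
  for (i in seq_len(n_wm)) rows <- c(rows, list(pair(sprintf("WM_%02d", i), "WM")))
  for (i in seq_len(n_subcortical)) {
    rows <- c(rows, list(pair(sprintf("Subcortical_%02d", i), "subcortical")))
  }
  if (cerebellum) rows <- c(rows, list(pair("Cerebellum", "cerebellum")))
  if (brainstem) {
    rows <- c(rows, list(data.frame(
      roi_name = "Brainstem", hemisphere = "U", tissue_class = "brainstem",
      homotopic_partner = NA_character_, stringsAsFactors = FALSE)))
  }
  atlas <- do.call(rbind, rows)
  atlas$label_id <- seq_len(nrow(atlas))
  atlas <- atlas[, c("label_id", "roi_name", "hemisphere", "tissue_class",
                     "homotopic_partner")]
  rownames(atlas) <- NULL
  validate_atlas(atlas)
}

#' Validate an atlas table
#'
#' Checks uniqueness of names, hemisphere and tissue-class domains, and that
#' homotopic pairing is involutive and only links a left region to a right
#' region.
#'
#' @param atlas Atlas data.frame.
#' @return The atlas, invisibly unchanged, or an error naming the offender.
#' @export
validate_atlas <- function(atlas) {
  required <- c("label_id", "roi_name", "hemisphere", "tissue_class",
                "homotopic_partner")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    stop("atlas is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atlas) < 2) stop("atlas must contain at least 2 ROIs", call. = FALSE)
  if (anyDuplicated(atlas$roi_name)) {
    stop("duplicate ROI name(s): ",
         paste(unique(atlas$roi_name[duplicated(atlas$roi_name)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(atlas$label_id)) stop("duplicate atlas label_id", call. = FALSE)
  bad <- !atlas$hemisphere %in% c("L", "R", "U")
  if (any(bad)) {
    stop("invalid hemisphere for ROI ", atlas$roi_name[which(bad)[1]], call. = FALSE)
  }
  bad <- !atlas$tissue_class %in% ATLAS_TISSUE_CLASSES
  if (any(bad)) {
    stop("invalid tissue_class for ROI ", atlas$roi_name[which(bad)[1]], call. = FALSE)
  }
  has_partner <- !is.na(atlas$homotopic_partner) & atlas$homotopic_partner != ""
  for (i in which(has_partner)) {
    p <- match(atlas$homotopic_partner[i], atlas$roi_name)
    if (is.na(p)) {
      stop("homotopic partner of ", atlas$roi_name[i], " not in atlas",
           call. = FALSE)
    }
    if (!identical(atlas$homotopic_partner[p], atlas$roi_name[i])) {
      stop("homotopic pairing not involutive at ", atlas$roi_name[i],
           call. = FALSE)
    }
    hs <- sort(c(atlas$hemisphere[i], atlas$hemisphere[p]))
    if (!identical(hs, c("L", "R"))) {
      stop("homotopic pair ", atlas$roi_name[i], "/", atlas$roi_name[p],
           " must link an L ROI to an R ROI", call. = FALSE)
    }
  }
  if (any(atlas$hemisphere == "U" & has_partner)) {
    stop("unpaired (U) ROIs cannot have a homotopic partner", call. = FALSE)
  }
  invisible(atlas)
}

#' Read / write an atlas TSV
#'
#' @param path Path to a tab-separated atlas file with columns
#'   \code{label_id}, \code{roi_name}, \code{hemisphere},
#'   \code{tissue_class}, \code{homotopic_partner} (empty for unpaired).
#' @return \code{read_atlas}: the validated atlas data.frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if ("label_id" %in% names(atlas)) atlas$label_id <- as.integer(atlas$label_id)
  if ("homotopic_partner" %in% names(atlas)) {
    atlas$homotopic_partner[atlas$homotopic_partner == ""] <- NA_character_
  }
  validate_atlas(atlas)
  atlas
}

#' @rdname read_atlas
#' @param atlas Atlas data.frame.
#' @return \code{write_atlas}: \code{path}, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  out <- atlas
  out$homotopic_partner[is.na(out$homotopic_partner)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Homotopic pairs as a two-column matrix of row indices (L, R), one row per
# pair, ordered by the left member's node index.
homotopic_pairs <- function(atlas) {
  has <- which(!is.na(atlas$homotopic_partner) & atlas$hemisphere == "L")
  cbind(L = has, R = match(atlas$homotopic_partner[has], atlas$roi_name))
}
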