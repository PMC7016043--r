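#' @title Synthetic neonatal cohort generator
#' @description Generates datasets with the statistical structure the MSN
#'   analysis assumes, so the whole pipeline is exercisable without the
#'   restricted cohort: tissue-class archetype metric profiles that produce
#'   the characteristic block structure of the cohort-average MSN (positive
#'   similarity within grey matter and within white matter, negative
#'   between them), age-dependent within-tissue convergence and grey-white
#'   divergence, an optional preterm effect on a fronto-temporal/subcortical
#'   subnetwork, optional extra right-hemisphere age signal, higher absolute
#'   motion in the preterm group, and the cohort's confound correlations
#'   (later scans for term-born and female infants). Homotopic partners
#'   share archetypes and region-specific deviations (mirror symmetry), so
#'   with zero lateralization the hemispheres are exchangeable by
#'   construction.
#' @name synthetic
NULL

#' Synthetic cohort configuration
#'
#' Defaults mirror the reference cohort: 46 term and 59 preterm infants,
#' birth ages 37-42 and 23.42-32 weeks respectively, scan ages in
#' [38, 44.56] weeks with a positive birth-age correlation and a negative
#' sex correlation, and a higher absolute-motion mean in the preterm group.
#'
#' @param n_term,n_preterm Group sizes.
#' @param pma_birth_term,pma_birth_preterm Birth-age ranges (weeks).
#' @param pma_scan_range Scan-age range (weeks).
#' @param age_effect Strength of the age-dependent structure (1 = default
#'   strength; 0 = no age signal in the features).
#' @param group_effect Preterm shift on the designated subnetwork (in units
#'   of the per-metric dispersion scale; 0 = none).
#' @param lateralization Extra right-hemisphere age signal (0 = mirror
#'   symmetric).
#' @param noise_sd Metric noise level in units of the per-metric dispersion
#'   scale.
#' @param scan_birth_slope Weeks of scan age per week of birth age (confound
#'   correlation; 0 disables).
#' @param scan_sex_shift Scan-age shift in weeks for male infants (negative
#'   = males scanned earlier).
#' @param motion_gap Multiplicative absolute-motion excess of the preterm
#'   group (0 = none).
#' @param atlas Atlas to generate over (default the 81-region atlas; use
#'   [synthetic_atlas()] for fast simulation studies).
#' @param seed Master seed; the same seed yields a byte-identical dataset.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_term = 46, n_preterm = 59,
                             pma_birth_term = c(37, 42),
                             pma_birth_preterm = c(23.42, 32),
                             pma_scan_range = c(38, 44.56),
                             age_effect = 1, group_effect = 0,
                             lateralization = 0, noise_sd = 0.6,
                             scan_birth_slope = 0.08,
                             scan_sex_shift = -0.45,
                             motion_gap = 0.5,
                             atlas = default_atlas(), seed = 1) {
  stopifnot(n_term >= 0, n_preterm >= 0, n_term + n_preterm > 0,
            noise_sd > 0, age_effect >= 0, lateralization >= 0)
  validate_atlas(atlas)
  structure(list(n_term = n_term, n_preterm = n_preterm,
                 pma_birth_term = pma_birth_term,
                 pma_birth_preterm = pma_birth_preterm,
                 pma_scan_range = pma_scan_range, age_effect = age_effect,
                 group_effect = group_effect, lateralization = lateralization,
                 noise_sd = noise_sd, scan_birth_slope = scan_birth_slope,
                 scan_sex_shift = scan_sex_shift, motion_gap = motion_gap,
                 atlas = atlas, seed = seed),
            class = "synthetic_config")
}

# Tissue-class archetype profiles over the 12 canonical metrics, in
# physically plausible neonatal ranges; and the dispersion scale used for
# region-specific deviations and noise.
.archetypes <- function() {
  m <- rbind(
    cGM         = c(2600, 1.00, 0.15, 1.30e-3, 1.50e-3, 1.20e-3, 0.70, 0.30, 0.150, 0.45, 0.35, 0.50),
    WM          = c(1800, 1.25, 0.25, 1.10e-3, 1.40e-3, 0.95e-3, 0.90, 0.35, 0.080, 0.30, 0.22, 0.35),
    subcortical = c(1100, 1.35, 0.22, 1.00e-3, 1.30e-3, 0.90e-3, 1.00, 0.40, 0.060, 0.35, 0.28, 0.40),
    brainstem   = c(2200, 1.50, 0.30, 0.95e-3, 1.35e-3, 0.80e-3, 1.10, 0.45, 0.050, 0.25, 0.18, 0.30),
    cerebellum  = c(2400, 1.20, 0.18, 1.15e-3, 1.40e-3, 1.05e-3, 0.85, 0.33, 0.090, 0.40, 0.30, 0.45))
  colnames(m) <- metric_names()
  m
}

.dispersion_scale <- function() {
  s <- c(400, 0.08, 0.030, 0.08e-3, 0.08e-3, 0.08e-3, 0.08, 0.040, 0.030,
         0.040, 0.040, 0.040)
  names(s) <- metric_names()
  s
}

# Clip generated values into their valid domains; count clip events.
.clip_metrics <- function(mat) {
  clipped <- 0L
  for (m in colnames(mat)) {
    x <- mat[, m]
    if (m %in% c("Volume", "MD", "AD", "RD")) {
      lo <- if (m == "Volume") 1 else 1e-5
      bad <- x < lo
    } else if (m == "T1T2" || m == "MK") {
      bad <- x < 1e-3
      lo <- 1e-3
    } else {
      bad <- x < 1e-4 | x > 0.999
      x[x > 0.999] <- 0.999
      lo <- 1e-4
    }
    x[x < lo] <- lo
    clipped <- clipped + sum(bad)
    mat[, m] <- x
  }
  attr(mat, "n_clipped") <- clipped
  mat
}

#' Generate a synthetic cohort
#'
#' Draws metadata (birth/scan ages, sex, motion) respecting the configured
#' ranges and confound structure, then builds each subject's regional
#' metrics as: class archetype whose between-class contrast grows with scan
#' age (grey-white divergence), plus a region-specific deviation shared by
#' homotopic partners whose amplitude shrinks with scan age (within-tissue
#' convergence), plus a preterm shift on a designated
#' fronto-temporal/subcortical subnetwork, plus extra age signal on
#' right-hemisphere regions when lateralization is positive, plus i.i.d.
#' noise. Values are clipped into their valid domains (clip count recorded
#' as attribute \code{n_clipped}).
#'
#' @param cfg A [synthetic_config()].
#' @return A validated \code{msn_dataset} with attribute \code{config}.
#' @examples
#' ds <- generate_cohort(synthetic_config(n_term = 5, n_preterm = 5,
#'                                        atlas = synthetic_atlas()))
#' ds
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  atlas <- cfg$atlas
  n <- cfg$n_term + cfg$n_preterm
  arch <- .archetypes()
  disp <- .dispersion_scale()
  metrics <- metric_names()

  with_seed(cfg$seed, {
    group <- c(rep("term", cfg$n_term), rep("preterm", cfg$n_preterm))
    pma_birth <- c(stats::runif(cfg$n_term, cfg$pma_birth_term[1],
                                cfg$pma_birth_term[2]),
                   stats::runif(cfg$n_preterm, cfg$pma_birth_preterm[1],
                                cfg$pma_birth_preterm[2]))
    sex <- stats::rbinom(n, 1, 0.5)
    lo <- cfg$pma_scan_range[1]
    hi <- cfg$pma_scan_range[2]
    pma_scan <- (lo + hi) / 2 +
      cfg$scan_birth_slope * (pma_birth - mean(pma_birth)) +
      cfg$scan_sex_shift * (sex - 0.5) +
      stats::rnorm(n, 0, (hi - lo) / 4.5)
    pma_scan <- pmin(pmax(pma_scan, lo), hi)
    pma_scan <- pmax(pma_scan, pma_birth + 0.5)  # scan strictly after birth
    pma_scan <- pmin(pma_scan, 46)
    motion_abs <- exp(stats::rnorm(n, log(0.45), 0.35)) *
      ifelse(group == "preterm", 1 + cfg$motion_gap, 1)
    motion_rel <- exp(stats::rnorm(n, log(0.12), 0.30))
    meta <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                       pma_birth = pma_birth, pma_scan = pma_scan,
                       sex = sex, group = group,
                       motion_abs = motion_abs, motion_rel = motion_rel,
                       stringsAsFactors = FALSE)

    # Region-specific deviations, shared between homotopic partners so the
    # hemispheres are mirror symmetric by construction.
    n_roi <- nrow(atlas)
    roi_dev <- matrix(stats::rnorm(n_roi * length(metrics)), n_roi,
                      length(metrics), dimnames = list(atlas$roi_name, metrics))
    pairs <- homotopic_pairs(atlas)
    roi_dev[pairs[, "R"], ] <- roi_dev[pairs[, "L"], ]
    roi_dev <- sweep(roi_dev, 2, disp, "*")

    # Preterm-affected subnetwork: fronto-temporal and subcortical regions.
    sub_idx <- grepl("Frontal|temporal|Temporal", atlas$roi_name) |
      atlas$tissue_class == "subcortical"
    shift_dir <- stats::rnorm(length(metrics))  # fixed shift direction
    right <- atlas$hemisphere == "R"

    conv_rate <- 0.06 * cfg$age_effect   # within-class convergence per week
    sep_rate <- 0.04 * cfg$age_effect    # grey-white divergence per week

    tables <- list()
    n_clipped <- 0L
    for (s in seq_len(n)) {
      dt <- pma_scan[s] - 40
      lat <- 1 + cfg$lateralization * right   # per-ROI age-signal gain
      base <- arch[atlas$tissue_class, , drop = FALSE]
      contrast <- sweep(base, 2, colMeans(arch[c("cGM", "WM"), ]))
      age_gain <- 1 + sep_rate * dt * lat
      dev_gain <- pmax(1 - conv_rate * dt * lat, 0.05)
      vals <- sweep(contrast, 1, age_gain - 1, "*") + base +
        roi_dev * as.vector(dev_gain)
      if (group[s] == "preterm" && cfg$group_effect != 0) {
        vals[sub_idx, ] <- vals[sub_idx, ] +
          cfg$group_effect * outer(rep(1, sum(sub_idx)), shift_dir * disp)
      }
      noise <- matrix(stats::rnorm(n_roi * length(metrics)), n_roi,
                      length(metrics))
      vals <- vals + cfg$noise_sd * sweep(noise, 2, disp, "*")
      dimnames(vals) <- list(atlas$roi_name, metrics)
      vals <- .clip_metrics(vals)
      n_clipped <- n_clipped + attr(vals, "n_clipped")
      attr(vals, "n_clipped") <- NULL
      tables[[meta$subject_id[s]]] <- vals
    }
    ds <- msn_dataset(atlas, meta, tables)
    attr(ds, "config") <- cfg
    attr(ds, "n_clipped") <- n_clipped
    ds
  })
}

#' Generate a null cohort
#'
#' As [generate_cohort()] but with every feature-target association removed:
#' zero age effect, zero group effect, zero lateralization, and additionally
#' zero confound structure (no motion gap and no scan-age correlations with
#' birth age or sex), so the prediction targets are fully independent of
#' both the features and the appended covariates.
#'
#' @param cfg A [synthetic_config()]; its effect and confound parameters are
#'   overridden to zero.
#' @return A validated \code{msn_dataset}.
#' @export
generate_null_cohort <- function(cfg = synthetic_config()) {
  cfg$age_effect <- 0
  cfg$group_effect <- 0
  cfg$lateralization <- 0
  cfg$motion_gap <- 0
  cfg$scan_birth_slope <- 0
  cfg$scan_sex_shift <- 0
  generate_cohort(cfg)
}
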