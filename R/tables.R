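# Default calibration tables for the synthetic cohort and phantoms.
#
# The biomarker population parameters, Fazekas group sizes, per-score NAWM
# distributions and vascular-risk-factor incidences are the published
# LBC1936 cohort summaries for the four white matter biomarkers (FA
# unitless, MD in 1e-9 m^2/s, MTR in %, T1 in s).  The structural contrast
# table is synthetic plumbing: arbitrary scanner units chosen so the
# red-green fusion rules are solvable (FLAIR hyperintense WMH, T2W bright
# CSF, T1W bright NAWM).

#' Default biomarker population table
#'
#' Per-tissue means and SDs of the four biomarkers across the cohort:
#' FA (unitless), MD (1e-9 m^2/s), MTR (%), T1 (s).  `rho` is the
#' between-tissue subject-level correlation used for paired draws; it is a
#' generator parameter (default 0.6) and does not affect pooled-SD effect
#' sizes.
#'
#' @param rho Between-tissue correlation in `[-1, 1]`.
#' @return A data.frame with columns `biomarker`, `mean_nawm`, `sd_nawm`,
#'   `mean_wmh`, `sd_wmh` and attribute `rho`.
#' @export
default_biomarker_table <- function(rho = 0.6) {
  if (!is.finite(rho) || rho < -1 || rho > 1) stop("rho must be in [-1, 1]")
  tab <- data.frame(
    biomarker = c("FA", "MD", "MTR", "T1"),
    mean_nawm = c(0.338, 0.692, 56.80, 1.002),
    sd_nawm   = c(0.024, 0.034, 0.99, 0.092),
    mean_wmh  = c(0.299, 0.833, 54.37, 1.086),
    sd_wmh    = c(0.042, 0.061, 1.51, 0.117),
    stringsAsFactors = FALSE)
  attr(tab, "rho") <- rho
  tab
}

#' Default Fazekas group sizes
#'
#' Number of subjects at each total Fazekas score 0..6 (sums to 676) and
#' the male count per group, as observed in the cohort.
#'
#' @return A data.frame with columns `score`, `n`, `n_male`.
#' @export
default_group_sizes <- function() {
  data.frame(score = 0:6,
             n = c(9L, 100L, 311L, 143L, 72L, 28L, 13L),
             n_male = c(6L, 57L, 161L, 86L, 32L, 13L, 3L))
}

#' Default per-score NAWM biomarker distributions
#'
#' Mean (SD) of each biomarker measured in NAWM for each total Fazekas
#' score group.  These are the marginals the cohort generator draws
#' per-subject NAWM summaries from.
#'
#' @return A data.frame with columns `score`, `biomarker`, `mean`, `sd`.
#' @export
default_score_nawm_table <- function() {
  scores <- 0:6
  fa_m  <- c(0.336, 0.343, 0.342, 0.335, 0.328, 0.314, 0.299)
  fa_s  <- c(0.037, 0.020, 0.023, 0.022, 0.023, 0.026, 0.025)
  md_m  <- c(0.675, 0.681, 0.688, 0.698, 0.709, 0.712, 0.720)
  md_s  <- c(0.042, 0.031, 0.033, 0.035, 0.034, 0.028, 0.029)
  mtr_m <- c(56.9, 56.7, 56.8, 57.0, 56.5, 56.8, 56.5)
  mtr_s <- c(1.0, 1.1, 0.9, 0.9, 1.0, 1.0, 1.1)
  t1_m  <- c(1.02, 1.00, 0.99, 1.00, 1.01, 1.07, 1.09)
  t1_s  <- c(0.12, 0.10, 0.09, 0.09, 0.09, 0.07, 0.11)
  data.frame(
    score = rep(scores, times = 4),
    biomarker = rep(c("FA", "MD", "MTR", "T1"), each = 7),
    mean = c(fa_m, md_m, mtr_m, t1_m),
    sd = c(fa_s, md_s, mtr_s, t1_s),
    stringsAsFactors = FALSE)
}

#' Default vascular risk factor incidence
#'
#' Self-reported VRF incidence (percent) by gender.  Smoking status is a
#' single categorical draw (current/ex/never); the remaining factors are
#' independent Bernoulli flags.
#'
#' @return A data.frame with columns `factor`, `male_pct`, `female_pct`.
#' @export
default_vrf_incidence <- function() {
  data.frame(
    factor = c("current_smoker", "ex_smoker", "hypertension", "diabetes",
               "hypercholesterolemia", "cardiovascular_disease", "stroke"),
    male_pct   = c(7.8, 50.8, 50.8, 13.1, 42.5, 33.2, 18.2),
    female_pct = c(8.5, 38.7, 46.9, 6.6, 40.9, 19.8, 15.6),
    stringsAsFactors = FALSE)
}

#' Default structural contrast table
#'
#' Synthetic per-(tissue, modality) mean intensities and noise SDs in
#' arbitrary scanner units, for the four structural contrasts.  Values are
#' chosen so the documented tissue orderings hold: FLAIR(WMH) > FLAIR(NAWM)
#' with CSF suppressed, T2W(CSF) > T2W(NAWM), T1W(NAWM) bright.  These
#' orderings make the colour-fusion segmentation solvable; absolute values
#' are arbitrary.
#'
#' @param noise_sd Gaussian noise SD applied to every (tissue, modality)
#'   pair; default 8 units, roughly SNR 15-25 for the tissue means used.
#' @return A data.frame with columns `tissue`, `modality`, `mean`, `sd`.
#' @export
default_contrast_table <- function(noise_sd = 8) {
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  means <- rbind(
    # T1W, T2W, FLAIR, T2*W
    background = c(5,   5,   5,   5),
    csf        = c(30,  230, 30,  220),
    nawm       = c(200, 60,  70,  140),
    wmh        = c(120, 150, 220, 110),
    stroke     = c(100, 160, 200, 100))
  data.frame(
    tissue = rep(rownames(means), times = 4),
    modality = rep(c("T1W", "T2W", "FLAIR", "T2starW"), each = 5),
    mean = as.vector(means),
    sd = noise_sd,
    stringsAsFactors = FALSE)
}

#' Default CSF parametric values
#'
#' Fixed biomarker values assigned to CSF (and, with zeros, background)
#' voxels in synthetic parametric maps: plausible free-fluid values.  They
#' only matter for partial-volume behaviour at mask borders.
#'
#' @return Named numeric vector for FA, MD, MTR, T1.
#' @export
default_csf_parametric <- function() {
  c(FA = 0.1, MD = 3.0, MTR = 5, T1 = 4.0)
}

#' Default penumbra configuration
#'
#' Distance-decaying NAWM gradient around lesions: at Euclidean distance
#' `d` mm from the nearest WMH voxel, a NAWM voxel's expected biomarker
#' value is shifted toward the WMH mean by
#' `alpha * exp(-d / lambda) * (mean_wmh - mean_nawm)`.
#' Defaults (`alpha = 0.3`, `lambda = 4` mm) qualitatively reproduce
#' decaying shell profiles; they are synthetic choices, not estimates.
#'
#' @param alpha Edge amplitude as a fraction of the NAWM-to-WMH difference,
#'   in `[0, 1]`.
#' @param lambda Decay length in mm, `> 0`.
#' @return A list of class `penumbra_config`.
#' @export
penumbra_config <- function(alpha = 0.3, lambda = 4) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be > 0")
  structure(list(alpha = alpha, lambda = lambda), class = "penumbra_config")
}
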