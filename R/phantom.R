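# Synthetic subject generator: 3-D tissue label geometry, structural
# contrasts, parametric biomarker maps, and cohort-level summary draws.
#
# The geometry is deliberately schematic (ellipsoidal lateral ventricles in
# a white-matter ellipsoid, periventricular caps and deep spheres for
# lesions); what is calibrated is the statistical structure: tissue
# contrast orderings, biomarker distributions per tissue and per Fazekas
# group, group sizes, gender fractions and risk-factor incidence.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# voxel-center coordinates (mm) relative to the grid center, per axis
axis_coords <- function(n, w) (seq_len(n) - (n + 1) / 2) * w

# mm coordinates of every voxel as three arrays matching the grid
grid_coords <- function(shape, voxel_dims) {
  cx <- axis_coords(shape[1], voxel_dims[1])
  cy <- axis_coords(shape[2], voxel_dims[2])
  cz <- axis_coords(shape[3], voxel_dims[3])
  list(x = array(rep(cx, times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(cy, each = shape[1]), times = shape[3]), dim = shape),
       z = array(rep(cz, each = shape[1] * shape[2]), dim = shape))
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

# periventricular cap thickness (mm) per periventricular score 0..3;
# starts at 4 mm so a 1-voxel (2 mm) CSF dilation never erases a cap
PV_CAP_MM <- c(0, 4, 6, 8)
DEEP_RADIUS_MM <- function(deep) 2 + deep   # sphere radius per deep score
DEEP_COUNT <- function(deep) 2L * deep      # sphere count per deep score

#' Generate a ground-truth label phantom
#'
#' Builds a schematic head: an ellipsoidal white-matter compartment (NAWM)
#' containing two ellipsoidal lateral-ventricle CSF bodies, plus WMH whose
#' total volume grows monotonically with the requested total Fazekas score.
#' The score is split into a periventricular part (rind of NAWM adjacent to
#' the ventricles, thicker for higher scores) and a deep part (isolated
#' spheres, more and larger for higher scores), mirroring the
#' periventricular/deep decomposition of the visual rating.  The generator
#' records the target scores as ground truth rather than re-deriving them
#' visually.
#'
#' @param shape Integer voxel triple; must be large enough to hold the
#'   ventricles plus a >= 12 mm NAWM margin (so 10 mm shells fit).
#' @param voxel_dims Voxel dimensions in mm (default 2 mm isotropic).
#' @param target_score Total Fazekas score 0..6; 0 means no WMH voxels.
#' @param seed RNG seed controlling deep-lesion placement; the same
#'   arguments and seed always give the identical volume, and at a fixed
#'   seed the WMH voxel count is non-decreasing in `target_score`.
#' @param stroke If TRUE, adds one spherical "old stroke" lesion (label 4)
#'   in NAWM, standing in for the neuroradiologist-delineated stroke mask.
#' @return A `label_volume` with attributes `fazekas_pv`, `fazekas_deep`.
#' @export
make_label_phantom <- function(shape = c(64, 64, 64), voxel_dims = c(2, 2, 2),
                               target_score = 2, seed = NULL, stroke = FALSE) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("bad shape")
  if (!target_score %in% 0:6) stop("target_score must be in 0..6")
  fov <- shape * voxel_dims
  brain_semi <- 0.42 * fov
  vent_semi <- c(8, 20, 12)
  vent_off <- 12
  need <- c(vent_off + vent_semi[1] + 12, vent_semi[2] + 12, vent_semi[3] + 12)
  if (any(brain_semi < need))
    stop("sizing error: grid too small for ventricles plus a 12 mm NAWM margin")

  co <- grid_coords(shape, voxel_dims)
  brain <- ellipsoid_mask(co, c(0, 0, 0), brain_semi)
  csf <- ellipsoid_mask(co, c(-vent_off, 0, 0), vent_semi) |
    ellipsoid_mask(co, c(vent_off, 0, 0), vent_semi)
  csf <- csf & brain

  labels <- array(0L, dim = shape)
  labels[brain] <- label_codes()[["nawm"]]
  labels[csf] <- label_codes()[["csf"]]

  pv <- as.integer(ceiling(target_score / 2))
  deep <- as.integer(floor(target_score / 2))

  nawm <- labels == label_codes()[["nawm"]]
  dist_csf <- distance_transform(binary_mask(csf, voxel_dims))$data

  wmh <- array(FALSE, dim = shape)
  if (pv > 0)
    wmh <- wmh | (nawm & dist_csf <= PV_CAP_MM[pv + 1] + 1e-9)

  # candidate deep centers: drawn once from the seed and consumed in order,
  # so lesion sets are nested across scores at a fixed seed
  n_centers <- DEEP_COUNT(3L) + as.integer(stroke)
  centers <- with_seed_if(if (is.null(seed)) 0L else seed, {
    eligible <- which(nawm & dist_csf >= 12 &
                        (co$x / brain_semi[1])^2 + (co$y / brain_semi[2])^2 +
                        (co$z / brain_semi[3])^2 <= 0.8^2)
    ord <- sample(eligible)
    picked <- integer(0)
    sep <- 2 * DEEP_RADIUS_MM(3L) + 4  # separation for the largest radius
    for (v in ord) {
      pos <- c(co$x[v], co$y[v], co$z[v])
      ok <- TRUE
      for (p in picked) {
        q <- c(co$x[p], co$y[p], co$z[p])
        if (sqrt(sum((pos - q)^2)) < sep) { ok <- FALSE; break }
      }
      if (ok) picked <- c(picked, v)
      if (length(picked) >= n_centers) break
    }
    if (length(picked) < n_centers)
      stop("sizing error: could not place deep lesions in NAWM")
    picked
  })

  if (deep > 0) {
    r <- DEEP_RADIUS_MM(deep)
    for (v in centers[seq_len(DEEP_COUNT(deep))]) {
      ctr <- c(co$x[v], co$y[v], co$z[v])
      wmh <- wmh | (nawm & ellipsoid_mask(co, ctr, rep(r, 3)))
    }
  }
  labels[wmh] <- label_codes()[["wmh"]]

  if (stroke) {
    v <- centers[n_centers]
    ctr <- c(co$x[v], co$y[v], co$z[v])
    st <- nawm & !wmh & ellipsoid_mask(co, ctr, rep(4, 3))
    labels[st] <- label_codes()[["stroke"]]
  }

  out <- label_volume(labels, voxel_dims)
  attr(out, "fazekas_pv") <- pv
  attr(out, "fazekas_deep") <- deep
  out
}

contrast_lookup <- function(contrasts, modality, labels_present) {
  sub <- contrasts[contrasts$modality == modality, ]
  names_needed <- names(label_codes())[match(labels_present, label_codes())]
  miss <- setdiff(names_needed, sub$tissue)
  if (length(miss))
    stop("configuration error: contrast table missing (",
         paste(miss, collapse = ", "), ", ", modality, ")")
  sub
}

#' Synthesize structural contrast volumes from a label phantom
#'
#' Each voxel's intensity is its tissue's mean plus Gaussian noise with the
#' tissue's SD, per modality.  All four volumes share the label grid
#' exactly (the phantoms are born co-registered; no registration is
#' modelled).
#'
#' @param labels A `label_volume`.
#' @param contrasts A contrast table as from [default_contrast_table()];
#'   must cover every (tissue, modality) pair present.
#' @param seed RNG seed; same seed, same arguments, identical outputs.
#' @return Named list of `volume_grid`s: `T1W`, `T2W`, `FLAIR`, `T2starW`.
#' @export
synthesize_structural <- function(labels, contrasts = default_contrast_table(),
                                  seed = NULL) {
  stopifnot(inherits(labels, "volume_grid"))
  present <- sort(unique(as.vector(labels$data)))
  modalities <- c("T1W", "T2W", "FLAIR", "T2starW")
  with_seed_if(seed, {
    out <- lapply(modalities, function(mod) {
      tab <- contrast_lookup(contrasts, mod, present)
      mu <- sig <- array(0, dim = dim(labels$data))
      for (k in seq_len(nrow(tab))) {
        code <- label_codes()[[tab$tissue[k]]]
        sel <- labels$data == code
        mu[sel] <- tab$mean[k]
        sig[sel] <- tab$sd[k]
      }
      noise <- array(stats::rnorm(length(mu)), dim = dim(mu))
      volume_grid(mu + sig * noise, labels$voxel_dims)
    })
    names(out) <- modalities
    out
  })
}

#' Synthesize parametric biomarker maps from a label phantom
#'
#' NAWM and WMH voxels are drawn around their tissue means with the table's
#' SDs (scaled by `noise_scale`; 0 gives noiseless expected values).  CSF
#' voxels receive fixed fluid values and background is 0.  When a penumbra
#' is configured, a NAWM voxel at Euclidean distance `d` mm from the
#' nearest WMH voxel has its expected value shifted toward the WMH mean by
#' `alpha * exp(-d / lambda) * (mean_wmh - mean_nawm)`, modelling graded
#' abnormality of the tissue surrounding lesions.
#'
#' @param labels A `label_volume`.
#' @param table Biomarker table as from [default_biomarker_table()].
#' @param penumbra A [penumbra_config()] or NULL for none.  `alpha = 0` is
#'   identical to NULL.
#' @param noise_scale Multiplier on the table SDs for voxel-level noise.
#' @param csf_values Named biomarker values for CSF voxels.
#' @param seed RNG seed.
#' @return Named list of `volume_grid`s: `FA`, `MD`, `MTR`, `T1`.
#' @export
synthesize_parametric <- function(labels, table = default_biomarker_table(),
                                  penumbra = NULL, noise_scale = 1,
                                  csf_values = default_csf_parametric(),
                                  seed = NULL) {
  stopifnot(inherits(labels, "volume_grid"))
  if (!is.null(penumbra) && !inherits(penumbra, "penumbra_config"))
    stop("penumbra must be a penumbra_config or NULL")
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("noise_scale must be >= 0")
  codes <- label_codes()
  is_nawm <- labels$data == codes[["nawm"]]
  is_wmh <- labels$data == codes[["wmh"]]
  is_csf <- labels$data == codes[["csf"]]
  is_stroke <- labels$data == codes[["stroke"]]

  dist_wmh <- NULL
  if (!is.null(penumbra) && penumbra$alpha > 0 && any(is_wmh))
    dist_wmh <- distance_transform(binary_mask(is_wmh, labels$voxel_dims))$data

  with_seed_if(seed, {
    out <- lapply(seq_len(nrow(table)), function(k) {
      bm <- table$biomarker[k]
      mu <- array(0, dim = dim(labels$data))
      sig <- array(0, dim = dim(labels$data))
      mu[is_nawm] <- table$mean_nawm[k]
      sig[is_nawm] <- table$sd_nawm[k] * noise_scale
      mu[is_wmh] <- table$mean_wmh[k]
      sig[is_wmh] <- table$sd_wmh[k] * noise_scale
      # stroke tissue shares the WMH distribution; it is excluded from the
      # analysis masks anyway
      mu[is_stroke] <- table$mean_wmh[k]
      sig[is_stroke] <- table$sd_wmh[k] * noise_scale
      mu[is_csf] <- csf_values[[bm]]
      if (!is.null(dist_wmh)) {
        shift <- penumbra$alpha * exp(-dist_wmh / penumbra$lambda) *
          (table$mean_wmh[k] - table$mean_nawm[k])
        mu[is_nawm] <- mu[is_nawm] + shift[is_nawm]
      }
      noise <- array(stats::rnorm(length(mu)), dim = dim(mu))
      volume_grid(mu + sig * noise, labels$voxel_dims)
    })
    names(out) <- table$biomarker
    out
  })
}

#' Simulate a cohort of per-subject tissue summaries
#'
#' Draws one subject record per row of the design: total Fazekas score
#' (split into periventricular and deep parts), gender (per-group male
#' fraction), age in days (uniform over 71.0-74.2 years), and for every
#' biomarker a paired (NAWM, WMH) pair of subject-level means from a
#' bivariate Gaussian with between-tissue correlation `rho` (an attribute
#' of `table`).  The NAWM marginal comes from the subject's Fazekas group
#' row of `per_score_nawm`; the WMH marginal from `table`.  With
#' `per_score_nawm = NULL` the NAWM marginal also comes from `table` for
#' every group (pure two-tissue calibration).
#'
#' @param group_sizes Data frame with columns `score`, `n` (and optionally
#'   `n_male`); default [default_group_sizes()] (totals 676 subjects).
#' @param table Biomarker table as from [default_biomarker_table()].
#' @param per_score_nawm Per-score NAWM table as from
#'   [default_score_nawm_table()], or NULL.
#' @param seed RNG seed.
#' @return A data.frame with one row per subject: `id`, `fazekas_pv`,
#'   `fazekas_deep`, `fazekas_total`, `gender`, `age_days`, and per
#'   biomarker `nawm_<b>` and `wmh_<b>` columns.
#' @export
make_cohort <- function(group_sizes = default_group_sizes(),
                        table = default_biomarker_table(),
                        per_score_nawm = default_score_nawm_table(),
                        seed = NULL) {
  if (any(group_sizes$n < 0)) stop("validation error: group size < 0")
  rho <- attr(table, "rho")
  if (is.null(rho)) rho <- 0.6
  scores <- rep(group_sizes$score, times = group_sizes$n)
  n <- length(scores)
  if (n == 0L) stop("validation error: empty cohort")
  male_frac <- if ("n_male" %in% names(group_sizes)) {
    ifelse(group_sizes$n > 0, group_sizes$n_male / pmax(group_sizes$n, 1), 0.5)
  } else rep(0.5, nrow(group_sizes))

  with_seed_if(seed, {
    pv <- as.integer(ceiling(scores / 2))
    dp <- as.integer(floor(scores / 2))
    pmale <- male_frac[match(scores, group_sizes$score)]
    gender <- ifelse(stats::runif(n) < pmale, "M", "F")
    age_days <- as.integer(round(stats::runif(n, 71.0, 74.2) * 365.25))
    out <- data.frame(id = sprintf("S%04d", seq_len(n)),
                      fazekas_pv = pv, fazekas_deep = dp,
                      fazekas_total = scores, gender = gender,
                      age_days = age_days, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(table))) {
      bm <- table$biomarker[k]
      if (is.null(per_score_nawm)) {
        mu_n <- rep(table$mean_nawm[k], n)
        sd_n <- rep(table$sd_nawm[k], n)
      } else {
        rows <- per_score_nawm[per_score_nawm$biomarker == bm, ]
        idx <- match(scores, rows$score)
        if (any(is.na(idx)))
          stop("per_score_nawm is missing rows for biomarker ", bm)
        mu_n <- rows$mean[idx]
        sd_n <- rows$sd[idx]
      }
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      nawm <- mu_n + sd_n * z1
      wmh <- table$mean_wmh[k] +
        table$sd_wmh[k] * (rho * z1 + sqrt(1 - rho^2) * z2)
      out[[paste0("nawm_", bm)]] <- nawm
      out[[paste0("wmh_", bm)]] <- wmh
    }
    out
  })
}

#' Assign vascular risk factor flags to a cohort
#'
#' Smoking status (current/ex/never) is one categorical draw per subject at
#' the gender-specific rates; the remaining factors are independent
#' Bernoulli draws at the gender-specific incidence.
#'
#' @param cohort A cohort data.frame (needs a `gender` column).
#' @param incidence Incidence table as from [default_vrf_incidence()],
#'   percentages in `[0, 100]`.
#' @param seed RNG seed.
#' @return The cohort with added logical columns, one per factor, plus a
#'   `smoking` factor column (`current`/`ex`/`never`).
#' @export
assign_vrf <- function(cohort, incidence = default_vrf_incidence(),
                       seed = NULL) {
  if (!all(c("male_pct", "female_pct") %in% names(incidence)) ||
      any(!is.finite(incidence$male_pct)) || any(!is.finite(incidence$female_pct)) ||
      any(incidence$male_pct < 0 | incidence$male_pct > 100) ||
      any(incidence$female_pct < 0 | incidence$female_pct > 100))
    stop("validation error: incidence percentages must be in [0, 100]")
  n <- nrow(cohort)
  male <- cohort$gender == "M"
  rate <- function(fac) {
    row <- incidence[incidence$factor == fac, ]
    if (nrow(row) != 1L) return(rep(0, n))
    ifelse(male, row$male_pct, row$female_pct) / 100
  }
  p_cur <- rate("current_smoker")
  p_ex <- rate("ex_smoker")
  if (any(p_cur + p_ex > 1))
    stop("validation error: current + ex smoker rates exceed 100%")
  with_seed_if(seed, {
    u <- stats::runif(n)
    smoking <- ifelse(u < p_cur, "current",
                      ifelse(u < p_cur + p_ex, "ex", "never"))
    cohort$smoking <- factor(smoking, levels = c("never", "ex", "current"))
    cohort$current_smoker <- smoking == "current"
    cohort$ex_smoker <- smoking == "ex"
    for (fac in setdiff(incidence$factor, c("current_smoker", "ex_smoker")))
      cohort[[fac]] <- stats::runif(n) < rate(fac)
    cohort
  })
}
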