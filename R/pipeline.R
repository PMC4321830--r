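# End-to-end orchestration: configuration, the cohort-level summary study
# (statistics on simulated subject means; cheap, used for the calibration
# checks), and the volumetric study (full phantom -> segmentation ->
# shells -> statistics path at small n).

#' Build a pipeline configuration
#'
#' All defaults are the calibrated cohort tables; every field is
#' overridable.  The configuration round-trips through JSON via
#' [write_config()] / [read_config()].
#'
#' @param group_sizes Fazekas group sizes (data.frame `score`, `n`,
#'   optionally `n_male`).
#' @param biomarker_table Population biomarker table (see
#'   [default_biomarker_table()]).
#' @param score_nawm Per-score NAWM marginals (see
#'   [default_score_nawm_table()]).
#' @param vrf_incidence VRF incidence table (see
#'   [default_vrf_incidence()]).
#' @param contrast_noise_sd Structural noise SD in scanner units.
#' @param penumbra_alpha,penumbra_lambda Penumbra amplitude (0 disables)
#'   and decay length in mm.
#' @param parametric_noise_scale Voxel-noise multiplier on the biomarker
#'   SDs in synthetic maps.
#' @param n_levels Colour levels for the quantizer.
#' @param shell_step_mm,shell_max_mm Shell spacing and outer distance.
#' @param shape,voxel_dims Phantom grid.
#' @param min_wmh_voxels Segmented WMH masks smaller than this are treated
#'   as "no lesion" (the subject skips the shell stage).
#' @param seed Base RNG seed for a run.
#' @param out_dir Optional output directory for result CSVs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(group_sizes = default_group_sizes(),
                            biomarker_table = default_biomarker_table(),
                            score_nawm = default_score_nawm_table(),
                            vrf_incidence = default_vrf_incidence(),
                            contrast_noise_sd = 8,
                            penumbra_alpha = 0.3,
                            penumbra_lambda = 4,
                            parametric_noise_scale = 1,
                            n_levels = 16,
                            shell_step_mm = 2,
                            shell_max_mm = 10,
                            shape = c(64, 64, 64),
                            voxel_dims = c(2, 2, 2),
                            min_wmh_voxels = 5,
                            seed = 1,
                            out_dir = NULL) {
  cfg <- list(group_sizes = group_sizes, biomarker_table = biomarker_table,
              rho = attr(biomarker_table, "rho") %||% 0.6,
              score_nawm = score_nawm, vrf_incidence = vrf_incidence,
              contrast_noise_sd = contrast_noise_sd,
              penumbra_alpha = penumbra_alpha,
              penumbra_lambda = penumbra_lambda,
              parametric_noise_scale = parametric_noise_scale,
              n_levels = n_levels, shell_step_mm = shell_step_mm,
              shell_max_mm = shell_max_mm, shape = shape,
              voxel_dims = voxel_dims, min_wmh_voxels = min_wmh_voxels,
              seed = seed, out_dir = out_dir)
  problems <- character(0)
  if (any(cfg$group_sizes$n < 0)) problems <- c(problems, "negative group size")
  if (cfg$penumbra_alpha < 0 || cfg$penumbra_alpha > 1)
    problems <- c(problems, "penumbra_alpha outside [0, 1]")
  if (cfg$penumbra_lambda <= 0) problems <- c(problems, "penumbra_lambda <= 0")
  if (cfg$n_levels < 2) problems <- c(problems, "n_levels < 2")
  if (cfg$shell_step_mm <= 0 || cfg$shell_max_mm < cfg$shell_step_mm)
    problems <- c(problems, "bad shell spacing")
  if (length(problems))
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline configuration to JSON
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON path written by [write_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  bt <- as_df(raw$biomarker_table)
  attr(bt, "rho") <- raw$rho %||% 0.6
  pipeline_config(group_sizes = as_df(raw$group_sizes),
                  biomarker_table = bt,
                  score_nawm = as_df(raw$score_nawm),
                  vrf_incidence = as_df(raw$vrf_incidence),
                  contrast_noise_sd = raw$contrast_noise_sd,
                  penumbra_alpha = raw$penumbra_alpha,
                  penumbra_lambda = raw$penumbra_lambda,
                  parametric_noise_scale = raw$parametric_noise_scale,
                  n_levels = raw$n_levels,
                  shell_step_mm = raw$shell_step_mm,
                  shell_max_mm = raw$shell_max_mm,
                  shape = raw$shape, voxel_dims = raw$voxel_dims,
                  min_wmh_voxels = raw$min_wmh_voxels,
                  seed = raw$seed, out_dir = raw$out_dir)
}

vrf_covariates <- function(cohort) {
  data.frame(smoking = cohort$smoking,
             hypertension = cohort$hypertension,
             diabetes = cohort$diabetes,
             hypercholesterolemia = cohort$hypercholesterolemia,
             cardiovascular_disease = cohort$cardiovascular_disease,
             stroke = cohort$stroke)
}

#' Run the cohort-level summary study
#'
#' Simulates per-subject paired (NAWM, WMH) biomarker summaries from the
#' configured tables, then runs the full statistics layer: paired t tests
#' with pooled-SD Cohen's d, per-biomarker ROC discrimination, per-score
#' NAWM means with Fazekas-trend ANCOVA (with and without the VRF block,
#' compared by a nested F test), and gender-incidence chi-squared tests.
#' Deterministic given the config seed; result tables are written as CSVs
#' when `out_dir` is set.
#'
#' @param config A `pipeline_config`.
#' @return List with data.frames `tissue_contrast` (per biomarker: tissue
#'   means/SDs, paired t, Cohen d), `roc` (AUC, CI, threshold, sens, spec,
#'   accuracy), `score_trend` (per-score NAWM summaries plus ANCOVA F, p,
#'   R2 with and without VRF and the nested F), `vrf_incidence`, and the
#'   simulated `cohort`.
#' @export
run_summary_study <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  bt <- config$biomarker_table
  attr(bt, "rho") <- config$rho
  cohort <- make_cohort(config$group_sizes, bt, config$score_nawm, seed = seed)
  cohort <- assign_vrf(cohort, config$vrf_incidence, seed = seed + 1L)

  biomarkers <- bt$biomarker
  tissue_contrast <- do.call(rbind, lapply(biomarkers, function(bm) {
    x <- cohort[[paste0("nawm_", bm)]]
    y <- cohort[[paste0("wmh_", bm)]]
    tt <- paired_t(x, y)
    data.frame(biomarker = bm,
               mean_nawm = mean(x), sd_nawm = stats::sd(x),
               mean_wmh = mean(y), sd_wmh = stats::sd(y),
               t = tt$t, df = tt$df, p = tt$p,
               cohen_d = cohen_d_pooled(mean(x), stats::sd(x),
                                        mean(y), stats::sd(y)),
               stringsAsFactors = FALSE)
  }))

  roc_fits <- lapply(biomarkers, function(bm) {
    v <- c(cohort[[paste0("nawm_", bm)]], cohort[[paste0("wmh_", bm)]])
    l <- rep(c(FALSE, TRUE), each = nrow(cohort))
    roc_discrimination(v, l)
  })
  names(roc_fits) <- biomarkers
  roc <- do.call(rbind, lapply(biomarkers, function(bm) {
    r <- roc_fits[[bm]]
    data.frame(biomarker = bm, auc = r$auc,
               ci_low = r$ci[["low"]], ci_high = r$ci[["high"]],
               threshold = r$threshold, direction = r$direction,
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, stringsAsFactors = FALSE)
  }))

  ancova_fits <- list()
  score_trend <- do.call(rbind, lapply(biomarkers, function(bm) {
    v <- cohort[[paste0("nawm_", bm)]]
    base <- ancova_trend(v, cohort$fazekas_total, cohort$age_days,
                         cohort$gender)
    full <- ancova_trend(v, cohort$fazekas_total, cohort$age_days,
                         cohort$gender, vrf = vrf_covariates(cohort))
    nf <- nested_f(base, full)
    ancova_fits[[bm]] <<- list(base = base, full = full, nested = nf)
    per_score <- do.call(rbind, lapply(sort(unique(cohort$fazekas_total)),
      function(s) {
        vs <- v[cohort$fazekas_total == s]
        data.frame(biomarker = bm, score = s, n = length(vs),
                   mean = mean(vs), sd = stats::sd(vs))
      }))
    sc <- function(a) a$terms[a$terms$term == "score", ]
    per_score$F_base <- sc(base)$F
    per_score$p_base <- sc(base)$p
    per_score$r2_base <- base$r_squared
    per_score$F_vrf <- sc(full)$F
    per_score$p_vrf <- sc(full)$p
    per_score$r2_vrf <- full$r_squared
    per_score$nested_F <- nf$F
    per_score$nested_p <- nf$p
    per_score
  }))

  male <- cohort$gender == "M"
  vrf_tab <- do.call(rbind, lapply(config$vrf_incidence$factor, function(fac) {
    flag <- cohort[[fac]]
    counts <- rbind(male = c(sum(flag & male), sum(!flag & male)),
                    female = c(sum(flag & !male), sum(!flag & !male)))
    cs <- chi_square_incidence(counts)
    data.frame(factor = fac, n = sum(flag),
               total_pct = 100 * mean(flag),
               male_pct = 100 * mean(flag[male]),
               female_pct = 100 * mean(flag[!male]),
               chisq = cs$chisq, p = cs$p, stringsAsFactors = FALSE)
  }))

  tables <- list(tissue_contrast = tissue_contrast, roc = roc,
                 score_trend = score_trend, vrf_incidence = vrf_tab)
  if (!is.null(config$out_dir)) save_results(tables, config$out_dir)
  c(tables, list(cohort = cohort, roc_fits = roc_fits,
                 ancova_fits = ancova_fits))
}

#' Replicate the two-class ROC calibration study
#'
#' For each of `n_seeds` replicate seeds, draws `n` paired (NAWM, WMH)
#' subject means of one biomarker from the configured bivariate Gaussian,
#' pools the `2n` labelled observations and runs the empirical ROC.
#' Reports the per-replicate Youden-optimal threshold, specificity,
#' sensitivity, AUC and accuracy, plus their medians.  This is the
#' calibration check for the published MD discrimination figures.
#'
#' @param biomarker Which biomarker (default `"MD"`).
#' @param table Biomarker table (the two marginals used).
#' @param n Subjects per replicate (default 676).
#' @param n_seeds Number of replicates (default 100).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `replicates` (data.frame) and `medians` (named
#'   vector: threshold, specificity, sensitivity, auc, accuracy).
#' @export
replicate_roc_study <- function(biomarker = "MD",
                                table = default_biomarker_table(),
                                n = 676, n_seeds = 100, seed = 1) {
  row <- table[table$biomarker == biomarker, ]
  if (nrow(row) != 1) stop("unknown biomarker: ", biomarker)
  one <- table[table$biomarker == biomarker, , drop = FALSE]
  attr(one, "rho") <- attr(table, "rho") %||% 0.6
  reps <- do.call(rbind, lapply(seq_len(n_seeds), function(r) {
    gs <- data.frame(score = 2, n = n)
    cohort <- make_cohort(gs, one, per_score_nawm = NULL,
                          seed = as.integer(seed) + r)
    v <- c(cohort[[paste0("nawm_", biomarker)]],
           cohort[[paste0("wmh_", biomarker)]])
    l <- rep(c(FALSE, TRUE), each = n)
    roc <- roc_discrimination(v, l)
    data.frame(seed = seed + r, threshold = roc$threshold,
               specificity = roc$specificity, sensitivity = roc$sensitivity,
               auc = roc$auc, accuracy = roc$accuracy)
  }))
  list(replicates = reps,
       medians = vapply(reps[, -1], stats::median, numeric(1)))
}

#' Run the volumetric study
#'
#' The full imaging path at small n: per subject, generate a label
#' phantom at a Fazekas score drawn from the configured group proportions,
#' synthesize structural contrasts and parametric maps (subject-level
#' tissue means drawn from the cohort model, voxel noise on top), segment
#' by colour fusion and quantization, refine masks, build distance shells
#' around the segmented WMH and average every biomarker per mask and per
#' shell.  Dice agreement between recovered and ground-truth masks
#' (processed with the same CSF-dilation refinement) is logged per
#' subject; subjects whose segmented WMH is below `min_wmh_voxels` skip
#' the shell stage and are counted.
#'
#' @param config A `pipeline_config`.
#' @param n_subjects Number of phantom subjects (default 5; `>= 2`).
#' @return List with `summaries` (per subject/tissue/biomarker means),
#'   `shells` (per subject/shell/biomarker means), `dice` (per subject
#'   WMH/NAWM Dice), `cohort` (subject records), `n_shell_skipped`, and
#'   `stats` (paired t and Cohen d per biomarker when enough subjects).
#' @export
run_volumetric_study <- function(config = pipeline_config(), n_subjects = 5) {
  stopifnot(inherits(config, "pipeline_config"))
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  seed <- as.integer(config$seed)
  bt <- config$biomarker_table
  attr(bt, "rho") <- config$rho

  # subject scores drawn from the configured group proportions
  probs <- config$group_sizes$n / sum(config$group_sizes$n)
  scores <- with_seed_if(seed, {
    config$group_sizes$score[sample.int(nrow(config$group_sizes), n_subjects,
                                        replace = TRUE, prob = probs)]
  })
  gs <- as.data.frame(table(factor(scores, levels = config$group_sizes$score)))
  gs <- data.frame(score = config$group_sizes$score, n = gs$Freq,
                   n_male = round(gs$Freq * config$group_sizes$n_male /
                                    pmax(config$group_sizes$n, 1)))
  cohort <- make_cohort(gs, bt, config$score_nawm, seed = seed + 1L)

  pen <- if (config$penumbra_alpha > 0)
    penumbra_config(config$penumbra_alpha, config$penumbra_lambda) else NULL
  contrasts <- default_contrast_table(config$contrast_noise_sd)
  biomarkers <- bt$biomarker

  summaries <- list(); shells_tab <- list(); dice_tab <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    sseed <- seed + 100L * i
    labels <- make_label_phantom(config$shape, config$voxel_dims,
                                 target_score = rec$fazekas_total,
                                 seed = sseed)
    structural <- synthesize_structural(labels, contrasts, seed = sseed + 1L)
    # subject-level tissue means come from the cohort draw, so the
    # volumetric and summary paths share the between-subject model
    sub_bt <- bt
    for (k in seq_len(nrow(sub_bt))) {
      bm <- sub_bt$biomarker[k]
      sub_bt$mean_nawm[k] <- rec[[paste0("nawm_", bm)]]
      sub_bt$mean_wmh[k] <- rec[[paste0("wmh_", bm)]]
    }
    maps <- synthesize_parametric(labels, sub_bt, penumbra = pen,
                                  noise_scale = config$parametric_noise_scale,
                                  seed = sseed + 2L)
    brain <- tissue_mask(labels, "brain")
    truth_stroke <- tissue_mask(labels, "stroke")
    seg <- suppressWarnings(
      segment_subject(structural, brain, config$n_levels,
                      stroke = truth_stroke))

    truth_ref <- refine_masks(tissue_mask(labels, "nawm"),
                              tissue_mask(labels, "wmh"),
                              tissue_mask(labels, "csf"))
    dice_tab[[i]] <- data.frame(
      id = rec$id, score = rec$fazekas_total,
      dice_nawm = dice(seg$nawm, truth_ref$nawm),
      dice_wmh = if (any(truth_ref$wmh$data != 0) || any(seg$wmh$data != 0))
        dice(seg$wmh, truth_ref$wmh) else NA_real_,
      stringsAsFactors = FALSE)

    for (bm in biomarkers) {
      for (tis in c("nawm", "wmh")) {
        msk <- seg[[tis]]
        if (!any(msk$data != 0)) next
        mm <- masked_mean(maps[[bm]], msk)
        summaries[[length(summaries) + 1L]] <- data.frame(
          id = rec$id, score = rec$fazekas_total, tissue = tis,
          biomarker = bm, value = mm$mean, n_voxels = mm$n_voxels,
          stringsAsFactors = FALSE)
      }
    }

    if (sum(seg$wmh$data != 0) >= config$min_wmh_voxels) {
      sh <- build_shells(seg$wmh, seg$nawm,
                         max_mm = config$shell_max_mm,
                         step_mm = config$shell_step_mm)
      for (bm in biomarkers) {
        sm <- shell_means(sh, maps[[bm]])
        sm$id <- rec$id; sm$score <- rec$fazekas_total; sm$biomarker <- bm
        shells_tab[[length(shells_tab) + 1L]] <- sm
      }
    } else {
      n_skipped <- n_skipped + 1L
    }
  }

  summaries <- do.call(rbind, summaries)
  shells_tab <- if (length(shells_tab)) do.call(rbind, shells_tab) else NULL
  dice_tab <- do.call(rbind, dice_tab)

  stats_tab <- NULL
  wide <- stats::reshape(summaries[, c("id", "tissue", "biomarker", "value")],
                         direction = "wide",
                         idvar = c("id", "biomarker"), timevar = "tissue")
  ok <- stats::complete.cases(wide)
  if (sum(ok) >= 3) {
    stats_tab <- do.call(rbind, lapply(biomarkers, function(bm) {
      sub <- wide[ok & wide$biomarker == bm, ]
      if (nrow(sub) < 3) return(NULL)
      tt <- paired_t(sub$value.nawm, sub$value.wmh)
      data.frame(biomarker = bm, n = nrow(sub), t = tt$t, p = tt$p,
                 cohen_d = cohen_d_pooled(mean(sub$value.nawm),
                                          stats::sd(sub$value.nawm),
                                          mean(sub$value.wmh),
                                          stats::sd(sub$value.wmh)),
                 stringsAsFactors = FALSE)
    }))
  }

  out <- list(summaries = summaries, shells = shells_tab, dice = dice_tab,
              cohort = cohort, n_shell_skipped = n_skipped,
              stats = stats_tab)
  if (!is.null(config$out_dir)) {
    keep <- Filter(Negate(is.null),
                   list(volumetric_summaries = summaries,
                        volumetric_shells = shells_tab,
                        volumetric_dice = dice_tab))
    save_results(keep, config$out_dir)
  }
  out
}
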