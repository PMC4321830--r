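# Statistical surface: per-mask aggregation, paired comparisons with
# pooled-SD effect sizes, empirical ROC discrimination with DeLong
# confidence intervals, Fazekas-trend ANCOVA with Type II sums of squares,
# nested model F tests, Pearson chi-squared incidence tests, and robust
# outlier flagging.

#' Mean of a parametric map over a mask
#'
#' @param map A `volume_grid`.
#' @param mask A binary `volume_grid` on the same lattice.
#' @return A list with `mean` and `n_voxels`.  An empty mask is a defined
#'   error (the subject is excluded from that comparison).
#' @export
masked_mean <- function(map, mask) {
  assert_same_grid(map, mask)
  sel <- mask_which(mask)
  n <- sum(sel)
  if (n == 0L) stop("empty-mask error: no voxels to average")
  list(mean = mean(map$data[sel]), n_voxels = n)
}

#' Paired t test
#'
#' Classic paired t on the differences `x - y`, two-sided p.
#'
#' @param x,y Paired numeric vectors, equal length `>= 3`, no missing
#'   values.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("degenerate input: zero variance of differences")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = mean(d))
}

#' Pooled-SD Cohen's d
#'
#' `d = (mean_x - mean_y) / sqrt((sd_x^2 + sd_y^2) / 2)`.  By the
#' package's sign convention the first argument is the NAWM summary, so
#' biomarkers elevated in WMH (MD, T1) give negative d.
#'
#' @param mean_x,sd_x First group (NAWM) mean and SD.
#' @param mean_y,sd_y Second group (WMH) mean and SD.
#' @return Cohen's d.
#' @export
cohen_d_pooled <- function(mean_x, sd_x, mean_y, sd_y) {
  if (sd_x < 0 || sd_y < 0) stop("SDs must be >= 0")
  if (sd_x == 0 && sd_y == 0) stop("both SDs are zero")
  (mean_x - mean_y) / sqrt((sd_x^2 + sd_y^2) / 2)
}

# DeLong variance of the empirical AUC (positives x, negatives y)
delong_var <- function(x, y) {
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  m <- length(x); n <- length(y)
  v10 <- vapply(x, function(a) mean(psi(a, y)), numeric(1))
  v01 <- vapply(y, function(b) mean(psi(x, b)), numeric(1))
  stats::var(v10) / m + stats::var(v01) / n
}

#' ROC discrimination between two classes
#'
#' Empirical ROC over candidate thresholds at midpoints of consecutive
#' sorted unique pooled values.  AUC by the trapezoid rule, which equals
#' the Mann-Whitney rank-sum statistic (concordant pairs plus half ties).
#' The 95% CI uses DeLong's method.  The optimal threshold maximises
#' Youden's J (sensitivity + specificity - 1), ties broken toward the
#' lower threshold; accuracy is the correctly classified fraction at that
#' threshold.  The direction (`">"` when the positive class takes higher
#' values) is inferred from the data.
#'
#' @param values Numeric observations (both classes pooled).
#' @param labels Logical/0-1 vector; TRUE/1 is the positive class (WMH).
#' @param level Confidence level for the AUC CI (default 0.95).
#' @return An object of class `roc_result`: `auc`, `ci` (low, high,
#'   level), `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `direction`, `n_pos`, `n_neg`, and the ROC `curve` (fpr, tpr).
#' @export
roc_discrimination <- function(values, labels, level = 0.95) {
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stop("missing values not allowed")
  pos <- values[labels]; neg <- values[!labels]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg))
  auc_raw <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  s <- if (auc_raw >= 0.5) 1 else -1
  w <- s * values
  wp <- w[labels]; wn <- w[!labels]
  auc <- if (s == 1) auc_raw else 1 - auc_raw

  u <- sort(unique(w))
  cand <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else u
  sens <- vapply(cand, function(t) mean(wp > t), numeric(1))
  spec <- vapply(cand, function(t) mean(wn <= t), numeric(1))
  j <- sens + spec - 1
  k <- if (s == 1) which.max(j) else length(j) + 1L - which.max(rev(j))
  thr <- s * cand[k]
  acc <- (sens[k] * m + spec[k] * n) / (m + n)

  se <- sqrt(delong_var(wp, wn))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(low = max(0, auc - z * se), high = min(1, auc + z * se))

  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  structure(list(auc = auc, ci = c(ci, level = level), threshold = thr,
                 sensitivity = sens[k], specificity = spec[k],
                 accuracy = acc, direction = if (s == 1) ">" else "<",
                 n_pos = m, n_neg = n,
                 curve = data.frame(fpr = rev(fpr), tpr = rev(tpr))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (%d%% CI %.3f-%.3f); threshold %s %.4g; sens %.3f spec %.3f acc %.3f\n",
    x$auc, round(100 * x$ci[["level"]]), x$ci[["low"]], x$ci[["high"]],
    x$direction, x$threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Univariate logistic regression by IRLS
#'
#' Maximum-likelihood fit of `logit P(y = 1) = a + b x` by iteratively
#' reweighted least squares; convergence when the log-likelihood change is
#' below 1e-8 or after 100 iterations.  Complete separation is reported
#' explicitly (deviance collapsing to zero) rather than silently returning
#' divergent coefficients; the finite-threshold ROC remains valid there.
#'
#' @param values Numeric predictor (must not be constant).
#' @param labels Logical/0-1 response; both classes present.
#' @return List with `intercept`, `slope`, `slope_se`, `deviance`,
#'   `separated`, `converged`, `iterations`.
#' @export
logistic_univariate <- function(values, labels) {
  y <- as.numeric(as.logical(labels))
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  if (stats::sd(values) == 0) stop("predictor is constant")
  X <- cbind(1, values)
  beta <- c(stats::qlogis(mean(y)), 0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(100L)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    if (abs(ll - ll_old) < 1e-8) { converged <- TRUE; break }
    ll_old <- ll
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  p <- stats::plogis(eta)
  deviance <- -2 * sum(y * log(pmax(p, 1e-300)) +
                         (1 - y) * log(pmax(1 - p, 1e-300)))
  separated <- deviance < 1e-4
  w <- pmax(p * (1 - p), 1e-10)
  vcv <- tryCatch(solve(t(X * w) %*% X), error = function(e) matrix(NA, 2, 2))
  list(intercept = beta[1], slope = beta[2], slope_se = sqrt(vcv[2, 2]),
       deviance = deviance, separated = separated, converged = converged,
       iterations = it)
}

#' ANCOVA of a biomarker across Fazekas score groups
#'
#' Linear model with the total Fazekas score as a categorical factor and
#' optional age, gender and vascular-risk-factor covariates.  Per-term F
#' statistics use Type II sums of squares (each term adjusted for all
#' others; with no interactions this is the `drop1` F).  Empty score
#' groups are dropped with a warning rather than crashing (the score-0
#' group is tiny in realistic cohorts).
#'
#' @param outcome Per-subject biomarker values.
#' @param score Total Fazekas scores (coerced to factor).
#' @param age,gender Optional covariates.
#' @param vrf Optional data.frame of additional covariates (one column per
#'   risk factor).
#' @return An object of class `ancova_result`: `terms` (data.frame with
#'   `term`, `df`, `sumsq`, `F`, `p`), `r_squared`, `df_residual`, and the
#'   underlying `fit`.
#' @export
ancova_trend <- function(outcome, score, age = NULL, gender = NULL,
                         vrf = NULL) {
  dat <- data.frame(outcome = outcome,
                    score = if (is.factor(score)) score else factor(score))
  declared <- levels(dat$score)
  dat$score <- droplevels(dat$score)
  if (length(levels(dat$score)) < length(declared))
    warning("dropping empty score group(s): ",
            paste(setdiff(declared, levels(dat$score)), collapse = ", "))
  if (nlevels(dat$score) < 2) stop("need at least 2 non-empty score groups")
  covars <- character(0)
  # constant categorical covariates carry no information and would break
  # the model matrix; they are silently dropped so the model reduces to
  # the plain ANOVA in the all-constant case
  usable <- function(x) {
    if (is.factor(x) || is.character(x) || is.logical(x))
      length(unique(x)) >= 2 else TRUE
  }
  if (!is.null(age)) { dat$age <- age; covars <- c(covars, "age") }
  if (!is.null(gender) && usable(gender)) {
    dat$gender <- factor(gender); covars <- c(covars, "gender")
  }
  if (!is.null(vrf)) {
    vrf <- as.data.frame(vrf)
    for (nm in names(vrf)) {
      if (!usable(vrf[[nm]])) next
      dat[[nm]] <- vrf[[nm]]
      covars <- c(covars, nm)
    }
  }
  fml <- stats::reformulate(c("score", covars), response = "outcome")
  fit <- stats::lm(fml, data = dat)
  dr <- stats::drop1(fit, test = "F")
  terms_tab <- data.frame(term = rownames(dr)[-1],
                          df = dr$Df[-1],
                          sumsq = dr$`Sum of Sq`[-1],
                          F = dr$`F value`[-1],
                          p = dr$`Pr(>F)`[-1],
                          stringsAsFactors = FALSE)
  structure(list(terms = terms_tab,
                 r_squared = summary(fit)$r.squared,
                 df_residual = fit$df.residual,
                 fit = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA (Type II): R^2 %.3f, residual df %d\n",
              x$r_squared, x$df_residual))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Nested model F test
#'
#' `F = ((RSS_small - RSS_big) / d_df) / (RSS_big / df_big)` comparing two
#' nested linear models on the same observations (e.g. the Fazekas ANCOVA
#' with and without the vascular-risk-factor block).  Adding only aliased
#' (duplicated) columns gives F = 0.
#'
#' @param model_small,model_big `lm` fits or `ancova_result`s; the small
#'   model's terms must be a subset of the big model's.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
nested_f <- function(model_small, model_big) {
  get_fit <- function(m) if (inherits(m, "ancova_result")) m$fit else m
  small <- get_fit(model_small); big <- get_fit(model_big)
  if (stats::nobs(small) != stats::nobs(big))
    stop("models must be fit to the same observations")
  ts <- attr(stats::terms(small), "term.labels")
  tb <- attr(stats::terms(big), "term.labels")
  if (!all(ts %in% tb)) stop("models are not nested")
  rss_s <- sum(stats::residuals(small)^2)
  rss_b <- sum(stats::residuals(big)^2)
  df1 <- small$df.residual - big$df.residual
  df2 <- big$df.residual
  if (df1 == 0) {
    if (rss_s - rss_b > 1e-8 * max(rss_s, 1)) stop("models are not nested")
    return(list(F = 0, df1 = 0, df2 = df2, p = 1))
  }
  F <- ((rss_s - rss_b) / df1) / (rss_b / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2,
                                                  lower.tail = FALSE))
}

#' Pearson chi-squared test on a 2 x k incidence table
#'
#' No continuity correction; `df = (rows - 1)(cols - 1)`.
#'
#' @param counts Numeric matrix of counts (2 rows, e.g. gender, by k
#'   outcome columns).
#' @return List with `chisq`, `df`, `p`, `expected`.
#' @export
chi_square_incidence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in incidence table")
  E <- outer(rs, cs) / sum(counts)
  chisq <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE), expected = E)
}

#' Flag outlying subject summaries
#'
#' Robust z-scores (median / scaled MAD) per biomarker; values with
#' `|z| > z_cut` are flagged for review rather than auto-dropped,
#' replacing the visual inspection step with a logged, reproducible flag.
#' If the MAD is zero the SD-based z-score is used with a warning.
#'
#' @param summaries Data frame with columns `biomarker` and `value` (other
#'   columns such as subject ids pass through).
#' @param z_cut Flagging threshold (default 3.5).
#' @return `summaries` with added `robust_z` and `flagged` columns.
#' @export
flag_outliers <- function(summaries, z_cut = 3.5) {
  stopifnot(all(c("biomarker", "value") %in% names(summaries)))
  summaries$robust_z <- NA_real_
  for (bm in unique(summaries$biomarker)) {
    sel <- summaries$biomarker == bm
    v <- summaries$value[sel]
    if (length(v) < 10)
      stop("need at least 10 subjects per biomarker (", bm, ")")
    md <- stats::median(v)
    sc <- stats::mad(v)
    if (sc == 0) {
      warning("MAD is zero for ", bm, "; falling back to SD-based z")
      sc <- stats::sd(v)
    }
    summaries$robust_z[sel] <- if (sc == 0) 0 else (v - md) / sc
  }
  summaries$flagged <- abs(summaries$robust_z) > z_cut
  summaries
}
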