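test_that("masked mean", {
  v <- volume_grid(array(c(1, 3), dim = c(2, 1, 1)), c(1, 1, 1))
  full <- binary_mask(array(TRUE, dim = c(2, 1, 1)), c(1, 1, 1))
  expect_equal(masked_mean(v, full)$mean, 2.0)
  const <- volume_grid(array(7, dim = c(2, 1, 1)), c(1, 1, 1))
  half <- binary_mask(array(c(TRUE, FALSE), dim = c(2, 1, 1)), c(1, 1, 1))
  expect_equal(masked_mean(const, half)$mean, 7)
  empty <- binary_mask(array(FALSE, dim = c(2, 1, 1)), c(1, 1, 1))
  expect_error(masked_mean(v, empty), "empty-mask")
})

test_that("paired t test", {
  out <- paired_t(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * pt(-out$t, 2), tolerance = 1e-12)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(paired_t(1:5, 1:4), "paired")
})

test_that("pooled-SD Cohen's d matches the published effect sizes", {
  tab <- default_biomarker_table()
  d <- mapply(cohen_d_pooled, tab$mean_nawm, tab$sd_nawm,
              tab$mean_wmh, tab$sd_wmh)
  expect_equal(unname(d), c(1.13, -2.85, 1.91, -0.80), tolerance = 0.02 / 1.13)
  expect_equal(cohen_d_pooled(5, 1, 5, 2), 0)
  expect_error(cohen_d_pooled(1, 0, 2, 0), "zero")
})

test_that("ROC discrimination: exact cases and the pair-counting oracle", {
  r <- roc_discrimination(c(0.6, 0.7, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$threshold, 0.75)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$direction, ">")

  same <- roc_discrimination(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(same$auc, 0.5)

  set.seed(19)
  for (rep in 1:25) {
    m <- sample(3:12, 1); n <- sample(3:12, 1)
    pos <- sample(0:6, m, replace = TRUE)   # heavy ties on purpose
    neg <- sample(0:6, n, replace = TRUE)
    r <- roc_discrimination(c(pos, neg), rep(c(1, 0), c(m, n)))
    oracle <- auc_paircount(pos, neg)
    expect_equal(r$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
  }

  # reversed direction: class low
  lo <- roc_discrimination(c(5, 6, 1, 2), c(0, 0, 1, 1))
  expect_equal(lo$direction, "<")
  expect_equal(lo$auc, 1)
  expect_error(roc_discrimination(1:3, c(1, 1, 1)), "both classes")
})

test_that("DeLong CI contains the AUC and covers near nominal rate", {
  set.seed(23)
  truth <- pnorm(1 / sqrt(2))   # AUC of N(0,1) vs N(1,1)
  cover <- 0L
  for (rep in 1:400) {
    x <- rnorm(40); y <- rnorm(40, 1)
    r <- roc_discrimination(c(x, y), rep(c(0, 1), each = 40))
    expect_true(r$ci[["low"]] <= r$auc && r$auc <= r$ci[["high"]])
    if (r$ci[["low"]] <= truth && truth <= r$ci[["high"]]) cover <- cover + 1L
  }
  # binomial(400, .95) within a wide 3-sigma band plus small-sample slack
  expect_gt(cover / 400, 0.90)
})

test_that("univariate logistic regression by IRLS", {
  set.seed(29)
  n <- 4000
  x <- rep(c(-1, 1), n / 2)
  p <- plogis(qlogis(0.75) * x)
  y <- runif(n) < p
  fit <- logistic_univariate(x, y)
  expect_true(fit$converged)
  expect_false(fit$separated)
  expect_lt(abs(fit$slope - qlogis(0.75)), 3 * fit$slope_se)

  ynull <- sample(y)
  fit0 <- logistic_univariate(x, ynull)
  expect_lt(abs(fit0$slope), 3 * fit0$slope_se)

  sep <- logistic_univariate(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separated)
  expect_error(logistic_univariate(rep(1, 6), c(0, 0, 0, 1, 1, 1)), "constant")
})

test_that("ANCOVA: hand-computed F, ANOVA reduction, empty groups, null", {
  out <- ancova_trend(c(1, 2, 3, 3, 4, 5), c(0, 0, 0, 1, 1, 1))
  sc <- out$terms[out$terms$term == "score", ]
  expect_equal(sc$F, 6.0, tolerance = 1e-12)
  expect_equal(sc$df, 1)

  # constant covariates reduce exactly to one-way ANOVA
  y <- c(1.2, 0.8, 2.5, 2.9, 3.1, 1.7, 2.2, 2.4)
  g <- c(0, 0, 1, 1, 2, 2, 0, 1)
  a1 <- ancova_trend(y, g, age = rep(5, 8), gender = rep("M", 8))
  f_oneway <- anova(lm(y ~ factor(g)))$`F value`[1]
  expect_equal(a1$terms$F[a1$terms$term == "score"], f_oneway,
               tolerance = 1e-10)

  expect_warning(
    ancova_trend(rnorm(20), factor(rep(c(0, 2), 10), levels = 0:6)),
    "empty score group")

  # null outcome: F near 1 on average
  set.seed(31)
  fs <- replicate(60, {
    y <- rnorm(140)
    g <- rep(0:6, each = 20)
    a <- ancova_trend(y, g, age = runif(140), gender = rep(c("M", "F"), 70))
    a$terms$F[a$terms$term == "score"]
  })
  expect_gt(median(fs), 0.5)
  expect_lt(median(fs), 1.6)
})

test_that("nested F test", {
  set.seed(37)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n); y <- 1 + x1 + rnorm(n)
  small <- lm(y ~ x1)
  big <- lm(y ~ x1 + x2)
  out <- nested_f(small, big)
  rss_s <- sum(residuals(small)^2); rss_b <- sum(residuals(big)^2)
  expect_equal(out$F, ((rss_s - rss_b) / 1) / (rss_b / (n - 3)),
               tolerance = 1e-12)
  expect_equal(out$df1, 1); expect_equal(out$df2, n - 3)

  dup <- lm(y ~ x1 + I(x1 * 1))   # aliased duplicate column
  expect_equal(nested_f(small, dup)$F, 0)
  expect_error(nested_f(big, lm(y ~ x2)), "not nested")

  # null VRF block: F statistic follows F(df1, df2)
  set.seed(41)
  fstats <- replicate(300, {
    x <- rnorm(60); yy <- x + rnorm(60)
    z <- matrix(rnorm(180), 60)
    nested_f(lm(yy ~ x), lm(yy ~ x + z))$F
  })
  expect_gt(ks.test(fstats, pf, df1 = 3, df2 = 55)$p.value, 0.01)
})

test_that("chi-squared incidence test", {
  out <- chi_square_incidence(rbind(c(10, 20), c(20, 10)))
  expect_equal(out$chisq, 20 / 3, tolerance = 1e-12)
  expect_equal(out$df, 1)

  prop <- rbind(c(10, 30), c(20, 60))   # proportional margins
  expect_equal(chi_square_incidence(prop)$chisq, 0, tolerance = 1e-12)

  # ex-smoker counts reconstructed from the published gender rates
  male <- round(0.508 * 358); female <- round(0.387 * 318)
  tab <- rbind(c(male, 358 - male), c(female, 318 - female))
  expect_lt(chi_square_incidence(tab)$p, 0.01)
  expect_error(chi_square_incidence(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("robust outlier flagging", {
  base <- data.frame(biomarker = "MD", value = rep(c(0.69, 0.7, 0.71), 5))
  expect_warning(out <- flag_outliers(rbind(
    data.frame(biomarker = "FA", value = rep(0.3, 12)), base)), "MAD")
  expect_false(any(out$flagged[out$biomarker == "FA"]))

  set.seed(43)
  vals <- rnorm(50, 0.7, 0.03)
  vals[7] <- 0.7 + 10 * mad(vals)
  fl <- flag_outliers(data.frame(biomarker = "MD", value = vals))
  expect_equal(which(fl$flagged), 7)

  # contaminated simulation: ~5% shifted by 6 SD get flagged
  set.seed(47)
  n <- 2000
  v <- rnorm(n)
  bad <- sample(n, 100)
  v[bad] <- v[bad] + 6
  fl2 <- flag_outliers(data.frame(biomarker = "T1", value = v))
  frac <- mean(fl2$flagged)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.005)
  expect_error(flag_outliers(data.frame(biomarker = "X", value = 1:5)),
               "at least 10")
})
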