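test_that("label phantom honours the score contract", {
  lab0 <- make_label_phantom(SMALL_SHAPE, target_score = 0, seed = 1)
  expect_equal(sum(lab0$data == label_codes()[["wmh"]]), 0)

  counts <- vapply(0:6, function(s) {
    sum(make_label_phantom(SMALL_SHAPE, target_score = s, seed = 1)$data ==
          label_codes()[["wmh"]])
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[7], counts[2])   # score 6 strictly above score 1

  # determinism and WMH/CSF disjointness
  a <- make_label_phantom(SMALL_SHAPE, target_score = 4, seed = 9)
  b <- make_label_phantom(SMALL_SHAPE, target_score = 4, seed = 9)
  expect_identical(a$data, b$data)
  expect_equal(sum(a$data == label_codes()[["wmh"]] &
                     a$data == label_codes()[["csf"]]), 0)

  expect_error(make_label_phantom(c(20, 20, 20), target_score = 1, seed = 1),
               "sizing error")
})

test_that("structural synthesis is the label map in the zero-noise limit", {
  lab <- make_label_phantom(SMALL_SHAPE, target_score = 2, seed = 3)
  st <- synthesize_structural(lab, default_contrast_table(0), seed = 1)
  tab <- default_contrast_table(0)
  for (mod in names(st)) {
    sub <- tab[tab$modality == mod, ]
    for (tis in sub$tissue) {
      sel <- lab$data == label_codes()[[tis]]
      if (!any(sel)) next
      expect_true(all(st[[mod]]$data[sel] == sub$mean[sub$tissue == tis]))
    }
  }
  # determinism with noise
  s1 <- synthesize_structural(lab, default_contrast_table(8), seed = 5)
  s2 <- synthesize_structural(lab, default_contrast_table(8), seed = 5)
  expect_identical(s1$FLAIR$data, s2$FLAIR$data)
  # missing (tissue, modality) entry
  broken <- default_contrast_table(0)
  broken <- broken[!(broken$tissue == "wmh" & broken$modality == "FLAIR"), ]
  expect_error(synthesize_structural(lab, broken), "configuration error")
})

test_that("parametric maps match the biomarker table and penumbra formula", {
  lab <- make_label_phantom(SMALL_SHAPE, target_score = 2, seed = 3)
  maps <- synthesize_parametric(lab, noise_scale = 0)
  nawm <- lab$data == label_codes()[["nawm"]]
  expect_true(all(maps$MD$data[nawm] == 0.692))
  expect_true(all(maps$FA$data[nawm] == 0.338))

  # alpha = 0 is the no-penumbra limit
  m0 <- synthesize_parametric(lab, penumbra = penumbra_config(0, 4),
                              noise_scale = 0)
  expect_identical(m0$MD$data, maps$MD$data)

  # penumbra shift equals direct evaluation of the formula at brute-force
  # distances (single central WMH voxel, zero noise)
  blk <- single_wmh_block(9)
  pen <- penumbra_config(alpha = 1, lambda = 50)
  mp <- synthesize_parametric(blk, penumbra = pen, noise_scale = 0)
  d <- bf_distance(blk$data == label_codes()[["wmh"]], blk$voxel_dims)
  tab <- default_biomarker_table()
  md <- tab[tab$biomarker == "MD", ]
  expected <- md$mean_nawm + 1 * exp(-d / 50) * (md$mean_wmh - md$mean_nawm)
  sel <- blk$data == label_codes()[["nawm"]]
  expect_equal(mp$MD$data[sel], expected[sel], tolerance = 1e-12)
  # lesion-adjacent voxels approach the WMH mean as lambda grows
  adjacent <- sel & d <= 2 + 1e-9
  expect_lt(max(abs(mp$MD$data[adjacent] - md$mean_wmh)), 0.03)

  expect_error(penumbra_config(0.3, -1), "lambda")
})

test_that("cohort generator reproduces its design", {
  cohort <- make_cohort(seed = 1)
  expect_equal(nrow(cohort), 676)
  expect_true(all(cohort$fazekas_total ==
                    cohort$fazekas_pv + cohort$fazekas_deep))
  expect_true(all(cohort$fazekas_total %in% 0:6))

  only2 <- make_cohort(data.frame(score = 0:6,
                                  n = c(0, 0, 50, 0, 0, 0, 0)), seed = 2)
  expect_true(all(only2$fazekas_total == 2))

  # parameter recovery: large score-2 group recovers the table-row FA mean
  big <- make_cohort(data.frame(score = 2, n = 20000), seed = 3)
  se <- 0.023 / sqrt(20000)
  expect_lt(abs(mean(big$nawm_FA) - 0.342), 3 * se)

  # pooled calibration: default cohort recovers the population MD values
  se_md <- 0.034 / sqrt(676)
  expect_lt(abs(mean(cohort$nawm_MD) - 0.692), 3 * se_md + 0.001)
  expect_lt(abs(mean(cohort$wmh_MD) - 0.833), 3 * 0.061 / sqrt(676))

  expect_error(make_cohort(data.frame(score = 1, n = -5)), "validation")
  expect_identical(make_cohort(seed = 7), make_cohort(seed = 7))
})

test_that("VRF assignment follows the incidence table", {
  cohort <- make_cohort(data.frame(score = 2, n = 8000), seed = 4)
  zero <- default_vrf_incidence()
  zero$male_pct <- zero$female_pct <- 0
  none <- assign_vrf(cohort, zero, seed = 1)
  expect_true(all(!none$hypertension) && all(none$smoking == "never"))

  vrf <- assign_vrf(cohort, seed = 5)
  male <- vrf$gender == "M"
  se <- sqrt(0.508 * 0.492 / sum(male))
  expect_lt(abs(mean(vrf$hypertension[male]) - 0.508), 3 * se)
  # smoker categories are mutually exclusive
  expect_true(all(!(vrf$current_smoker & vrf$ex_smoker)))
  expect_identical(assign_vrf(cohort, seed = 6), assign_vrf(cohort, seed = 6))

  bad <- default_vrf_incidence(); bad$male_pct[1] <- 120
  expect_error(assign_vrf(cohort, bad), "validation")
})
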