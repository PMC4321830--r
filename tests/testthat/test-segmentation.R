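test_that("channel normalisation clips at the 1st/99th percentiles", {
  dims <- c(101, 1, 1)
  v <- volume_grid(array(0:100, dim = dims), c(1, 1, 1))
  mask <- binary_mask(array(TRUE, dim = dims), c(1, 1, 1))
  out <- normalize_channel(v, mask)
  # direct percentile oracle
  p <- quantile(0:100, c(0.01, 0.99), names = FALSE)
  oracle <- pmin(pmax(0:100, p[1]), p[2])
  oracle <- (oracle - p[1]) / (p[2] - p[1]) * 255
  expect_equal(as.vector(out$data), oracle, tolerance = 1e-12)
  expect_equal(min(out$data), 0)
  expect_equal(max(out$data), 255)

  const <- volume_grid(array(7, dim = dims), c(1, 1, 1))
  expect_true(all(normalize_channel(const, mask)$data == 0))
  expect_error(normalize_channel(v, binary_mask(array(FALSE, dim = dims),
                                                c(1, 1, 1))), "empty")
})

test_that("red-green fusion stacks channels and rejects mismatched grids", {
  a <- volume_grid(array(255, dim = c(2, 2, 2)), c(1, 1, 1))
  b <- volume_grid(array(0, dim = c(2, 2, 2)), c(1, 1, 1))
  f <- fuse_red_green(a, b)
  expect_true(all(f$red$data == 255) && all(f$green$data == 0))
  g <- fuse_red_green(b, a)
  expect_identical(f$red$data, g$green$data)
  expect_identical(f$green$data, g$red$data)
  c3 <- volume_grid(array(0, dim = c(3, 2, 2)), c(1, 1, 1))
  expect_error(fuse_red_green(a, c3), "alignment")
})

quantize_points <- function(r, g, k) {
  n <- length(r)
  red <- volume_grid(array(r, dim = c(n, 1, 1)), c(1, 1, 1))
  green <- volume_grid(array(g, dim = c(n, 1, 1)), c(1, 1, 1))
  mask <- binary_mask(array(TRUE, dim = c(n, 1, 1)), c(1, 1, 1))
  minimum_variance_quantize(fuse_red_green(red, green), mask, k)
}

test_that("minimum-variance quantizer splits greedily and deterministically", {
  q <- quantize_points(c(0, 1, 8, 9), c(0, 0, 0, 0), 2)
  expect_equal(nrow(q$clusters), 2)
  expect_equal(sum(q$clusters$sse), 1.0)
  expect_setequal(q$clusters$red, c(0.5, 8.5))
  # membership: {0,1} together, {8,9} together
  expect_equal(q$assignment[1], q$assignment[2])
  expect_equal(q$assignment[3], q$assignment[4])
  expect_false(q$assignment[1] == q$assignment[3])

  same <- quantize_points(rep(3, 10), rep(4, 10), 8)
  expect_equal(nrow(same$clusters), 1)
  expect_equal(same$clusters$sse, 0)

  # total SSE is non-increasing in the number of levels
  set.seed(42)
  r <- sample(0:40, 60, replace = TRUE); g <- sample(0:40, 60, replace = TRUE)
  sses <- vapply(2:8, function(k) sum(quantize_points(r, g, k)$clusters$sse),
                 numeric(1))
  expect_true(all(diff(sses) <= 1e-9))
})

test_that("greedy quantizer is within 10% of the exhaustive optimum", {
  set.seed(11)
  for (rep in 1:15) {
    m <- sample(4:12, 1)
    r <- sample(0:15, m, replace = TRUE)
    g <- sample(0:15, m, replace = TRUE)
    for (k in 2:3) {
      greedy <- sum(quantize_points(r, g, k)$clusters$sse)
      opt <- opt_guillotine_sse(r, g, k)
      expect_lte(greedy, opt * 1.1 + 1e-9)
    }
  }
})

test_that("tissue selection recovers ground truth on a zero-noise phantom", {
  # extreme two-cluster case
  q <- quantize_points(c(250, 250, 10), c(10, 10, 250), 2)
  m <- select_tissue_clusters(q, "nawm", "T1W+T2W")
  expect_equal(as.vector(m$data), c(1, 1, 0))

  lab <- make_label_phantom(SMALL_SHAPE, target_score = 3, seed = 7,
                            stroke = TRUE)
  st <- synthesize_structural(lab, default_contrast_table(0), seed = 1)
  brain <- tissue_mask(lab, "brain")
  nc <- function(v) normalize_channel(v, brain)
  q1 <- minimum_variance_quantize(fuse_red_green(nc(st$T1W), nc(st$T2W)),
                                  brain, 16)
  q2 <- minimum_variance_quantize(fuse_red_green(nc(st$T2starW), nc(st$FLAIR)),
                                  brain, 16)
  nawm <- select_tissue_clusters(q1, "nawm", "T1W+T2W")
  csf <- select_tissue_clusters(q1, "csf", "T1W+T2W")
  wmh <- exclude_stroke(select_tissue_clusters(q2, "wmh", "T2starW+FLAIR"),
                        tissue_mask(lab, "stroke"))
  expect_equal(dice(nawm, tissue_mask(lab, "nawm")), 1)
  expect_equal(dice(csf, tissue_mask(lab, "csf")), 1)
  expect_equal(dice(wmh, tissue_mask(lab, "wmh")), 1)
})

test_that("noisy segmentation recovers WMH with high Dice and lesion-free
           subjects yield an empty mask", {
  lab <- make_label_phantom(SMALL_SHAPE, target_score = 3, seed = 21)
  st <- synthesize_structural(lab, default_contrast_table(8), seed = 22)
  seg <- segment_subject(st, tissue_mask(lab, "brain"), 16)
  truth <- refine_masks(tissue_mask(lab, "nawm"), tissue_mask(lab, "wmh"),
                        tissue_mask(lab, "csf"))
  expect_gte(dice(seg$wmh, truth$wmh), 0.90)
  expect_gte(dice(seg$nawm, truth$nawm), 0.90)

  lab0 <- make_label_phantom(SMALL_SHAPE, target_score = 0, seed = 23)
  st0 <- synthesize_structural(lab0, default_contrast_table(8), seed = 24)
  expect_warning(
    seg0 <- segment_subject(st0, tissue_mask(lab0, "brain"), 16),
    "empty mask")
  expect_equal(sum(seg0$wmh$data), 0)
})

test_that("mask refinement removes a 1-voxel CSF dilation", {
  dims <- c(7, 7, 7)
  vox <- c(2, 2, 2)
  ones <- binary_mask(array(TRUE, dim = dims), vox)
  csf <- array(FALSE, dim = dims); csf[4, 4, 4] <- TRUE
  ref <- refine_masks(ones, ones, binary_mask(csf, vox))
  expect_equal(sum(ones$data) - sum(ref$nawm$data), 27)

  empty_csf <- binary_mask(array(FALSE, dim = dims), vox)
  ref2 <- refine_masks(ones, ones, empty_csf)
  expect_identical(ref2$nawm$data, ones$data)

  # phantom property: no refined voxel is within one voxel of CSF
  lab <- make_label_phantom(SMALL_SHAPE, target_score = 2, seed = 5)
  tr <- refine_masks(tissue_mask(lab, "nawm"), tissue_mask(lab, "wmh"),
                     tissue_mask(lab, "csf"))
  csf_idx <- which(lab$data == label_codes()[["csf"]], arr.ind = TRUE)
  kept <- which(tr$nawm$data != 0, arr.ind = TRUE)
  # exhaustive neighbourhood scan on a subsample for speed
  set.seed(1)
  for (i in sample(nrow(kept), 200)) {
    cheb <- apply(abs(sweep(csf_idx, 2, kept[i, ])), 1, max)
    expect_gt(min(cheb), 1)
  }
})

test_that("stroke exclusion is exact set difference", {
  dims <- c(5, 5, 5)
  set.seed(3)
  for (rep in 1:5) {
    a <- array(runif(125) < 0.3, dim = dims)
    s <- array(runif(125) < 0.2, dim = dims)
    out <- exclude_stroke(binary_mask(a, c(1, 1, 1)),
                          binary_mask(s, c(1, 1, 1)))
    expect_identical(out$data != 0, a & !s)
  }
  m <- binary_mask(array(runif(125) < 0.3, dim = dims), c(1, 1, 1))
  none <- binary_mask(array(FALSE, dim = dims), c(1, 1, 1))
  expect_identical(exclude_stroke(m, none)$data, m$data)
  expect_equal(sum(exclude_stroke(m, m)$data), 0)
})
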