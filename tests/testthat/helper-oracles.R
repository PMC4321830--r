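# Independent oracles used to freeze expected values: brute-force distance
# computation, exhaustive guillotine-partition quantization, and pair-count
# AUC.  These deliberately share no code with the implementation paths they
# check.

# all-pairs Euclidean distance (mm) from every voxel to the nearest mask
# voxel; O(N * M), usable only on tiny grids
bf_distance <- function(mask_arr, voxel_dims) {
  idx <- which(mask_arr != 0, arr.ind = TRUE)
  dm <- dim(mask_arr)
  co <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                              z = seq_len(dm[3])))
  d <- apply(co, 1, function(p) {
    min(sqrt(((p[1] - idx[, 1]) * voxel_dims[1])^2 +
               ((p[2] - idx[, 2]) * voxel_dims[2])^2 +
               ((p[3] - idx[, 3]) * voxel_dims[3])^2))
  })
  array(d, dim = dm)
}

# weighted SSE of a point set about its centroid, both channels
sse_points <- function(r, g) {
  f <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  f(r) + f(g)
}

# exhaustive minimum over all recursive axis-aligned (guillotine) splits of
# the colour points into at most k boxes
opt_guillotine_sse <- function(r, g, k) {
  rec <- function(ir, ig, k) {
    base <- sse_points(ir, ig)
    if (k <= 1 || length(ir) <= 1) return(base)
    best <- base
    for (ch in 1:2) {
      v <- if (ch == 1) ir else ig
      for (t in sort(unique(v))[-length(unique(v))]) {
        L <- v <= t
        for (k1 in seq_len(k - 1)) {
          cand <- rec(ir[L], ig[L], k1) + rec(ir[!L], ig[!L], k - k1)
          if (cand < best) best <- cand
        }
      }
    }
    best
  }
  rec(r, g, k)
}

# Mann-Whitney pair-count AUC: concordant pairs plus half ties
auc_paircount <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# a small uniform-NAWM block with one central WMH voxel, handy for exact
# distance/shell/penumbra checks
single_wmh_block <- function(n = 9, voxel_dims = c(2, 2, 2)) {
  arr <- array(label_codes()[["nawm"]], dim = rep(n, 3))
  ctr <- (n + 1) / 2
  arr[ctr, ctr, ctr] <- label_codes()[["wmh"]]
  label_volume(arr, voxel_dims)
}

# small phantom grid used in imaging tests (just big enough for the
# ventricles plus the 12 mm shell margin)
SMALL_SHAPE <- c(48, 48, 48)
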