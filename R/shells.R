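# Distance-shell (lesion penumbra) ROIs: disjoint NAWM bands at nominal
# 2 mm increments around WMH, plus the remaining NAWM, and fixed-location
# spherical control ROIs.

#' Build disjoint NAWM shells around WMH
#'
#' The WMH mask is (conceptually) dilated to `step_mm, 2*step_mm, ...,
#' max_mm` and each dilation has the previous one subtracted, so only the
#' surrounding contours remain; every shell is then intersected with the
#' NAWM mask.  Realised with a single Euclidean distance transform:
#' `shell_k` is the set of NAWM voxels at distance in `(k - step, k]` mm
#' from the nearest WMH voxel.  Nominal distances are approximate: they
#' are quantised by the finite voxel size.
#'
#' @param wmh Non-empty binary WMH mask (subjects without lesions are a
#'   defined error; callers skip the shell analysis for them).
#' @param nawm Binary NAWM mask on the same lattice.
#' @param max_mm Outermost nominal distance (default 10 mm).
#' @param step_mm Shell increment (default 2 mm).
#' @return An object of class `shell_set`: named list `shells`
#'   (`shell_2`, ..., each a binary `volume_grid`), `remaining_nawm`,
#'   `voxel_dims`, `step_mm`, `max_mm`.  Shells are pairwise disjoint,
#'   disjoint from WMH, and together with `remaining_nawm` partition the
#'   NAWM mask exactly.
#' @export
build_shells <- function(wmh, nawm, max_mm = 10, step_mm = 2) {
  assert_same_grid(wmh, nawm)
  if (!any(wmh$data != 0))
    stop("empty WMH mask: subject has no lesions; skip shell analysis")
  if (step_mm <= 0 || max_mm < step_mm) stop("bad shell spacing")
  d <- distance_transform(wmh)$data
  in_nawm <- mask_which(nawm)
  edges <- seq(step_mm, max_mm, by = step_mm)
  tol <- 1e-9
  shells <- lapply(seq_along(edges), function(i) {
    lo <- if (i == 1) 0 else edges[i - 1]
    binary_mask(in_nawm & d > lo + tol & d <= edges[i] + tol,
                wmh$voxel_dims)
  })
  names(shells) <- paste0("shell_", edges)
  remaining <- binary_mask(in_nawm & d > max_mm + tol, wmh$voxel_dims)
  # voxels of NAWM that coincide with WMH (should not exist for disjoint
  # masks) fall in no shell because d = 0 there
  structure(list(shells = shells, remaining_nawm = remaining,
                 voxel_dims = wmh$voxel_dims,
                 step_mm = step_mm, max_mm = max_mm),
            class = "shell_set")
}

#' Mean biomarker value per shell
#'
#' @param shell_set A `shell_set`.
#' @param map A `volume_grid` parametric map on the same lattice.
#' @return A data.frame with columns `roi`, `mean`, `n_voxels`; ROIs are
#'   the shells in order, then `remaining_nawm`.  Empty ROIs get `NA`.
#' @export
shell_means <- function(shell_set, map) {
  stopifnot(inherits(shell_set, "shell_set"))
  rois <- c(shell_set$shells, list(remaining_nawm = shell_set$remaining_nawm))
  out <- lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    n <- sum(m$data != 0)
    data.frame(roi = nm, mean = if (n) mean(map$data[m$data != 0]) else NA_real_,
               n_voxels = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample fixed-location spherical ROIs
#'
#' Means of a map within spheres of radius `radius_mm` centred at given
#' voxel coordinates, the same coordinates for every participant.  A
#' sphere containing no in-grid (and, if given, in-mask) voxel yields NA.
#'
#' @param map A `volume_grid`.
#' @param centers Integer matrix (n x 3) of 1-based voxel coordinates.
#' @param radius_mm Sphere radius in mm.  A radius smaller than the voxel
#'   size reduces the ROI to the centre voxel.
#' @param mask Optional binary `volume_grid`; voxels outside it are
#'   excluded from the spheres.
#' @return Numeric vector of ROI means (NA where empty).
#' @export
sample_fixed_rois <- function(map, centers, radius_mm, mask = NULL) {
  stopifnot(inherits(map, "volume_grid"))
  centers <- matrix(as.integer(centers), ncol = 3)
  dm <- dim(map$data)
  if (any(centers < 1L) || any(t(centers) > dm))
    stop("ROI centers must lie inside the grid")
  w <- map$voxel_dims
  rad_vox <- pmax(0L, as.integer(floor(radius_mm / w)))
  ok <- if (is.null(mask)) NULL else mask_which(mask)
  apply(centers, 1, function(ctr) {
    xs <- max(1L, ctr[1] - rad_vox[1]):min(dm[1], ctr[1] + rad_vox[1])
    ys <- max(1L, ctr[2] - rad_vox[2]):min(dm[2], ctr[2] + rad_vox[2])
    zs <- max(1L, ctr[3] - rad_vox[3]):min(dm[3], ctr[3] + rad_vox[3])
    gg <- expand.grid(x = xs, y = ys, z = zs)
    d2 <- ((gg$x - ctr[1]) * w[1])^2 + ((gg$y - ctr[2]) * w[2])^2 +
      ((gg$z - ctr[3]) * w[3])^2
    keep <- d2 <= radius_mm^2 + 1e-9
    keep[d2 == 0] <- TRUE                    # centre voxel always included
    gg <- gg[keep, , drop = FALSE]
    if (!is.null(ok)) {
      inmask <- ok[cbind(gg$x, gg$y, gg$z)]
      gg <- gg[inmask, , drop = FALSE]
    }
    if (!nrow(gg)) return(NA_real_)
    mean(map$data[cbind(gg$x, gg$y, gg$z)])
  })
}
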