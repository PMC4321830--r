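# Voxel-lattice containers shared by the phantom generator, segmentation and
# shell analysis.  A volume is a plain 3-D array plus physical voxel
# dimensions in mm; masks are volumes whose data are strictly 0/1.

#' Tissue label codes
#'
#' Integer codes used in ground-truth label volumes: background 0, CSF 1,
#' NAWM 2, WMH 3, stroke 4.
#'
#' @return Named integer vector of the five label codes.
#' @export
label_codes <- function() {
  c(background = 0L, csf = 1L, nawm = 2L, wmh = 3L, stroke = 4L)
}

#' Construct a volume grid
#'
#' A scalar 3-D volume on a regular voxel lattice with physical voxel
#' dimensions.  This is the common currency of the package: structural
#' contrasts, parametric maps, label volumes and binary masks are all
#' `volume_grid` objects.
#'
#' @param data Numeric (or logical/integer) 3-D array of voxel values; all
#'   values must be finite.
#' @param voxel_dims Numeric length-3 vector `(dx, dy, dz)` of voxel edge
#'   lengths in mm; all strictly positive.  Default 2 mm isotropic.
#' @return An object of class `volume_grid` with elements `data` and
#'   `voxel_dims`.
#' @export
volume_grid <- function(data, voxel_dims = c(2, 2, 2)) {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all shape components must be >= 1")
  if (!all(is.finite(data))) stop("volume data must be finite")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("`voxel_dims` must be three positive numbers (mm)")
  structure(list(data = data, voxel_dims = voxel_dims),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm; range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_dims), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary mask volume
#'
#' @param data Logical or 0/1 numeric 3-D array.
#' @param voxel_dims Voxel dimensions in mm.
#' @return A `volume_grid` whose data are 0/1.
#' @export
binary_mask <- function(data, voxel_dims = c(2, 2, 2)) {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  v <- volume_grid(data, voxel_dims)
  if (!all(v$data %in% c(0, 1)))
    stop("mask data must be binary (0/1)")
  v
}

#' Construct a label volume
#'
#' @param data Integer 3-D array with values in `label_codes()`.
#' @param voxel_dims Voxel dimensions in mm.
#' @return A `volume_grid` of class `c("label_volume", "volume_grid")`.
#' @export
label_volume <- function(data, voxel_dims = c(2, 2, 2)) {
  v <- volume_grid(data, voxel_dims)
  if (!all(v$data %in% label_codes()))
    stop("label values must be in {0,1,2,3,4}")
  class(v) <- c("label_volume", class(v))
  v
}

#' Extract a tissue mask from a label volume
#'
#' @param labels A `label_volume`.
#' @param tissue One of `"csf"`, `"nawm"`, `"wmh"`, `"stroke"`,
#'   `"background"`, or `"brain"` (any non-background label).
#' @return A binary `volume_grid`.
#' @export
tissue_mask <- function(labels, tissue) {
  stopifnot(inherits(labels, "volume_grid"))
  d <- if (identical(tissue, "brain")) {
    labels$data != 0
  } else {
    code <- label_codes()[[match.arg(tissue, names(label_codes()))]]
    labels$data == code
  }
  binary_mask(d, labels$voxel_dims)
}

# internal: TRUE where mask is set
mask_which <- function(mask) mask$data != 0

#' Check that two volumes share a voxel lattice
#'
#' @param a,b `volume_grid` objects.
#' @param tol Relative tolerance on voxel dimensions.
#' @return TRUE invisibly; stops with an alignment error otherwise.
#' @export
assert_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("alignment error: volume shapes differ (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
  if (any(abs(a$voxel_dims - b$voxel_dims) >
          tol * pmax(a$voxel_dims, b$voxel_dims)))
    stop("alignment error: voxel dimensions differ")
  invisible(TRUE)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary `volume_grid` masks on the same lattice.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_same_grid(a, b)
  na <- sum(a$data != 0); nb <- sum(b$data != 0)
  if (na + nb == 0) return(1)
  2 * sum(a$data != 0 & b$data != 0) / (na + nb)
}

# internal set algebra on masks (same grid assumed checked by callers)
mask_and <- function(a, b)
  binary_mask(a$data != 0 & b$data != 0, a$voxel_dims)
mask_or <- function(a, b)
  binary_mask(a$data != 0 | b$data != 0, a$voxel_dims)
mask_minus <- function(a, b)
  binary_mask(a$data != 0 & b$data == 0, a$voxel_dims)
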