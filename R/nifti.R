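# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader is available in the supported dependency set, so the
# format is handled directly.  Scope is deliberately narrow and matches the
# package's phantom volumes: 3-D single-frame images, datatypes uint8,
# int16, int32, float32 and float64, pixdim used for voxel dimensions only
# (no oblique affine handling), optional scl_slope/scl_inter applied on
# read.  This is sufficient for volumes the package itself writes and for
# plain axial volumes written by common tools.

NIFTI_HDR_SIZE <- 348L

nifti_dtype_table <- function() {
  data.frame(code = c(2L, 4L, 8L, 16L, 64L),
             what = c("integer", "integer", "integer", "double", "double"),
             size = c(1L, 2L, 4L, 4L, 8L),
             signed = c(FALSE, TRUE, TRUE, TRUE, TRUE))
}

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes a single-file NIfTI-1 image (`.nii`, or gzip-compressed when the
#' path ends in `.nii.gz`).  Voxel dimensions are stored in `pixdim` and a
#' diagonal sform is recorded.  Data are written as float32 unless
#' `datatype = "uint8"` is requested (used for label volumes and masks).
#'
#' @param vol A `volume_grid`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"` (default), `"float64"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "float64", "uint8")) {
  stopifnot(inherits(vol, "volume_grid"))
  datatype <- match.arg(datatype)
  code <- switch(datatype, uint8 = 2L, float32 = 16L, float64 = 64L)
  size <- switch(datatype, uint8 = 1L, float32 = 4L, float64 = 8L)
  if (datatype == "uint8" &&
      (any(vol$data < 0) || any(vol$data > 255) ||
       any(vol$data != round(vol$data))))
    stop("uint8 datatype requires integer data in [0, 255]")

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  d <- dim(vol$data)
  w_i32(NIFTI_HDR_SIZE)                 # sizeof_hdr
  w_raw(36L)                            # data_type..dim_info (unused)
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))       # dim[8]
  w_f32(c(0, 0, 0))                     # intent_p1..p3
  w_i16(0L)                             # intent_code
  w_i16(code)                           # datatype
  w_i16(8L * size)                      # bitpix
  w_i16(0L)                             # slice_start
  w_f32(c(1, vol$voxel_dims, 1, 1, 1, 1))  # pixdim[8]
  w_f32(352)                            # vox_offset
  w_f32(1); w_f32(0)                    # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                  # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                      # glmax, glmin
  w_raw(80L + 24L)                      # descrip, aux_file
  w_i16(0L); w_i16(1L)                  # qform_code, sform_code
  w_f32(rep(0, 6))                      # quatern_b/c/d, qoffset_x/y/z
  w_f32(c(vol$voxel_dims[1], 0, 0, 0))  # srow_x
  w_f32(c(0, vol$voxel_dims[2], 0, 0))  # srow_y
  w_f32(c(0, 0, vol$voxel_dims[3], 0))  # srow_z
  w_raw(16L)                            # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w_raw(1L)  # magic
  w_raw(4L)                             # extension flag
  if (datatype == "uint8") {
    writeBin(as.integer(vol$data), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(vol$data), con, size = size, endian = "little")
  }
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads a single-file 3-D NIfTI-1 image.  `scl_slope`/`scl_inter` are
#' applied when set; both byte orders are handled.  Only `pixdim` is used
#' for geometry (no oblique affines), which is sufficient for the
#' co-registered phantom volumes this package deals in.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_grid`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE) stop("not a NIfTI-1 file (short header): ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != NIFTI_HDR_SIZE) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != NIFTI_HDR_SIZE) stop("not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[5:8][seq_len(max(0, ndim - 3))] > 1L))
    if (ndim != 3L && !(ndim >= 3L && all(dims[(ndim + 1):8] <= 1 | is.na(dims[(ndim + 1):8]))))
      stop("only 3-D volumes are supported")
  shape <- dims[2:4]
  dtype <- rd(70L, "integer", 1L, 2L)
  tab <- nifti_dtype_table()
  row <- tab[tab$code == dtype, ]
  if (nrow(row) != 1L) stop("unsupported NIfTI datatype code: ", dtype)
  pixdim <- rd(76L, "double", 8L, 4L)
  voxel_dims <- abs(pixdim[2:4])
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  data <- readBin(con, row$what, n = n_vox, size = row$size,
                  signed = row$signed, endian = endian)
  if (length(data) != n_vox) stop("truncated NIfTI data in ", path)
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  volume_grid(array(data, dim = shape), voxel_dims)
}
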