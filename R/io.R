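# Subject-level file handling: NIfTI volume bundles that must share a
# voxel lattice (the artifact models the post-registration state and
# refuses misaligned inputs rather than registering), and CSV result
# tables with a lossless NA round-trip convention (NA written as an empty
# field).

#' Load a subject bundle from NIfTI files
#'
#' Reads structural volumes, parametric maps and optional binary masks,
#' validating that every volume shares the same shape and voxel
#' dimensions.  Mismatched grids are an alignment error: the package does
#' not register, it refuses.
#'
#' @param structural Named character vector/list of NIfTI paths (e.g.
#'   `T1W`, `T2W`, `FLAIR`, `T2starW`).
#' @param parametric Named paths for parametric maps (e.g. `FA`, `MD`).
#' @param masks Named paths for binary masks (e.g. `csf`, `nawm`, `wmh`,
#'   `stroke`, `brain`); non-binary data is a validation error.
#' @param record Optional one-row data.frame with the subject's cohort
#'   record.
#' @return An object of class `subject_bundle` with elements `structural`,
#'   `parametric`, `masks`, `record`, `voxel_dims`.
#' @export
load_bundle <- function(structural = NULL, parametric = NULL, masks = NULL,
                        record = NULL) {
  read_set <- function(paths) {
    if (is.null(paths) || !length(paths)) return(list())
    out <- lapply(paths, read_nifti)
    names(out) <- names(paths)
    out
  }
  s <- read_set(structural); p <- read_set(parametric); m <- read_set(masks)
  vols <- c(s, p, m)
  if (!length(vols)) stop("no volumes given")
  ref <- vols[[1]]
  for (v in vols[-1]) assert_same_grid(ref, v)
  for (nm in names(m)) {
    if (!all(m[[nm]]$data %in% c(0, 1)))
      stop("validation error: mask '", nm, "' is not binary")
    m[[nm]] <- binary_mask(m[[nm]]$data, m[[nm]]$voxel_dims)
  }
  structure(list(structural = s, parametric = p, masks = m, record = record,
                 voxel_dims = ref$voxel_dims),
            class = "subject_bundle")
}

#' Write a phantom subject's volumes to NIfTI files
#'
#' One file per structural modality and parametric map plus the
#' ground-truth label volume, named `<id>_<name>.nii.gz`.
#'
#' @param out_dir Output directory (created if needed).
#' @param id Subject identifier used as the filename prefix.
#' @param labels Optional `label_volume` (written as uint8).
#' @param structural,parametric Optional named lists of `volume_grid`s.
#' @return Named character vector of written paths, invisibly.
#' @export
write_subject_volumes <- function(out_dir, id, labels = NULL,
                                  structural = NULL, parametric = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(vol, name, datatype = "float32") {
    p <- file.path(out_dir, paste0(id, "_", name, ".nii.gz"))
    write_nifti(vol, p, datatype = datatype)
    paths[[name]] <<- p
  }
  if (!is.null(labels)) wr(labels, "labels", "uint8")
  for (nm in names(structural)) wr(structural[[nm]], nm)
  for (nm in names(parametric)) wr(parametric[[nm]], nm)
  invisible(paths)
}

#' Save result tables as CSV
#'
#' Writes each table to `<out_dir>/<name>.csv` with a header row; NA cells
#' are written as empty fields and read back as missing, so the save/load
#' round trip is the identity on values up to float64 representation.
#'
#' @param tables Non-empty named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
save_results <- function(tables, out_dir) {
  if (!is.list(tables) || !length(tables) || is.null(names(tables)) ||
      any(names(tables) == ""))
    stop("`tables` must be a non-empty named list of data.frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Read a result table written by [save_results()]
#'
#' @param path CSV path.
#' @return A data.frame; empty fields become NA.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
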