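#' Gather per-timepoint NIfTI volumes into a longitudinal array
#'
#' Reads one volume per subject per timepoint and flattens voxels (optionally
#' restricted to a mask) into the subjects x voxels x timepoints array used
#' by [fit_voxel_slopes()].
#'
#' @param files character matrix of NIfTI paths, subjects in rows and
#'   timepoints in columns.
#' @param times follow-up times (months), one per column of `files`.
#' @param mask optional logical array (or NIfTI path) selecting voxels; all
#'   voxels are used when absent.
#' @return List with `values` (N x Q x T array), `times`, `voxel_index`
#'   (positions of the retained voxels in the volume) and `dim` (volume
#'   dimensions).
#' @export
read_longitudinal_nifti <- function(files, times, mask = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("Reading NIfTI volumes requires the RNifti package.")
  }
  files <- as.matrix(files)
  if (ncol(files) != length(times)) {
    stop("`files` must have one column per timepoint.")
  }
  first <- RNifti::readNifti(files[1, 1])
  vol_dim <- dim(first)
  if (is.character(mask)) mask <- RNifti::readNifti(mask) > 0
  keep <- if (is.null(mask)) seq_len(prod(vol_dim)) else which(as.logical(mask))
  n <- nrow(files)
  values <- array(NA_real_, c(n, length(keep), length(times)))
  for (i in seq_len(n)) {
    for (t in seq_along(times)) {
      vol <- RNifti::readNifti(files[i, t])
      if (!identical(dim(vol), vol_dim)) {
        stop("Volume ", files[i, t], " has dimensions ",
             paste(dim(vol), collapse = "x"), "; expected ",
             paste(vol_dim, collapse = "x"), ".")
      }
      values[i, , t] <- as.numeric(vol)[keep]
    }
  }
  list(values = values, times = times, voxel_index = keep, dim = vol_dim)
}

#' Write a voxel-selection mask as a NIfTI volume
#'
#' Places the selection mask of an [ancova_screen()] result back into volume
#' space (1 for selected voxels, 0 elsewhere).
#'
#' @param selection a `voxel_selection` object.
#' @param voxel_index voxel positions in the volume, as returned by
#'   [read_longitudinal_nifti()].
#' @param dim volume dimensions.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_selection_nifti <- function(selection, voxel_index, dim, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("Writing NIfTI volumes requires the RNifti package.")
  }
  stopifnot(inherits(selection, "voxel_selection"))
  vol <- array(0, dim)
  vol[voxel_index[selection$mask]] <- 1
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
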