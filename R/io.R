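#' Read and write volumes and label maps as NIfTI
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) is the one on-disk format: volumes are stored
#' with a floating-point dtype, label maps with an unsigned integer dtype.
#' Voxel spacing travels in the header `pixdim`. Round-trips are exact for the
#' stored dtype.
#'
#' @param path path to a single-channel 3D NIfTI file.
#' @param id identifier for the returned volume; defaults to the file name.
#' @return `read_volume()` a [volume()]; `read_labels()` a [labelmap()].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(volume(array(1:8 / 8, c(2, 2, 2))), f)
#' v <- read_volume(f)
#' @export
read_volume <- function(path, id = NULL) {
  img <- read_nifti3(path)
  vox_assert(all(is.finite(img$data)),
             sprintf("'%s' contains non-finite voxels", path),
             "voxseg_error_nonfinite")
  volume(img$data, spacing = img$spacing,
         id = if (is.null(id)) basename(path) else id)
}

#' @rdname read_volume
#' @param vol a [volume()].
#' @export
write_volume <- function(vol, path) {
  vox_assert(inherits(vol, "vox_volume"), "vol must be a vox_volume",
             "voxseg_error_bad_type")
  write_nifti3(vol$voxels, vol$spacing, path, datatype = "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  img <- read_nifti3(path)
  vox_assert(all(is.finite(img$data)) && all(img$data == round(img$data)),
             sprintf("'%s' does not hold an integer label grid", path),
             "voxseg_error_noninteger_label")
  vox_assert(min(img$data) >= 0, "negative labels on disk",
             "voxseg_error_invalid_label")
  labelmap(array(as.integer(round(img$data)), dim(img$data)))
}

#' @rdname read_volume
#' @param lm a [labelmap()]; labels must be non-negative integers.
#' @param spacing spacing to record in the header when writing labels.
#' @export
write_labels <- function(lm, path, spacing = c(1, 1, 1)) {
  vox_assert(inherits(lm, "vox_labelmap"), "lm must be a vox_labelmap",
             "voxseg_error_bad_type")
  vox_assert(min(lm$labels) >= 0, "labels must be non-negative integers",
             "voxseg_error_invalid_label")
  dt <- if (lm$num_classes <= 256) "uint8" else "uint16"
  write_nifti3(lm$labels, spacing, path, datatype = dt)
  invisible(path)
}

#' @rdname read_volume
#' @param pm a [probmap()]; stored as a 4D NIfTI (x, y, z, class).
#' @export
write_probmap <- function(pm, path, spacing = c(1, 1, 1)) {
  vox_assert(inherits(pm, "vox_probmap"), "pm must be a vox_probmap",
             "voxseg_error_bad_type")
  # NIfTI dimension order is spatial-first; classes go to the 4th axis
  arr <- aperm(pm$probs, c(2, 3, 4, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_probmap <- function(path) {
  vox_assert(file.exists(path), sprintf("file not found: '%s'", path),
             "voxseg_error_file_not_found")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  vox_assert(length(d) == 4L,
             sprintf("'%s' is not a 4D probability stack", path),
             "voxseg_error_not_4d")
  probmap(aperm(array(as.numeric(img), d), c(4, 1, 2, 3)))
}

read_nifti3 <- function(path) {
  vox_assert(is.character(path) && file.exists(path),
             sprintf("file not found: '%s'", path),
             "voxseg_error_file_not_found")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  vox_assert(length(d) == 3L,
             sprintf("'%s' is not a 3D volume (found %d dimensions)",
                     path, length(d)),
             "voxseg_error_not_3d")
  list(data = array(as.numeric(img), d),
       spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

write_nifti3 <- function(arr, spacing, path, datatype) {
  dir <- dirname(path)
  vox_assert(dir.exists(dir), sprintf("directory does not exist: '%s'", dir),
             "voxseg_error_unwritable")
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
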