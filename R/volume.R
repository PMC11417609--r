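#' Calibrated grayscale image volume
#'
#' Container for a 3D grayscale volume with isotropic voxel size and a flag
#' recording whether voxel values are calibrated volumetric bone mineral
#' density (mgHA/cm3).
#'
#' @param data 3D numeric array.
#' @param voxel_um Isotropic voxel size in micrometres.
#' @param units Unit string for voxel values.
#' @param calibrated Logical; `TRUE` when values are density-calibrated.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_um, units = "mgHA/cm3", calibrated = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("voxel_um must be a single positive number")
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 units = units, calibrated = isTRUE(calibrated)),
            class = "image_volume")
}

#' Binary (segmented) volume
#'
#' @param voxels 3D logical array (`TRUE` = phase of interest).
#' @param voxel_um Isotropic voxel size in micrometres.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, voxel_um) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("voxel_um must be a single positive number")
  structure(list(voxels = voxels, voxel_um = as.numeric(voxel_um)),
            class = "binary_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_volume %d x %d x %d, voxel %.1f um, %s%s\n",
              d[1], d[2], d[3], x$voxel_um, x$units,
              if (x$calibrated) " (calibrated)" else " (uncalibrated)"))
  cat(sprintf("  value range [%.2f, %.2f]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_volume %d x %d x %d, voxel %.1f um, %.1f%% foreground\n",
              d[1], d[2], d[3], x$voxel_um, 100 * mean(x$voxels)))
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the voxel size carried in the header
#' (converted to mm). Binary volumes are written as uint8 0/1.
#'
#' @param vol An `image_volume` or `binary_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `image_volume` (use `as_binary = TRUE` for a label mask).
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_volume")) {
    arr <- array(as.integer(vol$voxels), dim(vol$voxels))
    vox <- vol$voxel_um
  } else if (inherits(vol, "image_volume")) {
    arr <- vol$data
    vox <- vol$voxel_um
  } else stop("vol must be an image_volume or binary_volume")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vox / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param path Path to a NIfTI file.
#' @param as_binary Interpret the voxels as a 0/1 mask.
#' @param calibrated Whether grayscale values are density-calibrated.
#' @rdname write_volume
#' @export
read_volume <- function(path, as_binary = FALSE, calibrated = TRUE) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1] * 1000
  arr <- array(as.numeric(img), dim(img))
  if (as_binary) binary_volume(arr > 0.5, vox)
  else image_volume(arr, vox, calibrated = calibrated)
}
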