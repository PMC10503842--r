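#' Construct a volume series
#'
#' A `volume_series` is the package's carrier for 4D image data: a 3D voxel
#' grid stacked along a fourth (volume) axis, with voxel sizes in mm and a
#' 4x4 voxel-to-world affine.  Diffusion series, ASL control/label series,
#' M0 images, masks and fitted maps all travel in this container.  3D input
#' is promoted to a single-volume 4D array.
#'
#' @param data Numeric 3D or 4D array of signal intensities.
#' @param voxel_size Numeric length-3 vector of voxel edge lengths in mm
#'   (strictly positive).
#' @param affine 4x4 voxel-to-world transform; defaults to a scaling matrix
#'   built from `voxel_size`.
#' @return An object of class `volume_series` with elements `data` (4D
#'   array), `voxel_size`, `affine` and `n_volumes`.
#' @export
volume_series <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data), 1L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(
    list(data = data, voxel_size = voxel_size, affine = affine,
         n_volumes = dim(data)[4L]),
    class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d grid, %d volume(s), voxels %s mm\n",
              d[1], d[2], d[3], x$n_volumes,
              paste(format(x$voxel_size, digits = 3), collapse = " x ")))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

#' Read a NIfTI file as a volume series
#'
#' Reads a 3D or 4D NIfTI-1 volume (`.nii` or `.nii.gz`).  3D images are
#' promoted to a 4D series with one volume.  Voxel sizes are taken from the
#' spatial columns of the stored affine; no reorientation is performed.
#'
#' @param path Path to a readable NIfTI file.
#' @return A [volume_series].
#' @export
read_volume_series <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable volume: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd < 3L)
    stop("expected a 3D or 4D volume, got ", nd, " axes in ", path)
  if (nd > 4L)
    stop("more than 4 axes in ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  vox[vox <= 0] <- 1
  volume_series(arr, voxel_size = vox, affine = aff)
}

#' Write a volume series to NIfTI
#'
#' Data are stored as 32-bit float; the affine is written as the sform.
#'
#' @param series A [volume_series].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  dat <- series$data
  if (dim(dat)[4L] == 1L)
    dim(dat) <- dim(dat)[1:3]
  img <- RNifti::asNifti(dat, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Extract one 3D volume from a series
#'
#' @param series A [volume_series].
#' @param i Volume index (1-based).
#' @return 3D array.
#' @export
get_volume <- function(series, i) {
  stopifnot(inherits(series, "volume_series"),
            i >= 1, i <= series$n_volumes)
  series$data[, , , i, drop = TRUE]
}

#' Validate a series against its acquisition protocol
#'
#' Checks the consistency rules a decay fit relies on and returns a
#' character vector naming every violated rule (empty when fit-ready).
#' The series is never modified.
#'
#' @param series A [volume_series].
#' @param protocol An [acquisition_protocol].
#' @return Character vector of problems; `character(0)` means fit-ready.
#' @export
validate_series <- function(series, protocol) {
  stopifnot(inherits(series, "volume_series"),
            inherits(protocol, "acquisition_protocol"))
  report <- character(0)
  nb <- length(protocol$b_values)
  if (nb != series$n_volumes)
    report <- c(report, sprintf(
      "volume count mismatch: %d b-values vs %d volumes", nb,
      series$n_volumes))
  if (!any(protocol$b_values == 0))
    report <- c(report, "no b0 volume")
  if (any(protocol$b_values < 0))
    report <- c(report, "negative b-value")
  bad_dir <- protocol$b_values == 0 & protocol$direction_index != 0L
  if (any(bad_dir))
    report <- c(report, "b0 volume with nonzero direction index")
  if (any(series$data <= 0))
    report <- c(report, "nonpositive signal present")
  report
}
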