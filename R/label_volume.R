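#' Construct a label volume
#'
#' A 3D integer array of region codes with a legend mapping each code to a
#' region name.  Region masks are mutually exclusive by construction (one
#' code per voxel).  Every voxel value must appear in the legend.
#'
#' @param labels 3D integer array of region codes.
#' @param legend Named integer vector mapping region names to codes;
#'   defaults to [region_codes()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, legend = region_codes()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, legend)
  if (length(unknown))
    stop("voxel codes absent from legend: ", paste(unknown, collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  counts <- table(factor(x$labels, levels = x$legend))
  cat(sprintf("<label_volume> %d x %d x %d grid\n", d[1], d[2], d[3]))
  for (nm in names(x$legend))
    cat(sprintf("  %-20s code %d: %d voxels\n", nm, x$legend[[nm]],
                counts[[as.character(x$legend[[nm]])]]))
  invisible(x)
}

#' Logical mask for one region of a label volume
#'
#' @param atlas A [label_volume].
#' @param region Region code (integer) or region name present in the
#'   legend.
#' @return Logical 3D array.
#' @export
region_mask <- function(atlas, region) {
  stopifnot(inherits(atlas, "label_volume"))
  code <- resolve_region(atlas, region)
  atlas$labels == code
}

resolve_region <- function(atlas, region) {
  if (is.character(region)) {
    if (!region %in% names(atlas$legend))
      stop("unknown region name: ", region)
    code <- atlas$legend[[region]]
  } else {
    code <- as.integer(region)
    if (!code %in% atlas$legend)
      stop("unknown region code: ", code)
  }
  code
}

#' Read a label volume from NIfTI
#'
#' @param path Path to a NIfTI file of integer region codes.
#' @param legend Named integer vector of codes; defaults to
#'   [region_codes()].
#' @return A [label_volume].
#' @export
read_label_volume <- function(path, legend = region_codes()) {
  s <- read_volume_series(path)
  if (s$n_volumes != 1L) stop("label volume must be 3D")
  label_volume(array(as.integer(round(s$data)), dim(s$data)[1:3]), legend)
}

#' Write a label volume to NIfTI
#'
#' @param atlas A [label_volume].
#' @param path Output path.
#' @param voxel_size Voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(atlas, path, voxel_size = c(1.8, 1.8, 4)) {
  stopifnot(inherits(atlas, "label_volume"))
  write_volume_series(volume_series(atlas$labels + 0, voxel_size), path)
}
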