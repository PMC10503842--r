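#' Acquisition protocol for a diffusion or ASL series
#'
#' Carries the per-volume diffusion weighting (b-value, s/mm^2) and a
#' direction index (0 for b=0 volumes, 1..n_dirs otherwise), plus optional
#' ASL labeling parameters and the per-slice readout delay used for slice
#' timing correction.
#'
#' @param b_values Numeric vector of per-volume b-values (s/mm^2, all >= 0).
#' @param direction_index Integer vector, same length; 0 for every b=0
#'   volume.
#' @param asl_params Optional [asl_parameters].
#' @param slice_readout_time Per-slice readout delay in ms (ASL slice
#'   timing; 0 disables the correction).
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(b_values, direction_index = NULL,
                                 asl_params = NULL,
                                 slice_readout_time = 0) {
  b_values <- as.numeric(b_values)
  if (any(b_values < 0)) stop("negative b-value")
  if (is.null(direction_index))
    direction_index <- ifelse(b_values == 0, 0L, 1L)
  direction_index <- as.integer(direction_index)
  if (length(direction_index) != length(b_values))
    stop("direction_index length must match b_values")
  if (any(b_values == 0 & direction_index != 0L))
    stop("b0 volumes must have direction_index 0")
  if (slice_readout_time < 0) stop("negative slice readout time")
  structure(
    list(b_values = b_values, direction_index = direction_index,
         asl_params = asl_params, slice_readout_time = slice_readout_time),
    class = "acquisition_protocol")
}

#' ASL labeling parameters
#'
#' Parameters of the pseudo-continuous ASL labeling scheme used for
#' kinetic-model perfusion quantification.  Defaults are the constants of
#' the acquisition this pipeline targets: blood-brain partition coefficient
#' lambda = 0.9 mL/g, labeling efficiency alpha = 0.8 (dual background
#' suppression folded in), 3T blood T1 = 1624 ms, label duration 1800 ms
#' and post-label delay 2000 ms.
#'
#' @param lambda_partition Blood-brain partition coefficient (mL blood/g).
#' @param label_efficiency_alpha Labeling efficiency in (0, 1].
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms.
#' @param label_duration_tau Labeling pulse-train duration, ms.
#' @param post_label_delay Delay between end of labeling and readout, ms.
#' @return An object of class `asl_parameters`.
#' @export
asl_parameters <- function(lambda_partition = 0.9,
                           label_efficiency_alpha = 0.8,
                           t1_blood = 1624,
                           label_duration_tau = 1800,
                           post_label_delay = 2000) {
  p <- list(lambda_partition = lambda_partition,
            label_efficiency_alpha = label_efficiency_alpha,
            t1_blood = t1_blood,
            label_duration_tau = label_duration_tau,
            post_label_delay = post_label_delay)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v) && v > 0, logical(1))))
    stop("all ASL parameters must be single strictly positive numbers")
  if (label_efficiency_alpha > 1) stop("labeling efficiency alpha must be <= 1")
  structure(p, class = "asl_parameters")
}

#' Read an FSL-style bval/bvec pair as an acquisition protocol
#'
#' `bval_path` holds one whitespace-delimited row of b-values; `bvec_path`
#' holds three rows (x, y, z components).  Direction indices are assigned
#' by grouping identical unit vectors (equal within 1e-6 after
#' normalization); zero vectors map to index 0.
#'
#' @param bval_path Path to the .bval file.
#' @param bvec_path Path to the .bvec file.
#' @return An [acquisition_protocol].
#' @export
read_dwi_protocol <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(read.table(bvec_path))
  if (nrow(bvec) != 3L)
    stop("bvec file must have exactly 3 rows, found ", nrow(bvec))
  if (ncol(bvec) != length(bvals))
    stop(sprintf("bval/bvec length mismatch: %d b-values vs %d vectors",
                 length(bvals), ncol(bvec)))
  if (any(bvals < 0)) stop("negative b-value in ", bval_path)
  dir_idx <- group_directions(bvec)
  dir_idx[bvals == 0] <- 0L
  acquisition_protocol(bvals, dir_idx)
}

## Assign an integer index per column of a 3 x n gradient matrix; zero
## vectors get 0, nonzero vectors sharing a unit direction (within 1e-6,
## sign-sensitive) share an index.
group_directions <- function(bvec, tol = 1e-6) {
  n <- ncol(bvec)
  norms <- sqrt(colSums(bvec^2))
  idx <- integer(n)
  units <- matrix(0, 3, 0)
  for (j in seq_len(n)) {
    if (norms[j] < tol) next
    u <- bvec[, j] / norms[j]
    hit <- 0L
    if (ncol(units) > 0) {
      d <- sqrt(colSums((units - u)^2))
      if (any(d < tol)) hit <- which(d < tol)[1L]
    }
    if (hit == 0L) {
      units <- cbind(units, u)
      hit <- ncol(units)
    }
    idx[j] <- hit
  }
  idx
}

#' Write a protocol's b-values and directions as bval/bvec files
#'
#' Directions are emitted as canonical unit vectors per direction index
#' (sufficient for round-tripping phantom protocols, which are isotropic).
#'
#' @param protocol An [acquisition_protocol].
#' @param bval_path,bvec_path Output paths.
#' @return `bval_path`, invisibly.
#' @export
write_dwi_protocol <- function(protocol, bval_path, bvec_path) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  cat(paste(protocol$b_values, collapse = " "), "\n", file = bval_path)
  dirs <- canonical_directions(max(protocol$direction_index))
  vecs <- vapply(protocol$direction_index, function(i) {
    if (i == 0L) c(0, 0, 0) else dirs[, i]
  }, numeric(3))
  write.table(format(vecs, digits = 8), bvec_path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(bval_path)
}

## n approximately uniformly spread unit vectors (deterministic); used when
## the phantom needs nominal gradient directions.
canonical_directions <- function(n) {
  if (n == 0L) return(matrix(0, 3, 0))
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Read ASL parameters and slice timing from a YAML or JSON config
#'
#' The config carries keys `lambda_partition`, `label_efficiency_alpha`,
#' `t1_blood`, `label_duration_tau`, `post_label_delay` (ms) and optionally
#' `slice_readout_time` (ms per slice).
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return List with elements `asl_params` ([asl_parameters]) and
#'   `slice_readout_time`.
#' @export
read_asl_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("lambda_partition", "label_efficiency_alpha", "t1_blood",
            "label_duration_tau", "post_label_delay")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("ASL config missing keys: ", paste(missing, collapse = ", "))
  list(asl_params = do.call(asl_parameters, cfg[need]),
       slice_readout_time = if (is.null(cfg$slice_readout_time)) 0
                            else cfg$slice_readout_time)
}

#' Write an ASL config YAML
#'
#' @param asl_params An [asl_parameters].
#' @param slice_readout_time Per-slice readout delay, ms.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asl_config <- function(asl_params, slice_readout_time, path) {
  stopifnot(inherits(asl_params, "asl_parameters"))
  yaml::write_yaml(c(unclass(asl_params),
                     list(slice_readout_time = slice_readout_time)), path)
  invisible(path)
}
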