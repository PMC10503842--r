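## Digital phantom: a desk-scale label geometry plus forward signal models
## for the multi-b DWI and pCASL acquisitions, so the whole downstream
## pipeline can be exercised with known ground truth.

#' Ground-truth tissue parameters for the digital phantom
#'
#' One row per region: true decay rate `d_true` (mm^2/s), baseline signal
#' `s0_true` (arbitrary scanner units) and true perfusion `f_true`
#' (mL/100 g/min; nonzero only in the choroid plexus).  Defaults set each
#' region's decay rate to the healthy-cohort means of the study this
#' pipeline reproduces (ventricular CSF 0.00241, gray matter 0.00138,
#' white matter 0.00131, suprasellar cistern 0.00328 mm^2/s) and choroid
#' plexus perfusion to 31.3 mL/100 g/min.  The choroid plexus decay rate
#' has no reported value and defaults to a gray-matter-like 0.0014.
#'
#' @param d_true,s0_true,f_true Named numeric vectors keyed by region name
#'   overriding individual defaults.
#' @return A data frame of class `tissue_parameters` with columns `region`,
#'   `code`, `d_true`, `s0_true`, `f_true`.
#' @export
tissue_parameters <- function(d_true = NULL, s0_true = NULL, f_true = NULL) {
  tp <- data.frame(
    region = c("background", "white_matter", "gray_matter", "ventricle_csf",
               "choroid_plexus", "suprasellar_cistern"),
    code   = c(0L, 1L, 2L, 3L, 4L, 5L),
    d_true = c(0, 0.00131, 0.00138, 0.00241, 0.0014, 0.00328),
    s0_true = c(0, 90, 100, 250, 120, 250),
    f_true = c(0, 0, 0, 0, 31.3, 0),
    stringsAsFactors = FALSE)
  override <- function(col, vals) {
    if (is.null(vals)) return()
    bad <- setdiff(names(vals), tp$region)
    if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
    tp[[col]][match(names(vals), tp$region)] <<- vals
  }
  override("d_true", d_true)
  override("s0_true", s0_true)
  override("f_true", f_true)
  tissue <- tp$region != "background"
  if (any(tp$d_true[tissue] <= 0))
    stop("tissue decay rates must be strictly positive")
  class(tp) <- c("tissue_parameters", "data.frame")
  tp
}

## Run `expr` under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build the phantom tissue atlas
#'
#' Deterministically paints, into a `dims` grid, a gray-matter ellipsoidal
#' shell around a white-matter core, two lateral-ventricle CSF blocks each
#' containing a choroid plexus sub-block, and a small midline inferior
#' suprasellar-cistern CSF region.  The seed jitters region centers by at
#' most one voxel so that replicate phantoms differ slightly in geometry.
#'
#' @param dims Integer length-3 vector of voxel counts, each >= 16.
#' @param seed Integer seed.
#' @return A [label_volume] with every legend code present and every
#'   non-background region at least 20 voxels.
#' @export
build_tissue_atlas <- function(dims = c(64, 64, 28), seed = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 16L))
    stop("dims must be 3 integers, each >= 16")
  jit <- with_seed(seed, matrix(sample(-1:1, 12, replace = TRUE), 3, 4))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ix <- seq_len(nx); iy <- seq_len(ny); iz <- seq_len(nz)
  ell <- function(rx, ry, rz, ctr) {
    outer(outer(((ix - ctr[1]) / rx)^2, ((iy - ctr[2]) / ry)^2, `+`),
          ((iz - ctr[3]) / rz)^2, `+`) <= 1
  }
  box <- function(ctr, half) {
    ctr <- round(ctr)
    x <- abs(ix - ctr[1]) <= half[1]
    y <- abs(iy - ctr[2]) <= half[2]
    z <- abs(iz - ctr[3]) <= half[3]
    outer(outer(x, y, `&`), z, `&`)
  }
  lab <- array(0L, dims)
  head_ctr <- c(cx, cy, cz) + jit[, 1]
  lab[ell(0.45 * nx, 0.45 * ny, 0.45 * nz, head_ctr)] <- 2L  # GM shell
  lab[ell(0.33 * nx, 0.33 * ny, 0.33 * nz, head_ctr)] <- 1L  # WM core
  voff <- max(3, round(0.12 * nx))
  vhalf <- c(max(2, round(0.05 * nx)), max(2, round(0.08 * ny)),
             max(2, round(0.08 * nz)))
  for (s in c(-1, 1)) {
    vctr <- c(cx + s * voff, cy, cz) + jit[, 2 + (s + 1) / 2]
    lab[box(vctr, vhalf)] <- 3L                               # ventricle CSF
    lab[box(vctr + c(0, -1, 0), pmax(1, vhalf - 1))] <- 4L    # choroid plexus
  }
  sctr <- c(cx, cy + max(2, round(0.05 * ny)),
            max(3, round(0.2 * nz))) + jit[, 4]
  lab[box(sctr, c(1, 1, 1))] <- 5L                            # suprasellar
  atlas <- label_volume(lab)
  counts <- table(factor(lab, levels = 0:5))
  if (any(counts[-1] < 20))
    stop("dims too small to place all regions (a region has < 20 voxels)")
  atlas
}

## Per-voxel lookup of a tissue parameter column over an atlas.
param_map <- function(atlas, params, column) {
  vals <- params[[column]][match(as.vector(atlas$labels), params$code)]
  if (anyNA(vals))
    stop("region present in atlas but missing from tissue parameters")
  array(vals, dim(atlas$labels))
}

#' Simulate a multi-b diffusion-weighted series from the phantom
#'
#' The noiseless signal in a voxel of region r at b-value b is
#' `S0_true(r) * exp(-b * D_true(r))` — monoexponential decay, isotropic,
#' so all directions at one b share the same noiseless value.  With `snr`
#' set, magnitude (Rician) noise is applied:
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` and
#' `sigma = S0_true(white matter) / snr`.
#'
#' @param atlas A [label_volume] from [build_tissue_atlas()].
#' @param params A [tissue_parameters] table.
#' @param protocol An [acquisition_protocol] with at least two distinct
#'   b-values including 0.
#' @param snr Signal-to-noise ratio referenced to white-matter S0, or
#'   `NULL` for a noiseless series.
#' @param seed Integer seed (used only when `snr` is set).
#' @param voxel_size Voxel edge lengths in mm.
#' @return A [volume_series] with one volume per protocol entry.
#' @export
simulate_dwi_series <- function(atlas, params, protocol = default_dwi_protocol(),
                                snr = NULL, seed = 1,
                                voxel_size = c(1.8, 1.8, 4)) {
  stopifnot(inherits(atlas, "label_volume"),
            inherits(params, "tissue_parameters"),
            inherits(protocol, "acquisition_protocol"))
  b <- protocol$b_values
  if (length(unique(b)) < 2 || !any(b == 0))
    stop("protocol needs >= 2 distinct b-values including 0")
  d_map <- param_map(atlas, params, "d_true")
  s0_map <- param_map(atlas, params, "s0_true")
  dims <- dim(atlas$labels)
  dat <- array(0, c(dims, length(b)))
  for (k in seq_along(b))
    dat[, , , k] <- s0_map * exp(-b[k] * d_map)
  if (!is.null(snr)) {
    if (snr <= 0) stop("snr must be positive")
    sigma <- params$s0_true[params$region == "white_matter"] / snr
    dat <- with_seed(seed, {
      n1 <- array(rnorm(length(dat), 0, sigma), dim(dat))
      n2 <- array(rnorm(length(dat), 0, sigma), dim(dat))
      sqrt((dat + n1)^2 + n2^2)
    })
  }
  volume_series(dat, voxel_size)
}

#' The phantom's default multi-b diffusion protocol
#'
#' One leading b=0 volume followed by, for each of 6 diffusion directions,
#' a pseudo-randomized cycle through the seven b-values 0, 50, 100, 200,
#' 300, 700 and 1000 s/mm^2 (43 volumes in total).
#'
#' @param seed Seed for the per-direction b-value ordering.
#' @return An [acquisition_protocol] with 43 entries.
#' @export
default_dwi_protocol <- function(seed = 7) {
  shells <- c(0, 50, 100, 200, 300, 700, 1000)
  n_dirs <- 6L
  orders <- with_seed(seed,
    lapply(seq_len(n_dirs), function(i) sample(shells)))
  b <- c(0, unlist(orders))
  dir_idx <- c(0L, rep(seq_len(n_dirs), each = length(shells)))
  dir_idx[b == 0] <- 0L
  acquisition_protocol(b, dir_idx)
}

#' Simulate an interleaved ASL control/label series plus M0
#'
#' Control volumes carry the equilibrium tissue signal M0 (the region's
#' `s0_true`); label volumes are control minus the labeled-blood signal
#' `dM = forward_kinetic_signal(f_true, asl, pld_eff(slice)) * M0` in
#' perfused regions and equal to control elsewhere.  The slice-dependent
#' effective post-label delay along the third axis is baked into the
#' forward signal so that slice-delay-corrected quantification is exact.
#' With `snr` set, additive Gaussian noise with
#' `sigma = s0_true(white matter) / snr` corrupts every volume.
#'
#' @inheritParams simulate_dwi_series
#' @param asl An [asl_parameters].
#' @param n_pairs Number of control/label pairs (>= 1).
#' @param slice_readout_time Per-slice readout delay in ms.
#' @return List with elements `series` (a [volume_series] of `2 * n_pairs`
#'   volumes, control first and alternating) and `m0` (a single-volume
#'   [volume_series]).
#' @export
simulate_asl_series <- function(atlas, params, asl = asl_parameters(),
                                n_pairs = 10, snr = NULL, seed = 1,
                                slice_readout_time = 0,
                                voxel_size = c(1.8, 1.8, 4)) {
  stopifnot(inherits(atlas, "label_volume"),
            inherits(params, "tissue_parameters"),
            inherits(asl, "asl_parameters"))
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  m0_map <- param_map(atlas, params, "s0_true")
  f_map <- param_map(atlas, params, "f_true")
  dims <- dim(atlas$labels)
  scale <- vapply(seq_len(dims[3]) - 1L, function(sl)
    forward_kinetic_signal(1, asl, effective_pld(sl, asl, slice_readout_time)),
    numeric(1))
  dm <- f_map * m0_map *
    array(rep(scale, each = dims[1] * dims[2]), dims)
  dat <- array(0, c(dims, 2L * n_pairs))
  for (p in seq_len(n_pairs)) {
    dat[, , , 2L * p - 1L] <- m0_map       # control
    dat[, , , 2L * p] <- m0_map - dm       # label
  }
  if (!is.null(snr)) {
    if (snr <= 0) stop("snr must be positive")
    sigma <- params$s0_true[params$region == "white_matter"] / snr
    dat <- with_seed(seed,
      dat + array(rnorm(length(dat), 0, sigma), dim(dat)))
  }
  list(series = volume_series(dat, voxel_size),
       m0 = volume_series(m0_map, voxel_size))
}
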