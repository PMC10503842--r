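## Choroid plexus perfusion from pseudo-continuous ASL: surround
## subtraction of the interleaved control/label series, slice-delay
## correction, M0 normalization, and inversion of the single-compartment
## kinetic model in its post-bolus closed form.

CBF_FLOOR <- 10   # mL/100 g/min noise floor for quantified perfusion

#' Construct a perfusion map
#'
#' Voxelwise perfusion `cbf` (mL/100 g/min), the noise-floor mask
#' `above_floor`, and the pair-averaged normalized difference signal
#' `delta_m_mean` it was derived from.
#'
#' @param cbf,delta_m_mean Numeric 3D arrays.
#' @param above_floor Logical 3D array.
#' @return An object of class `perfusion_map`.
#' @export
perfusion_map <- function(cbf, above_floor, delta_m_mean) {
  stopifnot(length(dim(cbf)) == 3L,
            identical(dim(cbf), dim(above_floor)))
  structure(list(cbf = cbf, above_floor = above_floor,
                 delta_m_mean = delta_m_mean),
            class = "perfusion_map")
}

#' Surround subtraction of an interleaved control/label series
#'
#' Volumes alternate control, label, control, label, ... (control at even
#' 0-based indices).  Each label L_k is subtracted from the average of its
#' neighboring controls: `dM_k = (C_k + C_{k+1})/2 - L_k`; the terminal
#' label of the series uses its single preceding control.  A trailing
#' unpaired control is dropped with a warning.
#'
#' @param series A [volume_series] of interleaved control/label volumes.
#' @return A [volume_series] of difference volumes, one per pair.
#' @export
surround_subtract <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  nv <- series$n_volumes
  if (nv %% 2L == 1L) {
    warning("odd volume count: dropping trailing control")
    nv <- nv - 1L
  }
  n_pairs <- nv %/% 2L
  if (n_pairs < 1L) stop("no control/label pairs in series")
  dims <- dim(series$data)[1:3]
  out <- array(0, c(dims, n_pairs))
  for (k in seq_len(n_pairs)) {
    ctrl_prev <- series$data[, , , 2L * k - 1L]
    lab <- series$data[, , , 2L * k]
    if (2L * k + 1L <= nv) {
      ctrl_next <- series$data[, , , 2L * k + 1L]
      out[, , , k] <- (ctrl_prev + ctrl_next) / 2 - lab
    } else {
      out[, , , k] <- ctrl_prev - lab
    }
  }
  volume_series(out, series$voxel_size, series$affine)
}

#' Slice-dependent effective post-label delay
#'
#' In a 2D readout, later slices are acquired later, so their effective
#' post-label delay grows linearly:
#' `PLD_eff = post_label_delay + slice_index * slice_readout_time`.
#' Setting `slice_readout_time = 0` disables the correction.
#'
#' @param slice_index 0-based slice index (vectorized).
#' @param asl An [asl_parameters].
#' @param slice_readout_time Per-slice readout delay, ms.
#' @return Effective post-label delay in ms.
#' @export
effective_pld <- function(slice_index, asl, slice_readout_time) {
  stopifnot(inherits(asl, "asl_parameters"))
  if (slice_readout_time < 0) stop("negative slice readout time")
  if (any(slice_index < 0)) stop("slice_index must be >= 0")
  asl$post_label_delay + slice_index * slice_readout_time
}

#' Forward single-compartment kinetic signal
#'
#' Normalized label-control difference produced by perfusion `cbf` in the
#' post-bolus regime of the single-compartment kinetic model:
#' `dM/M0 = cbf * 2 * alpha * T1b * (1 - exp(-tau/T1b)) * exp(-pld/T1b) /
#' (6000 * lambda)` with T1b, tau and pld in consistent time units (ms
#' internally; the 6000 factor converts mL/g/s to mL/100 g/min).  Strictly
#' increasing and linear in `cbf`; doubles as the quantification oracle.
#'
#' @param cbf Perfusion in mL/100 g/min (vectorized).
#' @param asl An [asl_parameters].
#' @param pld_eff Effective post-label delay in ms; defaults to the
#'   nominal post-label delay.
#' @return Dimensionless dM/M0.
#' @export
forward_kinetic_signal <- function(cbf, asl, pld_eff = asl$post_label_delay) {
  stopifnot(inherits(asl, "asl_parameters"))
  t1b <- asl$t1_blood
  if (t1b <= 0) stop("nonpositive T1 of blood")
  cbf * 2 * asl$label_efficiency_alpha * (t1b / 1000) *
    (1 - exp(-asl$label_duration_tau / t1b)) * exp(-pld_eff / t1b) /
    (6000 * asl$lambda_partition)
}

#' Quantify perfusion from a difference series and M0
#'
#' Averages the difference volumes over pairs, normalizes by M0, and
#' inverts [forward_kinetic_signal()] with each voxel's slice-dependent
#' effective post-label delay (slices along the third axis, acquired
#' ascending).  The noise floor of 10 mL/100 g/min is then applied:
#' `above_floor = (cbf >= 10)`.  Voxels with M0 <= 0 are unquantifiable
#' (`cbf = NA`, below floor).
#'
#' @param dm_series A [volume_series] of difference volumes (from
#'   [surround_subtract()]).
#' @param m0 A single-volume [volume_series] (or 3D array) of equilibrium
#'   magnetization.
#' @param asl An [asl_parameters].
#' @param slice_readout_time Per-slice readout delay, ms.
#' @return A [perfusion_map].
#' @export
quantify_cbf <- function(dm_series, m0, asl = asl_parameters(),
                         slice_readout_time = 0) {
  stopifnot(inherits(dm_series, "volume_series"))
  m0_arr <- if (inherits(m0, "volume_series")) get_volume(m0, 1L) else m0
  dims <- dim(dm_series$data)[1:3]
  if (!identical(dim(m0_arr), dims)) stop("M0 grid mismatch")
  dm_mean <- apply_mean4(dm_series$data)
  quant <- m0_arr > 0
  dm_norm <- array(NA_real_, dims)
  dm_norm[quant] <- dm_mean[quant] / m0_arr[quant]
  ## per-slice inversion constant: dM/M0 per unit cbf
  k_slice <- forward_kinetic_signal(
    1, asl, effective_pld(seq_len(dims[3]) - 1L, asl, slice_readout_time))
  cbf <- dm_norm / array(rep(k_slice, each = dims[1] * dims[2]), dims)
  above <- !is.na(cbf) & cbf >= CBF_FLOOR
  perfusion_map(cbf = cbf, above_floor = above, delta_m_mean = dm_mean)
}

#' Mean perfusion within an atlas region
#'
#' Mean cbf over the above-floor voxels of one region (the noise floor is
#' applied voxelwise before averaging).
#'
#' @param map A [perfusion_map].
#' @param atlas A [label_volume] on the same grid.
#' @param region Region code or name.
#' @return List with `mean` (mL/100 g/min) and `n_voxels` used.
#' @export
summarize_perfusion <- function(map, atlas, region) {
  stopifnot(inherits(map, "perfusion_map"), inherits(atlas, "label_volume"))
  if (!identical(dim(map$cbf), dim(atlas$labels))) stop("grid mismatch")
  in_region <- region_mask(atlas, region)
  if (!any(in_region)) stop("empty region")
  sel <- in_region & map$above_floor
  if (!any(sel)) stop("no quantifiable voxels above the noise floor")
  list(mean = mean(map$cbf[sel]), n_voxels = sum(sel))
}
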