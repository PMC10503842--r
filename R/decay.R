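## Voxelwise exponential decay-rate mapping from a multi-b diffusion
## series: S(b) = S0 * exp(-b * D).  Larger D means faster signal decay
## across the b-value range, i.e. more fluid motion; in slowly flowing CSF
## this is read as a neurofluid-motion magnitude rather than pure
## molecular diffusion.

D_FLOOR <- 1e-8   # positivity floor, mm^2/s; fits at/below it are invalid

#' Construct a decay map
#'
#' Voxelwise decay-rate map with fit diagnostics: `d` (mm^2/s), `s0`
#' (signal units), `r_squared` (computed on the untransformed signal
#' scale), `n_shells_used` and `valid_mask`.  `d` is `NA` wherever the
#' voxel is invalid.
#'
#' @param d,s0,r_squared Numeric 3D arrays.
#' @param n_shells_used Integer 3D array.
#' @param valid_mask Logical 3D array.
#' @return An object of class `decay_map`.
#' @export
decay_map <- function(d, s0, r_squared, n_shells_used, valid_mask) {
  stopifnot(length(dim(d)) == 3L,
            identical(dim(d), dim(s0)),
            identical(dim(d), dim(valid_mask)))
  d[!valid_mask] <- NA_real_
  structure(list(d = d, s0 = s0, r_squared = r_squared,
                 n_shells_used = n_shells_used, valid_mask = valid_mask),
            class = "decay_map")
}

#' @export
print.decay_map <- function(x, ...) {
  dm <- dim(x$d)
  cat(sprintf("<decay_map> %d x %d x %d, %d valid voxels, median D %.3g mm^2/s\n",
              dm[1], dm[2], dm[3], sum(x$valid_mask),
              median(x$d[x$valid_mask])))
  invisible(x)
}

#' Correct bulk head motion by integer-voxel translation
#'
#' Rigidly realigns every volume to the reference (the first b=0 volume
#' when a protocol is given, otherwise the first volume) by the integer
#' translation within a +/- `max_shift` voxel window that maximizes the
#' normalized cross-correlation.  Volumes are mean-removed and shifts are
#' circular, which makes the correlation norm shift-invariant, so the
#' search is carried out on the FFT cross-correlation surface.  Ties and
#' flat correlation give a zero shift.
#'
#' @param series A [volume_series] with at least 2 volumes.
#' @param protocol Optional [acquisition_protocol] identifying the b=0
#'   reference volume.
#' @param max_shift Half-width of the search window in voxels.
#' @return List with `series` (the realigned [volume_series]) and `shifts`
#'   (an n_volumes x 3 integer matrix of applied corrective shifts).
#' @export
correct_bulk_motion <- function(series, protocol = NULL, max_shift = 3) {
  stopifnot(inherits(series, "volume_series"))
  if (series$n_volumes < 2L) stop("nothing to align: series has one volume")
  ref_idx <- 1L
  if (!is.null(protocol)) {
    z <- which(protocol$b_values == 0)
    if (length(z)) ref_idx <- z[1L]
  }
  dims <- dim(series$data)[1:3]
  ref <- get_volume(series, ref_idx)
  f_ref <- stats::fft(ref - mean(ref))
  window <- as.matrix(expand.grid(dx = -max_shift:max_shift,
                                  dy = -max_shift:max_shift,
                                  dz = -max_shift:max_shift))
  ## linear indices into the correlation array for each candidate shift
  widx <- apply(window, 1L, function(s) {
    i <- (-s) %% dims   # peak at index -s marks a volume displaced by +s
    1 + i[1] + dims[1] * (i[2] + dims[2] * i[3])
  })
  out <- series$data
  shifts <- matrix(0L, series$n_volumes, 3,
                   dimnames = list(NULL, c("dx", "dy", "dz")))
  n_vox <- prod(dims)
  for (k in seq_len(series$n_volumes)) {
    if (k == ref_idx) next
    vol <- series$data[, , , k]
    cc <- Re(stats::fft(f_ref * Conj(stats::fft(vol - mean(vol))),
                        inverse = TRUE)) / n_vox
    vals <- cc[widx]
    best <- which.max(vals)
    zero <- which(window[, 1] == 0 & window[, 2] == 0 & window[, 3] == 0)
    if (vals[best] <= vals[zero] + 1e-12 * abs(vals[zero])) best <- zero
    disp <- window[best, ]            # detected displacement of the volume
    corr <- -as.integer(disp)         # corrective shift applied
    if (any(corr != 0L))
      out[, , , k] <- circular_shift3(vol, corr)
    shifts[k, ] <- corr
  }
  list(series = volume_series(out, series$voxel_size, series$affine),
       shifts = shifts)
}

## Shift a 3D array circularly by integer s (voxels moved toward +index).
circular_shift3 <- function(x, s) {
  d <- dim(x)
  idx <- lapply(1:3, function(k) ((seq_len(d[k]) - 1L - s[k]) %% d[k]) + 1L)
  x[idx[[1]], idx[[2]], idx[[3]]]
}

#' Combine diffusion directions into per-shell volumes
#'
#' For each distinct b-value, the direction volumes are combined voxelwise
#' by their geometric mean (equivalent to averaging log-signals — a
#' trace-style isotropic decay estimate); b=0 volumes are averaged
#' arithmetically.  Output shells are sorted by ascending b.
#'
#' @param series A [volume_series].
#' @param protocol An [acquisition_protocol] describing it.
#' @return List with `series` (one volume per shell) and `b_values`
#'   (ascending shell b-values).
#' @export
combine_directions <- function(series, protocol) {
  stopifnot(inherits(series, "volume_series"),
            inherits(protocol, "acquisition_protocol"))
  if (length(protocol$b_values) != series$n_volumes)
    stop("protocol does not match series volume count")
  shells <- sort(unique(protocol$b_values))
  dims <- dim(series$data)[1:3]
  out <- array(0, c(dims, length(shells)))
  for (i in seq_along(shells)) {
    ks <- which(protocol$b_values == shells[i])
    if (!length(ks)) stop("shell with zero volumes")  # unreachable by construction
    vols <- series$data[, , , ks, drop = FALSE]
    if (shells[i] == 0) {
      out[, , , i] <- apply_mean4(vols)
    } else {
      ## geometric mean; nonpositive values poison the voxel's shell (NaN),
      ## which the fit then drops
      lv <- log(vols)
      lv[vols <= 0] <- NaN
      out[, , , i] <- exp(apply_mean4(lv))
    }
  }
  list(series = volume_series(out, series$voxel_size, series$affine),
       b_values = shells)
}

## mean over the 4th axis without apply()'s overhead
apply_mean4 <- function(x) {
  d <- dim(x)
  m <- x[, , , 1L]
  if (d[4L] > 1L) for (k in 2:d[4L]) m <- m + x[, , , k]
  m / d[4L]
}

#' Fit the exponential decay model in one voxel
#'
#' Nonlinear least squares of `S(b) = S0 * exp(-b * D)` on the
#' untransformed signal scale, initialized from ordinary least squares on
#' the log-signal.  Shells with nonpositive signal are dropped; at least 3
#' valid shells are required, and D is constrained nonnegative with fits
#' at or below the positivity floor (1e-8 mm^2/s) flagged invalid.
#'
#' @param shell_signals Numeric vector of per-shell signals.
#' @param shell_bvalues Matching b-values in s/mm^2.
#' @return List with `s0`, `d` (mm^2/s), `r_squared`, `n_shells_used` and
#'   `valid`.
#' @export
fit_decay_voxel <- function(shell_signals, shell_bvalues) {
  if (length(shell_signals) != length(shell_bvalues))
    stop("signal and b-value lengths differ")
  fit <- fit_decay_matrix(matrix(shell_signals, nrow = 1), shell_bvalues)
  list(s0 = fit$s0[1], d = fit$d[1], r_squared = fit$r_squared[1],
       n_shells_used = fit$n_shells_used[1], valid = fit$valid[1])
}

## Vectorized decay fit: rows of S are voxels, columns are shells.
## Log-linear OLS init (exact in the noiseless case) followed by damped
## Gauss-Newton refinement of the untransformed-scale least squares.
fit_decay_matrix <- function(S, b, max_iter = 25L, tol = 1e-12) {
  n_vox <- nrow(S)
  nb <- length(b)
  if (n_vox == 0L)
    return(list(s0 = numeric(0), d = numeric(0), r_squared = numeric(0),
                n_shells_used = integer(0), valid = logical(0),
                d_init = numeric(0), s0_init = numeric(0)))
  W <- is.finite(S) & S > 0
  nW <- rowSums(W)
  ok <- nW >= 3L
  Sw <- S
  Sw[!W] <- 0

  ## --- log-linear initializer (weighted by shell availability) ---
  L <- matrix(0, n_vox, nb)
  L[W] <- log(S[W])
  bM <- matrix(b, n_vox, nb, byrow = TRUE)
  sum_b <- rowSums(bM * W); sum_b2 <- rowSums(bM^2 * W)
  sum_l <- rowSums(L); sum_bl <- rowSums(bM * L)
  det <- nW * sum_b2 - sum_b^2
  det[det == 0 | !ok] <- NA
  slope <- (nW * sum_bl - sum_b * sum_l) / det
  icpt <- (sum_l - slope * sum_b) / nW
  D <- pmax(0, -slope)
  S0 <- exp(icpt)
  D[!ok] <- NA; S0[!ok] <- NA
  d_init <- D; s0_init <- S0

  ## --- damped Gauss-Newton on the signal scale ---
  sse_of <- function(S0, D) {
    Fm <- S0 * exp(-outer(D, b))
    rowSums((Sw - Fm)^2 * W)
  }
  act <- which(ok)
  if (length(act)) {
    sse <- sse_of(S0, D)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(D[act], b))
      Fm <- S0[act] * E
      R <- Sw[act, , drop = FALSE] - Fm
      Wa <- W[act, , drop = FALSE]
      J2 <- -Fm * bM[act, , drop = FALSE]      # dF/dD
      a11 <- rowSums(E * E * Wa)
      a12 <- rowSums(E * J2 * Wa)
      a22 <- rowSums(J2 * J2 * Wa)
      g1 <- rowSums(E * R * Wa)
      g2 <- rowSums(J2 * R * Wa)
      det2 <- a11 * a22 - a12^2
      det2[abs(det2) < 1e-300] <- NA
      dS0 <- (a22 * g1 - a12 * g2) / det2
      dD <- (a11 * g2 - a12 * g1) / det2
      dS0[is.na(dS0)] <- 0; dD[is.na(dD)] <- 0
      ## step halving per voxel until SSE does not increase
      step <- rep(1, length(act))
      for (h in 1:20) {
        S0n <- S0[act] + step * dS0
        Dn <- pmax(0, D[act] + step * dD)
        Fn <- S0n * exp(-outer(Dn, b))
        sse_n <- rowSums((Sw[act, , drop = FALSE] - Fn)^2 * Wa)
        worse <- sse_n > sse[act] + 1e-15
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      S0n <- S0[act] + step * dS0
      Dn <- pmax(0, D[act] + step * dD)
      Fn <- S0n * exp(-outer(Dn, b))
      sse_n <- rowSums((Sw[act, , drop = FALSE] - Fn)^2 * Wa)
      improve <- sse_n <= sse[act]
      S0[act[improve]] <- S0n[improve]
      D[act[improve]] <- Dn[improve]
      sse[act[improve]] <- sse_n[improve]
      if (max(abs(c(dS0 * step, dD * step))) < tol) break
    }
  }

  ## --- diagnostics ---
  mean_s <- rowSums(Sw) / pmax(nW, 1L)
  sst <- rowSums((Sw - mean_s)^2 * W)
  Fm <- S0 * exp(-outer(ifelse(is.na(D), 0, D), b))
  sse_fin <- rowSums((Sw - Fm)^2 * W)
  r2 <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse_fin / sst)), 1)
  r2[!ok] <- NA
  valid <- ok & is.finite(D) & D > D_FLOOR
  list(s0 = S0, d = D, r_squared = r2, n_shells_used = nW, valid = valid,
       d_init = d_init, s0_init = s0_init)
}

#' Fit a voxelwise decay-rate map
#'
#' Runs the full mapping chain: bulk-motion correction (optional),
#' direction combination into per-shell volumes, and the voxelwise
#' nonlinear exponential fit over the masked voxels.  Unmasked voxels are
#' invalid in the result.
#'
#' @param series A [volume_series] of diffusion volumes.
#' @param protocol The matching [acquisition_protocol].
#' @param mask A [label_volume] (all nonzero codes fitted) or a logical 3D
#'   array; `NULL` fits every voxel.
#' @param correct_motion Apply [correct_bulk_motion()] first.
#' @return A [decay_map].
#' @export
fit_decay_map <- function(series, protocol, mask = NULL,
                          correct_motion = TRUE) {
  stopifnot(inherits(series, "volume_series"),
            inherits(protocol, "acquisition_protocol"))
  problems <- validate_series(series, protocol)
  problems <- setdiff(problems, "nonpositive signal present")  # handled per voxel
  if (length(problems))
    stop("series fails validation: ", paste(problems, collapse = "; "))
  dims <- dim(series$data)[1:3]
  if (is.null(mask)) {
    mask_arr <- array(TRUE, dims)
  } else if (inherits(mask, "label_volume")) {
    mask_arr <- mask$labels != 0L
  } else {
    mask_arr <- mask
  }
  if (!identical(dim(mask_arr), dims)) stop("mask grid mismatch")
  if (correct_motion && series$n_volumes >= 2L)
    series <- correct_bulk_motion(series, protocol)$series
  comb <- combine_directions(series, protocol)
  nb <- length(comb$b_values)
  vox <- which(mask_arr)
  Smat <- matrix(comb$series$data, ncol = nb)[vox, , drop = FALSE]
  fit <- fit_decay_matrix(Smat, comb$b_values)
  mk <- function(v, fill) { a <- array(fill, dims); a[vox] <- v; a }
  decay_map(d = mk(fit$d, NA_real_),
            s0 = mk(fit$s0, NA_real_),
            r_squared = mk(fit$r_squared, NA_real_),
            n_shells_used = mk(fit$n_shells_used, 0L),
            valid_mask = mk(fit$valid, FALSE))
}

#' Mean decay rate within an atlas region
#'
#' Arithmetic mean of D over the valid voxels of one region, mirroring the
#' per-participant ROI averaging of the decay maps.
#'
#' @param map A [decay_map].
#' @param atlas A [label_volume] on the same grid.
#' @param region Region code or name.
#' @return List with `mean` (mm^2/s) and `n_voxels` used.
#' @export
summarize_roi <- function(map, atlas, region) {
  stopifnot(inherits(map, "decay_map"), inherits(atlas, "label_volume"))
  if (!identical(dim(map$d), dim(atlas$labels))) stop("grid mismatch")
  sel <- region_mask(atlas, region) & map$valid_mask
  if (!any(sel)) stop("region has zero valid voxels")
  list(mean = mean(map$d[sel]), n_voxels = sum(sel))
}
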