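test_that("bulk-motion correction recovers injected integer shifts", {
  atlas <- tiny_atlas()
  dwi <- simulate_dwi_series(atlas, tissue_parameters(),
                             default_dwi_protocol(), snr = 40, seed = 2)
  injected <- list(`5` = c(2L, 0L, -1L), `9` = c(-3L, 1L, 0L),
                   `20` = c(0L, 0L, 3L))
  shifted <- dwi
  for (k in names(injected))
    shifted$data[, , , as.integer(k)] <-
      csfmotion:::circular_shift3(dwi$data[, , , as.integer(k)],
                                  injected[[k]])
  mc <- correct_bulk_motion(shifted, default_dwi_protocol())
  for (k in names(injected))
    expect_equal(mc$shifts[as.integer(k), ], -injected[[k]],
                 ignore_attr = TRUE)
  untouched <- setdiff(seq_len(43), as.integer(names(injected)))
  expect_true(all(mc$shifts[untouched, ] == 0L))
  # realigned volumes equal the originals
  expect_equal(mc$series$data[, , , 5], dwi$data[, , , 5])
})

test_that("FFT shift detection agrees with the brute-force NCC search", {
  set.seed(31)
  ref <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  for (s in list(c(0L, 0L, 0L), c(1L, -2L, 3L), c(-3L, -3L, -3L))) {
    vol <- csfmotion:::circular_shift3(ref, s) + rnorm(length(ref), 0, 0.2)
    series <- volume_series(array(c(ref, vol), c(16, 16, 16, 2)))
    mc <- correct_bulk_motion(series)
    oracle <- brute_force_shift(ref, vol)   # corrective shift for vol
    expect_equal(unname(mc$shifts[2, ]), oracle)
    expect_equal(oracle, -s)  # the oracle itself undoes the injected shift
  }
})

test_that("single-volume series cannot be aligned", {
  s <- volume_series(array(1, c(8, 8, 8, 1)))
  expect_error(correct_bulk_motion(s), "nothing to align")
})

test_that("direction combination is a per-shell geometric mean", {
  dat <- array(0, c(2, 2, 2, 4))
  dat[, , , 1] <- 10            # b = 0
  dat[, , , 2] <- 1; dat[, , , 3] <- 2; dat[, , , 4] <- 4
  s <- volume_series(dat)
  prot <- acquisition_protocol(c(0, 500, 500, 500), c(0L, 1L, 2L, 3L))
  comb <- combine_directions(s, prot)
  expect_equal(comb$b_values, c(0, 500))
  expect_equal(unique(as.vector(comb$series$data[, , , 2])), 2)  # (1*2*4)^(1/3)
  # permuting direction volumes leaves the result unchanged
  s2 <- volume_series(dat[, , , c(1, 4, 2, 3)])
  comb2 <- combine_directions(s2, prot)
  expect_equal(comb2$series$data, comb$series$data)
  # isotropic noiseless input: combined equals any single direction
  atlas <- tiny_atlas()
  prot6 <- acquisition_protocol(c(0, rep(700, 6)), c(0L, 1:6))
  d6 <- simulate_dwi_series(atlas, tissue_parameters(), prot6)
  c6 <- combine_directions(d6, prot6)
  tissue <- atlas$labels != 0L   # background is zero-signal, hence dropped
  expect_equal(c6$series$data[, , , 2][tissue], d6$data[, , , 2][tissue],
               tolerance = 1e-12)
})

test_that("voxel fit recovers reference decay rates to machine precision", {
  b <- c(0, 50, 100, 200, 300, 700, 1000)
  for (d_true in c(0.00328, 0.00256, 0.00138, 0.00241)) {
    sig <- 120 * exp(-b * d_true)
    fit <- fit_decay_voxel(sig, b)
    expect_true(fit$valid)
    expect_equal(fit$d, d_true, tolerance = 1e-12)
    expect_equal(fit$s0, 120, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1)
    expect_equal(fit$n_shells_used, 7L)
  }
})

test_that("two-point closed form ln(S0/S)/b is reproduced", {
  b <- c(0, 500, 1000)
  d_cf <- log(2) / 1000
  sig <- 1 * exp(-b * d_cf)   # S(0)=1, S(1000)=0.5, consistent midpoint
  fit <- fit_decay_voxel(sig, b)
  expect_equal(fit$d, d_cf, tolerance = 1e-12)
})

test_that("degenerate voxels are flagged, not fitted", {
  b <- c(0, 50, 100, 200, 300, 700, 1000)
  # constant signal: D at the zero boundary -> invalid
  fit <- fit_decay_voxel(rep(5, 7), b)
  expect_false(fit$valid)
  # nonpositive shells dropped and counted out
  sig <- 100 * exp(-b * 0.002); sig[c(2, 5)] <- 0
  fit2 <- fit_decay_voxel(sig, b)
  expect_equal(fit2$n_shells_used, 5L)
  expect_equal(fit2$d, 0.002, tolerance = 1e-12)
  # fewer than 3 positive shells: invalid, no exception
  fit3 <- fit_decay_voxel(c(10, 5, 0, 0, 0, 0, 0), b)
  expect_false(fit3$valid)
})

test_that("nonlinear refinement matches an independent NLS fit on noisy data", {
  skip_if_not_installed("minpack.lm")
  set.seed(77)
  b <- c(0, 50, 100, 200, 300, 700, 1000)
  for (i in 1:25) {
    d_true <- runif(1, 5e-4, 4e-3)
    sig <- pmax(1e-3, 100 * exp(-b * d_true) + rnorm(7, 0, 2))
    mine <- fit_decay_voxel(sig, b)
    ref <- minpack.lm::nlsLM(
      sig ~ s0 * exp(-b * d), start = list(s0 = sig[1], d = 1e-3),
      lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
    expect_equal(mine$d, coef(ref)[["d"]], tolerance = 1e-6)
    expect_equal(mine$s0, coef(ref)[["s0"]], tolerance = 1e-6)
  }
})

test_that("log-linear initializer and refinement agree on noiseless input", {
  b <- c(0, 50, 100, 200, 300, 700, 1000)
  S <- matrix(80 * exp(-b * 0.0026), nrow = 1)
  fit <- csfmotion:::fit_decay_matrix(S, b)
  expect_lt(abs(fit$d - fit$d_init) / fit$d, 1e-3)
})

test_that("fit is scale invariant and monotone in the true decay rate", {
  b <- c(0, 50, 100, 200, 300, 700, 1000)
  sig <- 100 * exp(-b * 0.0021)
  f1 <- fit_decay_voxel(sig, b)
  f2 <- fit_decay_voxel(1000 * sig, b)
  expect_equal(f2$d, f1$d, tolerance = 1e-12)
  expect_equal(f2$s0, 1000 * f1$s0, tolerance = 1e-9)
  d_grid <- seq(5e-4, 5e-3, length.out = 9)
  fits <- vapply(d_grid, function(d)
    fit_decay_voxel(100 * exp(-b * d), b)$d, numeric(1))
  expect_true(all(diff(fits) > 0))
  sigs <- vapply(d_grid, function(d) 100 * exp(-700 * d), numeric(1))
  expect_true(all(diff(sigs) < 0))
})

test_that("map-level fit recovers every region exactly on the noiseless phantom", {
  atlas <- tiny_atlas()
  tp <- tissue_parameters()
  prot <- default_dwi_protocol()
  dwi <- simulate_dwi_series(atlas, tp, prot)
  dm <- fit_decay_map(dwi, prot, mask = atlas)
  for (r in c("white_matter", "gray_matter", "ventricle_csf",
              "choroid_plexus", "suprasellar_cistern")) {
    d_true <- tp$d_true[tp$region == r]
    sel <- region_mask(atlas, r)
    expect_true(all(dm$valid_mask[sel]))
    expect_lt(max(abs(dm$d[sel] - d_true)), 1e-10)
  }
  # unmasked (background) voxels are invalid and NA
  bg <- region_mask(atlas, "background")
  expect_true(all(!dm$valid_mask[bg]))
  expect_true(all(is.na(dm$d[bg])))
})

test_that("an all-zero voxel is isolated without contaminating neighbors", {
  atlas <- tiny_atlas()
  prot <- default_dwi_protocol()
  dwi <- simulate_dwi_series(atlas, tissue_parameters(), prot)
  wm_idx <- which(region_mask(atlas, "white_matter"))[1]
  coords <- arrayInd(wm_idx, dim(atlas$labels))
  dwi$data[coords[1], coords[2], coords[3], ] <- 0
  dm <- fit_decay_map(dwi, prot, mask = atlas, correct_motion = FALSE)
  expect_false(dm$valid_mask[coords])
  others <- setdiff(which(region_mask(atlas, "white_matter")), wm_idx)
  expect_lt(max(abs(dm$d[others] - 0.00131)), 1e-10)
})

test_that("empty masks and grid mismatches are rejected cleanly", {
  atlas <- tiny_atlas()
  prot <- default_dwi_protocol()
  dwi <- simulate_dwi_series(atlas, tissue_parameters(), prot)
  dm <- fit_decay_map(dwi, prot, mask = array(FALSE, dim(atlas$labels)),
                      correct_motion = FALSE)
  expect_equal(sum(dm$valid_mask), 0L)
  expect_error(fit_decay_map(dwi, prot, mask = array(TRUE, c(4, 4, 4))),
               "mismatch")
})

test_that("ROI summaries average valid voxels only", {
  atlas <- tiny_atlas()
  prot <- default_dwi_protocol()
  dwi <- simulate_dwi_series(atlas, tissue_parameters(), prot)
  dm <- fit_decay_map(dwi, prot, mask = atlas, correct_motion = FALSE)
  s <- summarize_roi(dm, atlas, "ventricle_csf")
  expect_equal(s$mean, 0.00241, tolerance = 1e-10)
  # invalidate half the region: mean over the valid half only
  sel <- which(region_mask(atlas, "ventricle_csf"))
  half <- sel[seq_len(length(sel) %/% 2)]
  dm$valid_mask[half] <- FALSE
  dm$d[half] <- 99  # would poison the mean if masking were ignored
  s2 <- summarize_roi(dm, atlas, "ventricle_csf")
  expect_equal(s2$mean, 0.00241, tolerance = 1e-10)
  expect_equal(s2$n_voxels, length(sel) - length(half))
  expect_error(summarize_roi(dm, atlas, 42L), "unknown region")
})
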