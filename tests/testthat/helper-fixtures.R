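## Shared fixtures and independent oracles used across the suite.

tiny_atlas <- function(seed = 1) build_tissue_atlas(c(16, 16, 16), seed)

small_atlas <- function(seed = 1) build_tissue_atlas(c(32, 32, 16), seed)

## Exhaustive Mann-Whitney enumeration: two-sided p of the rank-sum test
## by enumerating all C(m+n, m) assignments of the pooled ranks.
enumerate_wilcoxon_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  ## two-sided: double the smaller tail (as in the exact distribution)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

## Brute-force integer-shift NCC search (the motion-correction oracle).
brute_force_shift <- function(ref, vol, max_shift = 3) {
  best <- c(0L, 0L, 0L); best_cc <- -Inf
  ref0 <- ref - mean(ref)
  grid <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift,
                      dz = -max_shift:max_shift)
  for (i in seq_len(nrow(grid))) {
    s <- as.integer(grid[i, ])
    shifted <- csfmotion:::circular_shift3(vol, s)
    cc <- sum(ref0 * (shifted - mean(shifted)))
    if (cc > best_cc + 1e-12) { best_cc <- cc; best <- s }
  }
  best
}
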