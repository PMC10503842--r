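## Synthetic cohort with the statistical structure the group-level
## analysis assumes: per-group ROI decay-rate and perfusion distributions,
## a rank correlation between suprasellar decay and choroid plexus
## perfusion in the disease group, and demographics.

#' Specification of a synthetic two-group cohort
#'
#' Defaults reproduce the study conditions: 32 healthy and 27 Parkinson's
#' disease (PD) subjects; per-ROI decay-rate means/SDs and choroid plexus
#' perfusion per group from the group-descriptives table (suprasellar
#' cistern 0.00328 +/- 0.00123 healthy vs 0.00256 +/- 0.00094 PD mm^2/s;
#' perfusion 31.3 +/- 5.6 vs 31.5 +/- 7.9 mL/100 g/min); a target Spearman
#' correlation of -0.51 between suprasellar decay and perfusion in PD and
#' 0 in healthy; age 67.6 +/- 9.0 vs 66.0 +/- 6.8 years; UPDRS 32.4 +/-
#' 12.5 (PD only) and MoCA 26.5 +/- 2.8 vs 24.3 +/- 3.9.  The study
#' reports no sex counts, so the sex ratio defaults to 0.5 in both groups.
#'
#' @param n_per_group Integer length-2 vector: c(healthy, PD), each >= 2.
#' @param roi_means,roi_sds Lists with elements `healthy` and `pd`, each a
#'   named numeric vector of decay-rate means/SDs (mm^2/s) per ROI.
#' @param perfusion_mean,perfusion_sd Length-2 numeric c(healthy, pd).
#' @param rho_s Length-2 target Spearman correlation between suprasellar
#'   decay and perfusion, c(healthy, pd), each in [-1, 1].
#' @param age_mean,age_sd,moca_mean,moca_sd Length-2 numeric c(healthy, pd).
#' @param updrs_mean,updrs_sd PD-only UPDRS distribution.
#' @param sex_ratio Length-2 probability of female per group.
#' @param rho_s_updrs Optional target Spearman correlation between UPDRS
#'   and suprasellar decay in PD (default 0: no injected effect).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_per_group = c(healthy = 32L, pd = 27L),
    roi_means = list(
      healthy = c(ventricle_csf = 0.00241, gray_matter = 0.00138,
                  white_matter = 0.00131, suprasellar_cistern = 0.00328),
      pd = c(ventricle_csf = 0.00239, gray_matter = 0.00136,
             white_matter = 0.00129, suprasellar_cistern = 0.00256)),
    roi_sds = list(
      healthy = c(ventricle_csf = 0.00035, gray_matter = 0.00026,
                  white_matter = 0.00026, suprasellar_cistern = 0.00123),
      pd = c(ventricle_csf = 0.00033, gray_matter = 0.00024,
             white_matter = 0.00023, suprasellar_cistern = 0.00094)),
    perfusion_mean = c(healthy = 31.3, pd = 31.5),
    perfusion_sd = c(healthy = 5.6, pd = 7.9),
    rho_s = c(healthy = 0, pd = -0.51),
    age_mean = c(healthy = 67.6, pd = 66.0),
    age_sd = c(healthy = 9.0, pd = 6.8),
    updrs_mean = 32.4, updrs_sd = 12.5,
    moca_mean = c(healthy = 26.5, pd = 24.3),
    moca_sd = c(healthy = 2.8, pd = 3.9),
    sex_ratio = c(healthy = 0.5, pd = 0.5),
    rho_s_updrs = 0,
    seed = 1L) {
  if (length(n_per_group) != 2L || any(n_per_group < 2L))
    stop("n_per_group must be two counts >= 2")
  if (any(unlist(roi_sds) < 0) || any(perfusion_sd < 0))
    stop("SDs must be >= 0")
  if (any(abs(rho_s) > 1) || abs(rho_s_updrs) > 1)
    stop("rank correlations must lie in [-1, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Pearson parameter of a Gaussian copula for a target Spearman rho
#'
#' For a bivariate Gaussian copula the population Spearman correlation
#' rho_s relates to the Pearson parameter rho by
#' `rho_s = (6/pi) * asin(rho/2)`; inverting gives
#' `rho = 2 * sin(pi * rho_s / 6)`.
#'
#' @param rho_s Target Spearman correlation in [-1, 1].
#' @return Pearson correlation parameter.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1)) stop("rho_s must lie in [-1, 1]")
  2 * sin(pi * rho_s / 6)
}

#' Draw standard-normal pairs with a target Spearman correlation
#'
#' Samples `n` pairs from a bivariate normal whose Pearson parameter is
#' calibrated via [spearman_to_pearson()] so that the population Spearman
#' correlation of the sample equals `rho_s`.
#'
#' @param n Number of pairs.
#' @param rho_s Target Spearman correlation.
#' @param seed Integer seed.
#' @return An `n` x 2 matrix of standard-normal margins.
#' @export
sample_rank_correlated_pairs <- function(n, rho_s, seed = 1L) {
  rho <- spearman_to_pearson(rho_s)
  sigma <- matrix(c(1, rho, rho, 1), 2, 2)
  with_seed(seed, MASS::mvrnorm(n, mu = c(0, 0), Sigma = sigma))
}

#' Simulate a synthetic cohort table
#'
#' Draws one record per subject: group, age, sex, per-ROI decay rates,
#' choroid plexus perfusion, UPDRS (PD only) and MoCA.  Suprasellar decay
#' and perfusion are drawn jointly through a Gaussian copula calibrated to
#' the group's target Spearman correlation; all other ROI rates are
#' independent Normals.  Decay rates are truncated below at 1e-5 mm^2/s
#' and perfusion at the 10 mL/100 g/min noise floor, so every recorded
#' value is physically admissible.  Deterministic given the seed carried
#' by the [cohort_spec].
#'
#' @param spec A [cohort_spec].
#' @return A data frame of class `cohort_table` with columns `subject_id`,
#'   `group`, `age`, `sex`, one `decay_<roi>` column per ROI,
#'   `cp_perfusion`, `updrs`, `moca`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  d_floor <- 1e-5
  groups <- c("healthy", "pd")
  with_seed(spec$seed, {
    rows <- lapply(seq_along(groups), function(g) {
      grp <- groups[g]
      n <- spec$n_per_group[[g]]
      ## joint draw: suprasellar decay, perfusion (copula), plus an
      ## optional UPDRS component rank-correlated with suprasellar decay
      rho_dp <- spearman_to_pearson(spec$rho_s[[g]])
      rho_du <- if (grp == "pd") spearman_to_pearson(spec$rho_s_updrs) else 0
      sigma <- diag(3)
      sigma[1, 2] <- sigma[2, 1] <- rho_dp
      sigma[1, 3] <- sigma[3, 1] <- rho_du
      z <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = sigma)
      supra <- pmax(d_floor, spec$roi_means[[grp]]["suprasellar_cistern"] +
                      spec$roi_sds[[grp]]["suprasellar_cistern"] * z[, 1])
      perf <- pmax(CBF_FLOOR, spec$perfusion_mean[[g]] +
                     spec$perfusion_sd[[g]] * z[, 2])
      other <- setdiff(names(spec$roi_means[[grp]]), "suprasellar_cistern")
      roi <- vapply(other, function(r)
        pmax(d_floor, rnorm(n, spec$roi_means[[grp]][r],
                            spec$roi_sds[[grp]][r])), numeric(n))
      df <- data.frame(
        subject_id = sprintf("%s_%03d", grp, seq_len(n)),
        group = grp,
        age = round(rnorm(n, spec$age_mean[[g]], spec$age_sd[[g]]), 1),
        sex = ifelse(runif(n) < spec$sex_ratio[[g]], "F", "M"),
        stringsAsFactors = FALSE)
      for (r in other) df[[paste0("decay_", r)]] <- roi[, r]
      df$decay_suprasellar_cistern <- as.numeric(supra)
      df$cp_perfusion <- as.numeric(perf)
      df$updrs <- if (grp == "pd")
        pmax(0, spec$updrs_mean + spec$updrs_sd * z[, 3]) else NA_real_
      df$moca <- pmin(30, round(rnorm(n, spec$moca_mean[[g]],
                                      spec$moca_sd[[g]])))
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Write / read a cohort table as TSV
#'
#' @param table A `cohort_table` data frame.
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_cohort_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
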