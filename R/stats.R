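## Cohort-level statistics: group descriptives, Wilcoxon rank-sum and
## chi-squared comparisons, Spearman rank correlations, and simple linear
## regressions of decay rate on cohort, age and sex.  Significance is
## two-sided p < 0.05 with no multiplicity adjustment.

ALPHA <- 0.05

#' Wilcoxon rank-sum comparison of two samples
#'
#' Midranks handle ties.  With combined n <= 12 and no ties the two-sided
#' p-value comes from exact enumeration of the rank-sum distribution;
#' otherwise from the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variable Label for the compared variable.
#' @return List of class `group_comparison`: `variable`, `test`,
#'   `mean_x`, `sd_x`, `mean_y`, `sd_y`, `statistic` (Mann-Whitney U of
#'   `x`), `p_value`, `significant`.
#' @export
wilcoxon_rank_sum <- function(x, y, variable = "value") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  exact <- (length(x) + length(y)) <= 12 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  comparison_result(variable, "wilcoxon_rank_sum", x, y,
                    statistic = unname(wt$statistic), p = wt$p.value)
}

comparison_result <- function(variable, test, x, y, statistic, p) {
  structure(list(variable = variable, test = test,
                 mean_x = mean(x), sd_x = sd(x),
                 mean_y = mean(y), sd_y = sd(y),
                 statistic = statistic, p_value = p,
                 significant = is.finite(p) && p < ALPHA),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: %.4g +/- %.4g vs %.4g +/- %.4g, stat = %.4g, p = %.4g%s\n",
              x$variable, x$test, x$mean_x, x$sd_x, x$mean_y, x$sd_y,
              x$statistic, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of midranks, with the two-sided p-value from the
#' t approximation.  Constant input yields an undefined-rho flagged
#' result rather than an error.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @param pair Label for the variable pair.
#' @return List of class `correlation_result`: `pair`, `rho`, `p_value`,
#'   `n`, `defined`.
#' @export
spearman_corr <- function(x, y, pair = "x~y") {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(pair = pair, rho = NA_real_, p_value = NA_real_,
                          n = n, defined = FALSE),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(pair = pair, rho = unname(ct$estimate),
                 p_value = ct$p.value, n = n, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("%s: Spearman rho = %.3f, p = %.4g, n = %d\n",
                x$pair, x$rho, x$p_value, x$n))
  else
    cat(sprintf("%s: rho undefined (constant input), n = %d\n", x$pair, x$n))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom.
#'
#' @param table 2x2 matrix of counts.
#' @param variable Label.
#' @return A `group_comparison` (means/SDs are the per-group proportions
#'   of the first category).
#' @export
chi_squared_2x2 <- function(table, variable = "category") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected count <= 0")
  p1 <- table[1, 1] / sum(table[, 1])
  p2 <- table[1, 2] / sum(table[, 2])
  structure(list(variable = variable, test = "chi_squared",
                 mean_x = p1, sd_x = NA_real_, mean_y = p2, sd_y = NA_real_,
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 significant = ct$p.value < ALPHA),
            class = "group_comparison")
}

#' Simple (and optional joint) linear regression of a response
#'
#' Ordinary least squares with t-based two-sided p-values.  Matching the
#' cohort analysis design, each covariate is fitted in its own simple
#' regression by default; `joint = TRUE` adds the all-covariate model.
#' Sex enters as a binary indicator; cohort as an indicator of the second
#' group level.
#'
#' @param response Numeric response vector.
#' @param covariates Data frame of covariates (numeric, or 2-level
#'   factor/character encoded as 0/1).
#' @param joint Also fit the joint model.
#' @return Data frame with columns `model`, `term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`.
#' @export
linear_regression <- function(response, covariates, joint = FALSE) {
  covariates <- as.data.frame(covariates)
  n <- length(response)
  if (n != nrow(covariates)) stop("length mismatch")
  if (n <= ncol(covariates) + 1L) stop("too few observations")
  enc <- as.data.frame(lapply(covariates, function(v) {
    if (is.numeric(v)) return(v)
    lv <- sort(unique(as.character(v)))
    if (length(lv) != 2) stop("non-numeric covariates must have 2 levels")
    as.numeric(as.character(v) == lv[2])
  }))
  one <- function(df, label) {
    fit <- lm(response ~ ., data = df)
    sm <- summary(fit)$coefficients
    data.frame(model = label, term = rownames(sm), estimate = sm[, 1],
               std_error = sm[, 2], t_value = sm[, 3], p_value = sm[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(enc), function(nm)
    one(enc[, nm, drop = FALSE], nm)))
  if (joint) out <- rbind(out, one(enc, "joint"))
  out
}

#' Full cohort-level analysis bundle
#'
#' Reproduces the group-level analysis on a cohort table: group
#' descriptives for every continuous variable; Wilcoxon rank-sum
#' comparisons of age, each ROI decay rate, perfusion and MoCA between
#' groups; chi-squared comparison of sex; Spearman correlation of
#' suprasellar decay rate vs choroid plexus perfusion within each group
#' and pooled; exploratory Spearman of UPDRS and MoCA vs suprasellar
#' decay in the disease group; and simple regressions of suprasellar
#' decay on cohort, age and sex.
#'
#' @param table A `cohort_table` data frame (see [simulate_cohort()]).
#' @return List of class `cohort_analysis` with elements `descriptives`,
#'   `comparisons`, `correlations` and `regressions` (data frames).
#' @export
cohort_analysis <- function(table) {
  need <- c("group", "age", "sex", "decay_suprasellar_cistern",
            "cp_perfusion")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  groups <- sort(unique(table$group))
  if (length(groups) != 2)
    stop("need exactly two groups, found: ", paste(groups, collapse = ", "))
  g1 <- table[table$group == groups[1], ]
  g2 <- table[table$group == groups[2], ]
  cont <- c("age", grep("^decay_", names(table), value = TRUE),
            "cp_perfusion", intersect("moca", names(table)))

  desc <- do.call(rbind, lapply(cont, function(v) data.frame(
    variable = v,
    mean_1 = mean(g1[[v]], na.rm = TRUE), sd_1 = sd(g1[[v]], na.rm = TRUE),
    mean_2 = mean(g2[[v]], na.rm = TRUE), sd_2 = sd(g2[[v]], na.rm = TRUE),
    stringsAsFactors = FALSE)))
  names(desc)[2:5] <- c(paste0(c("mean_", "sd_"), groups[1]),
                        paste0(c("mean_", "sd_"), groups[2]))

  comp <- lapply(cont, function(v)
    wilcoxon_rank_sum(g1[[v]], g2[[v]], variable = v))
  sex_tab <- table(factor(table$sex), factor(table$group, levels = groups))
  comp <- c(comp, list(chi_squared_2x2(as.matrix(sex_tab), "sex")))
  comparisons <- do.call(rbind, lapply(comp, function(r)
    data.frame(variable = r$variable, test = r$test, statistic = r$statistic,
               p_value = r$p_value, significant = r$significant,
               stringsAsFactors = FALSE)))

  cors <- list(
    spearman_corr(table$decay_suprasellar_cistern, table$cp_perfusion,
                  "suprasellar_decay~cp_perfusion[pooled]"))
  for (g in groups) {
    sub <- table[table$group == g, ]
    cors <- c(cors, list(spearman_corr(
      sub$decay_suprasellar_cistern, sub$cp_perfusion,
      sprintf("suprasellar_decay~cp_perfusion[%s]", g))))
  }
  pd_like <- if ("pd" %in% groups) "pd" else groups[2]
  pd <- table[table$group == pd_like, ]
  if ("updrs" %in% names(table) && sum(!is.na(pd$updrs)) >= 3)
    cors <- c(cors, list(spearman_corr(
      pd$updrs, pd$decay_suprasellar_cistern,
      sprintf("updrs~suprasellar_decay[%s]", pd_like))))
  if ("moca" %in% names(table))
    cors <- c(cors, list(spearman_corr(
      pd$moca, pd$decay_suprasellar_cistern,
      sprintf("moca~suprasellar_decay[%s]", pd_like))))
  correlations <- do.call(rbind, lapply(cors, function(r)
    data.frame(pair = r$pair, rho = r$rho, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)))

  regressions <- linear_regression(
    table$decay_suprasellar_cistern,
    table[, c("group", "age", "sex")])

  structure(list(descriptives = desc, comparisons = comparisons,
                 correlations = correlations, regressions = regressions,
                 groups = groups),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis (", paste(x$groups, collapse = " vs "), ")\n\n",
      sep = "")
  cat("Group comparisons:\n")
  print(x$comparisons, row.names = FALSE)
  cat("\nRank correlations:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Write a cohort analysis bundle as TSV files
#'
#' Emits `descriptives.tsv`, `comparisons.tsv`, `correlations.tsv` and
#' `regressions.tsv` into a directory; each round-trips losslessly via
#' [read.table()].
#'
#' @param results A `cohort_analysis`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_analysis <- function(results, dir) {
  stopifnot(inherits(results, "cohort_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("descriptives", "comparisons", "correlations", "regressions"))
    write.table(results[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
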