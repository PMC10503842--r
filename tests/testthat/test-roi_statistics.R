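test_that("rank-sum test reproduces exact small-sample p-values", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)          # exhaustive C(6,3)=20 enumeration
  expect_equal(r$p_value, enumerate_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  # symmetry in the sample order
  r2 <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p_value, r$p_value)
  # identical multisets: p near 1
  set.seed(1)
  x <- rnorm(20)
  r3 <- wilcoxon_rank_sum(x, x)
  expect_gt(r3$p_value, 0.95)
  expect_false(r3$significant)
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "n >= 2")
})

test_that("small-sample p-values equal exhaustive enumeration exactly", {
  set.seed(42)
  for (m in 3:6) for (n in 3:(12 - m)) {
    x <- rnorm(m); y <- rnorm(n, 0.8)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, enumerate_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the approximation used above the exact switch stays within 0.02", {
  ## exhaustive check over every attainable statistic at the splits of 12
  ## with both groups >= 4 (the smallest sizes the approximation serves)
  for (mn in list(c(6, 6), c(5, 7), c(4, 8))) {
    m <- mn[1]; n <- mn[2]
    for (u in 0:(m * n)) {
      p_exact <- min(1, 2 * min(pwilcox(u, m, n), 1 - pwilcox(u - 1, m, n)))
      mu <- m * n / 2; sg <- sqrt(m * n * (m + n + 1) / 12)
      z <- (u - mu - sign(u - mu) * 0.5) / sg
      p_norm <- min(1, 2 * min(pnorm(z), 1 - pnorm(z)))
      expect_lt(abs(p_norm - p_exact), 0.02)
    }
  }
})

test_that("rank-sum handles ties through midranks", {
  x <- c(1, 2, 2, 3); y <- c(2, 4, 4, 5)
  r <- wilcoxon_rank_sum(x, y)
  expect_true(is.finite(r$p_value))
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("Spearman correlation is a rank statistic with t-based p", {
  dec <- spearman_corr(1:10, 10:1)
  expect_equal(dec$rho, -1)
  # hand-checkable midrank case: ranks y = (2,1,4,3,5), sum d^2 = 4
  r <- spearman_corr(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))  # = 0.8
  # invariance under strictly increasing transforms of x
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_corr(exp(x), y)$rho, spearman_corr(x, y)$rho)
  expect_equal(spearman_corr(x^3, y)$rho, spearman_corr(x, y)$rho)
  # constant input: flagged, not an exception
  flat <- spearman_corr(rep(1, 5), 1:5)
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})

test_that("chi-squared on 2x2 tables matches the closed-form statistic", {
  even <- chi_squared_2x2(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  diag40 <- chi_squared_2x2(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(diag40$statistic, 40)
  m <- matrix(c(12, 5, 7, 14), 2, 2)
  expect_equal(chi_squared_2x2(t(m))$statistic, chi_squared_2x2(m)$statistic)
  expect_error(chi_squared_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("simple regressions recover slopes and agree with the OLS identity", {
  age <- seq(50, 80, length.out = 31)
  resp <- 0.004 - 2e-5 * age
  out <- suppressWarnings(linear_regression(resp, data.frame(age = age)))
  slope <- out$estimate[out$term == "age"]
  expect_equal(slope, -2e-5, tolerance = 1e-12)
  expect_lt(out$p_value[out$term == "age"], 1e-10)
  # closed form cov(x,y)/var(x)
  set.seed(4)
  x <- rnorm(40); y <- 2 + 0.5 * x + rnorm(40, 0, 0.3)
  out2 <- linear_regression(y, data.frame(x = x))
  expect_equal(out2$estimate[out2$term == "x"], cov(x, y) / var(x),
               tolerance = 1e-12)
})

test_that("regression p-values are calibrated against a permutation oracle", {
  set.seed(12)
  n <- 40
  x <- rnorm(n)
  y <- rnorm(n)   # independent of x
  out <- linear_regression(y, data.frame(x = x))
  slope_obs <- out$estimate[out$term == "x"]
  p_t <- out$p_value[out$term == "x"]
  perm <- replicate(10000, {
    xp <- sample(x)
    cov(xp, y) / var(xp)
  })
  p_perm <- mean(abs(perm) >= abs(slope_obs))
  expect_lt(abs(p_perm - p_t), 0.03)
  expect_lt(abs(slope_obs), 3 * sd(perm))  # null slope within its null spread
})

test_that("joint and categorical designs are handled", {
  set.seed(6)
  df <- data.frame(group = rep(c("healthy", "pd"), each = 15),
                   age = rnorm(30, 67, 8))
  y <- ifelse(df$group == "pd", 0.0026, 0.0033) + rnorm(30, 0, 5e-4)
  out <- linear_regression(y, df, joint = TRUE)
  expect_setequal(unique(out$model), c("group", "age", "joint"))
  est <- out$estimate[out$model == "group" & out$term == "group"]
  expect_lt(est, 0)  # pd coded 1 lowers the decay rate
  expect_error(linear_regression(y[1:3], df[1:3, ]), "too few")
})

test_that("cohort analysis flags the injected suprasellar group difference", {
  tab <- simulate_cohort(cohort_spec(seed = 7))
  res <- cohort_analysis(tab)
  expect_s3_class(res, "cohort_analysis")
  expect_true("decay_suprasellar_cistern" %in% res$comparisons$variable)
  pd_cor <- res$correlations[
    res$correlations$pair == "suprasellar_decay~cp_perfusion[pd]", ]
  expect_lt(pd_cor$rho, 0)
  # serialization round trip of the bundle
  dir <- withr::local_tempdir()
  write_cohort_analysis(res, dir)
  comp <- read.table(file.path(dir, "comparisons.tsv"), sep = "\t",
                     header = TRUE)
  expect_equal(comp$p_value, res$comparisons$p_value, tolerance = 1e-12)
  expect_equal(nrow(read.table(file.path(dir, "descriptives.tsv"),
                               sep = "\t", header = TRUE)),
               nrow(res$descriptives))
})

test_that("the suprasellar comparison is usually detected at study sizes", {
  hits <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    tab <- simulate_cohort(cohort_spec(seed = 5000 + i))
    res <- cohort_analysis(tab)
    row <- res$comparisons[
      res$comparisons$variable == "decay_suprasellar_cistern", ]
    hits <- hits + row$significant
  }
  expect_gt(hits / n_rep, 0.5)  # detected in the majority of replicates
})

test_that("analysis rejects single-group and incomplete tables", {
  tab <- simulate_cohort(cohort_spec(seed = 1))
  expect_error(cohort_analysis(tab[tab$group == "pd", ]), "two groups")
  expect_error(cohort_analysis(tab[, setdiff(names(tab), "cp_perfusion")]),
               "missing required")
})
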