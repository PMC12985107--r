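# Frozen reference values: the Shapiro-Wilk W for the fixed 10-point
# sample and the 8x3 within-subject ANOVA results were computed once with
# an independent reference implementation (scipy.stats.shapiro and
# pingouin.rm_anova / pingouin.sphericity) and recorded here.

sw_fixture <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195)

rm_fixture <- matrix(c(45, 50, 55,
                       42, 42, 45,
                       36, 41, 43,
                       39, 35, 40,
                       51, 55, 59,
                       44, 49, 56,
                       37, 37, 45,
                       40, 46, 60), nrow = 8, byrow = TRUE)

test_that("Shapiro-Wilk gate matches the reference implementation", {
  got <- shapiro_wilk(sw_fixture)
  expect_equal(got$w, 0.908049, tolerance = 1e-3)
  expect_error(shapiro_wilk(rep(5, 10)), "constant")
  set.seed(1)
  bimodal <- c(rnorm(25, -4, 0.5), rnorm(25, 4, 0.5))
  expect_lt(shapiro_wilk(bimodal)$p, 0.01)
})

test_that("paired comparison agrees with t.test and is internally consistent", {
  set.seed(31)
  x <- rnorm(12, 100, 20); y <- x + rnorm(12, 15, 10)
  got <- paired_compare(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-12)
  expect_equal(got$df, 11L)
  # effect-size identities
  expect_equal(got$cohen_d, got$t_stat / sqrt(12), tolerance = 1e-12)
  expect_equal(got$hedges_g, got$cohen_d * (1 - 3 / (4 * 11 - 1)),
               tolerance = 1e-12)
  expect_true(got$ci_low <= got$mean_diff && got$mean_diff <= got$ci_high)

  expect_error(paired_compare(c(1, 2, 3), c(2, 3, 4)), "degenerate")
})

test_that("regression diagnostics match oracles including Durbin-Watson", {
  # perfect line: exact fit, DW undefined
  x <- 1:6; y <- 2 * x + 1
  got <- ols_with_diagnostics(x, y)
  expect_equal(got$slope, 2, tolerance = 1e-12)
  expect_equal(got$intercept, 1, tolerance = 1e-12)
  expect_equal(got$r2, 1)
  expect_false(got$dw_defined)
  expect_true(is.na(got$durbin_watson))

  # constructed residuals (1,-1,1,-1) orthogonal to {1, x}: DW = 3 exactly
  x2 <- c(1, 2, 4, 3); e <- c(1, -1, 1, -1)
  y2 <- 2 * x2 + 1 + e
  got2 <- ols_with_diagnostics(x2, y2)
  expect_equal(got2$durbin_watson, 3, tolerance = 1e-9)

  # random data: normal equations, lmtest cross-check, R^2 = cor^2
  set.seed(17)
  x3 <- rnorm(12); y3 <- 1.5 * x3 + rnorm(12, 0, 0.8)
  got3 <- ols_with_diagnostics(x3, y3)
  X <- cbind(1, x3)
  bh <- solve(t(X) %*% X, t(X) %*% y3)
  expect_equal(got3$intercept, bh[1], tolerance = 1e-9)
  expect_equal(got3$slope, bh[2], tolerance = 1e-9)
  expect_equal(got3$r2, cor(x3, y3)^2, tolerance = 1e-12)
  expect_equal(got3$f_stat, (12 - 2) * got3$r2 / (1 - got3$r2),
               tolerance = 1e-12)
  if (requireNamespace("lmtest", quietly = TRUE)) {
    ref <- lmtest::dwtest(lm(y3 ~ x3))
    expect_equal(got3$durbin_watson, unname(ref$statistic),
                 tolerance = 1e-9)
  }
  expect_error(ols_with_diagnostics(rep(2, 5), rnorm(5)), "singular")
})

test_that("z-standardization normalizes, is idempotent, and names offenders", {
  m <- cohort_matrix(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  z <- zscore_columns(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  expect_equal(unclass(zscore_columns(z)), unclass(z), tolerance = 1e-12)
  m2 <- cohort_matrix(cbind(a = c(1, 2, 3), flat = c(4, 4, 4)))
  expect_error(zscore_columns(m2), "flat")
})

test_that("within-subject ANOVA matches the reference fixture", {
  got <- rmanova_gg(rm_fixture)
  expect_equal(got$f_stat, 15.499115, tolerance = 1e-4)
  expect_equal(got$mauchly_w, 0.548762, tolerance = 1e-3)
  expect_equal(got$mauchly_p, 0.165254, tolerance = 1e-3)
  expect_equal(got$epsilon_gg, 0.689067, tolerance = 1e-3)
  expect_equal(got$p, 0.000282, tolerance = 5e-3)
  expect_equal(got$p_gg, 0.001793, tolerance = 5e-3)
  expect_equal(got$df1_gg, got$epsilon_gg * 2, tolerance = 1e-12)
  expect_equal(got$df2_gg, got$epsilon_gg * 14, tolerance = 1e-12)
})

test_that("ANOVA degenerates and bounds behave", {
  m <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  got <- rmanova_gg(m)
  expect_true(got$degenerate)

  # epsilon within [1/(k-1), 1]; W = 1 exactly for k = 2
  set.seed(23)
  r <- rmanova_gg(matrix(rnorm(36), 12, 3))
  expect_gte(r$epsilon_gg, 0.5)
  expect_lte(r$epsilon_gg, 1)
  expect_gt(r$mauchly_w, 0); expect_lte(r$mauchly_w, 1)
  r2 <- rmanova_gg(matrix(rnorm(24), 12, 2))
  expect_equal(r2$mauchly_w, 1)
})

test_that("z-standardized input forces a null method effect", {
  set.seed(41)
  for (k in c(3, 4)) {
    z <- zscore_columns(cohort_matrix(matrix(rnorm(12 * k), 12, k)))
    got <- rmanova_gg(z)
    expect_lt(abs(got$f_stat), 1e-12)
    expect_gt(got$p_gg, 1 - 1e-8)
  }
})

test_that("method report assembles descriptives, tests and the z-scored ANOVA", {
  set.seed(13)
  m <- cohort_matrix(cbind(krappinger = rnorm(12, 115, 35),
                           bma = rnorm(12, 207, 24),
                           ctoam = rnorm(12, 167, 40)),
                     units = c("mg/cm3", "mg/cm3", "a.u."))
  rep <- method_report(m, pairs_to_test = list(c("krappinger", "bma")),
                       regressions_to_fit = list(c("ctoam", "bma")))
  expect_equal(nrow(rep$descriptives), 3L)
  expect_equal(rep$descriptives$mean, unname(colMeans(m)))
  expect_equal(rep$descriptives$sd, unname(apply(m, 2, sd)))
  expect_length(rep$paired, 1L)
  expect_equal(rep$paired[[1]]$mean_diff, mean(m[, 2] - m[, 1]))
  expect_lt(abs(rep$rmanova$f_stat), 1e-12)
  expect_error(method_report(m[, integer(0), drop = FALSE]), "empty|3")
})
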