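#' Cohort matrix of method outputs
#'
#' An `n_specimens x k_methods` numeric matrix with method labels as
#' column names, specimen labels (donor + side) as row names, and a unit
#' per method. Inferential operations require a complete matrix.
#'
#' @param values numeric matrix (or data.frame) of method outputs.
#' @param methods optional column labels.
#' @param specimens optional row labels.
#' @param units optional character vector of per-method units.
#' @return A `cohort_matrix` (numeric matrix with attributes).
#' @export
cohort_matrix <- function(values, methods = colnames(values),
                          specimens = rownames(values), units = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("need at least 3 specimens")
  colnames(m) <- methods %||% paste0("method", seq_len(ncol(m)))
  rownames(m) <- specimens %||% paste0("S", seq_len(nrow(m)))
  attr(m, "units") <- units
  class(m) <- c("cohort_matrix", class(m))
  m
}

assert_complete <- function(m) {
  if (any(!is.finite(m))) stop("cohort matrix has missing cells")
  invisible(m)
}

#' Shapiro-Wilk normality test
#' @param sample numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `w` and `p`.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(sample) == 0) stop("constant sample: normality test undefined")
  t <- shapiro.test(sample)
  list(w = unname(t$statistic), p = t$p.value)
}

#' Paired comparison with CI and effect sizes
#'
#' For differences `d_i = y_i - x_i`: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `df = n - 1`; 95% CI `mean(d) +/- t_{0.975,df} * sd(d)/sqrt(n)`;
#' Cohen's d for paired data `mean(d)/sd(d)` (equal to `t/sqrt(n)`);
#' Hedges' g applies the small-sample correction
#' `J = 1 - 3/(4 df - 1)`. The SD uses the n-1 denominator. The
#' Shapiro-Wilk p of the differences is reported as the normality gate.
#'
#' @param x,y paired numeric vectors of equal length (n >= 3).
#' @param conf confidence level (default 0.95).
#' @return List of class `paired_test_result`: `mean_diff`, `ci_low`,
#'   `ci_high`, `t_stat`, `df`, `p`, `cohen_d`, `hedges_g`,
#'   `shapiro_p_diff`, `n`.
#' @export
paired_compare <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  d <- y - x
  s <- sd(d)
  if (s == 0) stop("degenerate input: zero-variance differences")
  se <- s / sqrt(n)
  df <- n - 1L
  tstat <- mean(d) / se
  tcrit <- qt(1 - (1 - conf) / 2, df)
  cd <- mean(d) / s
  structure(
    list(mean_diff = mean(d), ci_low = mean(d) - tcrit * se,
         ci_high = mean(d) + tcrit * se, t_stat = tstat, df = df,
         p = 2 * pt(-abs(tstat), df), cohen_d = cd,
         hedges_g = cd * (1 - 3 / (4 * df - 1)),
         shapiro_p_diff = shapiro_wilk(d)$p, n = n),
    class = "paired_test_result")
}

#' Simple OLS with residual diagnostics
#'
#' Ordinary least squares of `y` on `x` with the diagnostics used for
#' cross-modality agreement: R-squared, the overall F test
#' (`F = (n-2) R^2/(1-R^2)`, df 1 and n-2), the Durbin-Watson statistic on
#' residuals in input order, and the residual Shapiro-Wilk p. Rows must
#' therefore arrive in a fixed, documented specimen order. With an exact
#' fit the Durbin-Watson statistic is undefined and flagged rather than
#' returned as NaN.
#'
#' @param x predictor vector (non-constant, n >= 3).
#' @param y response vector.
#' @return List of class `regression_diagnostics`: `slope`, `intercept`,
#'   `r2`, `f_stat`, `df1`, `df2`, `p`, `durbin_watson`, `dw_defined`,
#'   `resid_shapiro_p`, `n`.
#' @export
ols_with_diagnostics <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need equal-length x, y with n >= 3")
  if (sd(x) == 0) stop("singular fit: constant predictor")
  fit <- lm(y ~ x)
  e <- unname(fit$residuals)
  ss_res <- sum(e^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  df2 <- n - 2L
  f <- if (r2 < 1) df2 * r2 / (1 - r2) else Inf
  dw_defined <- ss_res > max(ss_tot, 1) * 1e-12
  dw <- if (dw_defined) sum(diff(e)^2) / ss_res else NA_real_
  sw <- if (dw_defined) shapiro_wilk(e)$p else NA_real_
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, f_stat = f, df1 = 1L, df2 = df2,
         p = pf(f, 1, df2, lower.tail = FALSE),
         durbin_watson = dw, dw_defined = dw_defined,
         resid_shapiro_p = sw, n = n),
    class = "regression_diagnostics")
}

#' Z-standardize each method column
#'
#' Each column is centered to mean 0 and scaled to sample SD 1 (n-1
#' denominator), enabling comparison across measurement scales.
#'
#' @param matrix a [cohort_matrix()] (or plain matrix) with non-constant
#'   columns.
#' @return The standardized matrix (same class/attributes).
#' @export
zscore_columns <- function(matrix) {
  m <- matrix
  assert_complete(m)
  for (j in seq_len(ncol(m))) {
    s <- sd(m[, j])
    if (s == 0)
      stop("constant column cannot be z-scored: ",
           colnames(m)[j] %||% j)
    m[, j] <- (m[, j] - mean(m[, j])) / s
  }
  m
}

#' Within-subject repeated-measures ANOVA with sphericity handling
#'
#' One-way within-subject ANOVA on the method factor:
#' `F = MS_method / MS_(method x subject)`. Sphericity is assessed by
#' Mauchly's W computed from the covariance of orthonormal contrasts with
#' the standard chi-square approximation, and the Greenhouse-Geisser
#' epsilon from the same contrast covariance deflates both degrees of
#' freedom; corrected and uncorrected p values are reported together.
#'
#' @param matrix complete `n x k` [cohort_matrix()], `n >= k >= 2`.
#' @return List of class `rmanova_result`: `f_stat`, `df1`, `df2`, `p`
#'   (uncorrected), `mauchly_w`, `mauchly_p`, `epsilon_gg`, `df1_gg`,
#'   `df2_gg`, `p_gg`, `degenerate`.
#' @export
rmanova_gg <- function(matrix) {
  m <- as.matrix(matrix)
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("need at least 2 methods")
  if (n < k) stop("need at least as many specimens as methods")
  assert_complete(m)
  grand <- mean(m)
  meth <- colMeans(m)
  subj <- rowMeans(m)
  ss_method <- n * sum((meth - grand)^2)
  resid <- m - outer(subj, rep(1, k)) - outer(rep(1, n), meth) + grand
  ss_error <- sum(resid^2)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  if (ss_error <= 1e-12 * max(sum((m - grand)^2), 1)) {
    return(structure(
      list(f_stat = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
           mauchly_w = NA_real_, mauchly_p = NA_real_,
           epsilon_gg = NA_real_, df1_gg = NA_real_, df2_gg = NA_real_,
           p_gg = NA_real_, degenerate = TRUE),
      class = "rmanova_result"))
  }
  f <- (ss_method / df1) / (ss_error / df2)

  # orthonormal contrasts of the method factor
  C <- qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
  A <- t(C) %*% stats::cov(m) %*% C
  trA <- sum(diag(A))
  w <- det(A) / (trA / df1)^df1
  w <- min(max(w, 0), 1)
  mdf <- k * (k - 1L) / 2L - 1L
  if (mdf > 0 && w > 0) {
    fcorr <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    chi <- -(n - 1) * fcorr * log(w)
    mp <- pchisq(chi, mdf, lower.tail = FALSE)
  } else mp <- NA_real_
  eps <- trA^2 / (df1 * sum(A^2))
  eps <- min(max(eps, 1 / df1), 1)
  df1_gg <- eps * df1
  df2_gg <- eps * df2
  structure(
    list(f_stat = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         mauchly_w = w, mauchly_p = mp, epsilon_gg = eps,
         df1_gg = df1_gg, df2_gg = df2_gg,
         p_gg = pf(f, df1_gg, df2_gg, lower.tail = FALSE),
         degenerate = FALSE),
    class = "rmanova_result")
}

#' Assemble the full method-comparison report
#'
#' Descriptive statistics per method, the requested paired comparisons and
#' cross-modality regressions, and the repeated-measures ANOVA on the
#' z-standardized matrix.
#'
#' @param matrix a [cohort_matrix()].
#' @param pairs_to_test list of length-2 character vectors (x, y column
#'   names) for paired comparisons.
#' @param regressions_to_fit list of length-2 character vectors
#'   (predictor, response) fitted by [ols_with_diagnostics()]. Regressions
#'   may reference columns of a second matrix via `extra`.
#' @param extra optional second `cohort_matrix` (e.g. the other modality)
#'   whose columns regressions may reference.
#' @param rmanova_columns columns entering the z-scored rmANOVA (default
#'   all columns of `matrix`).
#' @return List of class `method_report`: `descriptives` (data.frame),
#'   `paired`, `regressions`, `rmanova`, `zscored`.
#' @export
method_report <- function(matrix, pairs_to_test = list(),
                          regressions_to_fit = list(), extra = NULL,
                          rmanova_columns = colnames(matrix)) {
  m <- matrix
  assert_complete(m)
  if (ncol(m) < 1L) stop("empty method list")
  units <- attr(m, "units")
  lookup <- function(name) {
    if (name %in% colnames(m)) return(m[, name])
    if (!is.null(extra) && name %in% colnames(extra))
      return(extra[, name])
    stop("unknown method column: ", name)
  }
  desc <- data.frame(
    method = colnames(m),
    unit = if (!is.null(units)) units else NA_character_,
    n = nrow(m),
    mean = apply(m, 2, mean), sd = apply(m, 2, sd),
    min = apply(m, 2, min), max = apply(m, 2, max),
    row.names = NULL)
  paired <- lapply(pairs_to_test, function(p)
    c(list(x = p[1], y = p[2]), unclass(paired_compare(lookup(p[1]),
                                                       lookup(p[2])))))
  regs <- lapply(regressions_to_fit, function(p)
    c(list(predictor = p[1], response = p[2]),
      unclass(ols_with_diagnostics(lookup(p[1]), lookup(p[2])))))
  z <- zscore_columns(m[, rmanova_columns, drop = FALSE])
  structure(
    list(descriptives = desc, paired = paired, regressions = regs,
         rmanova = rmanova_gg(z), zscored = z),
    class = "method_report")
}
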