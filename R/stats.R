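# Core statistics: winsorisation, correlation, standardized OLS, and the a
# priori power computation. The JZS Bayes factor lives in bayes.R.

#' Winsorise a numeric vector at k standard deviations
#'
#' Clips values beyond `mean(x) +/- k * sd(x)` to that threshold, using the
#' mean and SD of the *original* vector (one pass, no re-estimation after
#' clipping). Missing values pass through untouched; a vector with zero SD is
#' returned unchanged.
#'
#' @param x Numeric vector, length at least 2 (ignoring `NA`).
#' @param k Threshold in SD units; default 3.
#' @return The clipped vector, same length and `NA` pattern as `x`.
#' @export
#' @examples
#' winsorize(c(rnorm(20), 50))
winsorize <- function(x, k = 3) {
  check_scalar_number(k, "k", lower = 0)
  if (sum(!is.na(x)) < 2L) abort("need at least 2 non-missing values")
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x)
  pmin(pmax(x, m - k * s), m + k * s)
}

#' Pearson correlation with test
#'
#' Product-moment correlation on pairwise-complete cases, with the two-sided
#' p value from the t transform (df = n - 2). Wraps [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs.
#' @return One-row tibble with `r`, `df`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (sum(ok) < 3L) abort("need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("correlation undefined: zero variance",
          class = "facecue_degenerate_error")
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate),
    df = unname(ct$parameter),
    p = ct$p.value,
    n = sum(ok)
  )
}

#' Standardized multiple regression
#'
#' Z-scores the outcome and every predictor on the complete cases, fits
#' ordinary least squares, and reports the standardized coefficient (beta),
#' t statistic, residual degrees of freedom, and two-sided p value per
#' predictor. With a single predictor the beta equals the Pearson r.
#'
#' @param data A data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `std_ols`; use [tidy()] for the per-predictor
#'   effect table and [glance()] for model-level fit statistics.
#' @export
standardized_ols <- function(data, outcome, predictors) {
  stopifnot(is.data.frame(data), length(predictors) >= 1L)
  vars <- c(outcome, predictors)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(sprintf("missing columns: %s", paste(missing, collapse = ", ")),
          class = "facecue_schema_error")
  }
  d <- data[vars]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1L) {
    abort(sprintf("need more than %d complete cases, got %d", p + 1L, n))
  }
  sds <- vapply(d, sd, 1)
  if (sds[[outcome]] == 0) {
    abort("zero-variance outcome", class = "facecue_degenerate_error")
  }
  if (any(sds[predictors] == 0)) {
    abort("zero-variance predictor", class = "facecue_degenerate_error")
  }
  z <- as.data.frame(lapply(d, function(v) (v - mean(v)) / sd(v)))
  x_mat <- as.matrix(z[predictors])
  if (qr(cbind(1, x_mat))$rank < p + 1L) {
    abort("rank-deficient design: predictors are collinear",
          class = "facecue_degenerate_error")
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- lm(fml, data = z)
  sm <- summary(fit)
  co <- sm$coefficients[predictors, , drop = FALSE]
  df <- n - p - 1L
  results <- tibble::tibble(
    outcome = outcome,
    term = predictors,
    beta = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    t = unname(co[, "t value"]),
    df = df,
    p = unname(co[, "Pr(>|t|)"]),
    n = n
  )
  structure(
    list(results = results, fit = fit, outcome = outcome,
         predictors = predictors, n = n, df = df,
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma),
    class = "std_ols"
  )
}

#' @export
print.std_ols <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s ~ %s  (n = %d, R2 = %.4f)\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              x$n, x$r_squared))
  print(x$results)
  invisible(x)
}

#' Required sample size for a regression coefficient test
#'
#' Smallest total N at which a test of one model term reaches the target
#' power, where the test statistic follows a noncentral F distribution with
#' `df1` numerator and `N - n_predictors - 1` denominator degrees of freedom
#' and noncentrality `f2 * N`. Found by iterating N upward.
#'
#' @param f2 Cohen's f-squared effect size of the tested term (> 0);
#'   f2 = 0.027 is a small effect.
#' @param power Target power, in (0, 1); default 0.80.
#' @param alpha Significance level; default 0.05.
#' @param df1 Numerator degrees of freedom of the tested term; default 1
#'   (a single coefficient).
#' @param n_predictors Total predictors in the model; default 2.
#' @param n_max Search cap; exceeding it raises an error.
#' @return The smallest integer N attaining the power.
#' @export
#' @examples
#' required_n(f2 = 0.027, power = 0.80, alpha = 0.05, df1 = 1)  # 293
required_n <- function(f2, power = 0.80, alpha = 0.05, df1 = 1L,
                       n_predictors = 2L, n_max = 1e6L) {
  check_scalar_number(f2, "f2", lower = .Machine$double.eps)
  check_scalar_number(power, "power", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (df1 < 1L) abort("df1 must be >= 1")
  for (n in seq.int(n_predictors + 2L, n_max)) {
    df2 <- n - n_predictors - 1L
    crit <- qf(1 - alpha, df1, df2)
    pw <- pf(crit, df1, df2, ncp = f2 * n, lower.tail = FALSE)
    if (pw >= power) return(n)
  }
  abort(sprintf("power %.2f not attainable for f2 = %g below N = %d",
                power, f2, n_max),
        class = "facecue_power_error")
}
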