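# Default (JZS / Zellner-Siow) Bayes factors for regression effects.
#
# For a linear model with n observations, p standardized predictors, and
# coefficient of determination R2, the Bayes factor of the model against the
# intercept-only null under the Zellner-Siow prior (a Cauchy prior with scale
# `prior_scale` on standardized slopes, equivalently g ~ InverseGamma(1/2,
# n * prior_scale^2 / 2) in a g-prior) is the one-dimensional integral
#
#   BF = Int_0^Inf (1+g)^((n-1-p)/2) * (1 + g(1-R2))^(-(n-1)/2) * pi(g) dg,
#   pi(g) = (n s^2 / 2)^(1/2) / Gamma(1/2) * g^(-3/2) * exp(-n s^2 / (2 g)).
#
# The integral is evaluated on the log-g scale, shifted by the mode of the
# log integrand for numerical stability, with adaptive quadrature.

log1pe <- function(x) ifelse(x > 33, x, log1p(exp(x)))

jzs_log_integrand <- function(log_g, n, p, r2, prior_scale) {
  0.5 * log(n * prior_scale^2 / 2) - lgamma(0.5) -
    0.5 * log_g - n * prior_scale^2 / 2 * exp(-log_g) +
    ((n - 1 - p) / 2) * log1pe(log_g) -
    ((n - 1) / 2) * log1pe(log_g + log1p(-r2))
}

#' JZS Bayes factor of a regression model against the intercept-only null
#'
#' @param n Number of observations.
#' @param p Number of predictors (0 returns 1: the model is the null).
#' @param r2 Coefficient of determination of the model.
#' @param prior_scale Scale of the Zellner-Siow Cauchy prior on standardized
#'   slopes; the default `sqrt(2)/2` is the conventional "medium" setting.
#' @return The Bayes factor (model over intercept-only), a positive number.
#' @seealso [jzs_bf()] for the effect-level (inclusion) Bayes factor.
#' @export
jzs_bf_r2 <- function(n, p, r2, prior_scale = sqrt(2) / 2) {
  check_scalar_number(n, "n", lower = 3)
  check_scalar_number(r2, "r2", lower = 0, upper = 1 - 1e-12)
  check_scalar_number(prior_scale, "prior_scale", lower = 1e-9)
  if (p == 0L) return(1)
  if (n - 1 - p <= 0) abort("need n > p + 1")
  f <- function(lg) jzs_log_integrand(lg, n, p, r2, prior_scale)
  opt <- optimize(function(lg) -f(lg), interval = c(-45, 45))
  m <- -opt$objective
  quad <- tryCatch(
    integrate(function(lg) exp(f(lg) - m), -Inf, Inf,
              rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L),
    error = function(e) e
  )
  if (inherits(quad, "error") || quad$message != "OK") {
    msg <- if (inherits(quad, "error")) conditionMessage(quad) else quad$message
    abort(sprintf(
      "Bayes-factor quadrature did not converge (n=%d, p=%d, R2=%.4g): %s",
      n, p, r2, msg
    ), class = "facecue_bf_error")
  }
  exp(m + log(quad$value))
}

#' Effect-level JZS Bayes factor for one focal predictor
#'
#' Evidence for including the focal predictor: the ratio of the JZS Bayes
#' factor (against the intercept-only null) of the full model to that of the
#' model omitting the focal predictor, both fitted on the same complete
#' cases. Values above 1 favour inclusion; values below 1 favour the null.
#'
#' @inheritParams standardized_ols
#' @param focal Name of the focal predictor (must be in `predictors`).
#' @param prior_scale Zellner-Siow prior scale; default `sqrt(2)/2`.
#' @return The Bayes factor `bf10` as a single positive number.
#' @export
jzs_bf <- function(data, outcome, predictors, focal,
                   prior_scale = sqrt(2) / 2) {
  if (!focal %in% predictors) {
    abort(sprintf("focal predictor `%s` is not among the predictors", focal))
  }
  vars <- c(outcome, predictors)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(sprintf("missing columns: %s", paste(missing, collapse = ", ")),
          class = "facecue_schema_error")
  }
  d <- data[vars]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p_full <- length(predictors)
  if (n <= p_full + 1L) abort("too few complete cases")
  r2_of <- function(preds) {
    if (length(preds) == 0L) return(0)
    fit <- lm(stats::reformulate(preds, response = outcome), data = d)
    summary(fit)$r.squared
  }
  reduced <- setdiff(predictors, focal)
  bf_full <- jzs_bf_r2(n, p_full, r2_of(predictors), prior_scale)
  bf_reduced <- jzs_bf_r2(n, length(reduced), r2_of(reduced), prior_scale)
  bf_full / bf_reduced
}
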