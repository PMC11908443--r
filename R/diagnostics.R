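#' Regress observed on predicted values
#'
#' Ordinary least squares of observed heights (or biomass) on model
#' predictions. A well-calibrated model gives intercept 0 and slope 1; the
#' joint hypothesis is tested by [graybill_test()] and the squared-error
#' partition by [theil_decomposition()].
#'
#' @param obs Observed values.
#' @param pred Predicted values, same length (>= 3).
#' @return An `obs_pred_reg` object with `intercept`, `slope`, their standard
#'   errors, `mse` (residual mean square), `n` and the underlying `lm` fit.
#' @export
obs_vs_pred <- function(obs, pred) {
  if (length(obs) != length(pred)) abort("`obs` and `pred` must have equal length.")
  if (length(obs) < 3) abort("At least 3 observation pairs are required.")
  check_numeric(obs, "obs"); check_numeric(pred, "pred")
  if (sd(pred) == 0) abort("`pred` has zero variance; regression is degenerate.")
  fit <- lm(obs ~ pred)
  sm <- summary(fit)
  structure(list(
    intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    intercept_se = sm$coefficients[1, 2], slope_se = sm$coefficients[2, 2],
    mse = sm$sigma^2, n = length(obs), lm = fit,
    obs = obs, pred = pred
  ), class = "obs_pred_reg")
}

#' @export
print.obs_pred_reg <- function(x, ...) {
  cat(sprintf("<obs_pred_reg> n = %d: obs = %.4g + %.4g * pred (residual MS %.4g)\n",
              x$n, x$intercept, x$slope, x$mse))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.obs_pred_reg <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std_error = c(x$intercept_se, x$slope_se))
}

#' Graybill's joint F test of intercept 0 and slope 1
#'
#' Simultaneous test of H0: (intercept, slope) = (0, 1) in the
#' observed-versus-predicted regression,
#' `F = (b - theta)' X'X (b - theta) / (2 MSE)` against `F(2, n - 2)`.
#' Rejection means predictions deviate systematically from the 1:1 line.
#'
#' @param reg An `obs_pred_reg` from [obs_vs_pred()], or can be called as
#'   `graybill_test(obs, pred)` with two numeric vectors.
#' @param pred Optional; predicted values when `reg` is the observed vector.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
graybill_test <- function(reg, pred = NULL) {
  if (!inherits(reg, "obs_pred_reg")) reg <- obs_vs_pred(reg, pred)
  X <- cbind(1, reg$pred)
  d <- c(reg$intercept - 0, reg$slope - 1)
  mse <- reg$mse
  stat <- if (mse <= 0) {
    if (sum(d^2) < 1e-12) 0 else Inf
  } else {
    drop(t(d) %*% crossprod(X) %*% d) / (2 * mse)
  }
  df2 <- reg$n - 2
  tibble(statistic = stat, df1 = 2, df2 = df2,
         p_value = pf(stat, 2, df2, lower.tail = FALSE))
}

#' Theil's decomposition of squared prediction error
#'
#' Partitions the total squared prediction error `sum((obs - pred)^2)` into
#' three exactly additive components, each named as in model-validation
#' practice:
#' \describe{
#'   \item{bias ("no bias")}{`n (mean(obs) - mean(pred))^2` - departure of the
#'     intercept from zero}
#'   \item{consistency}{`(slope - 1)^2 sum((pred - mean(pred))^2)` - departure
#'     of the slope from one}
#'   \item{regression lack-of-fit}{the residual SS of the obs-on-pred OLS -
#'     scatter (including non-linear deviation) about the fitted line}
#' }
#' The bias and consistency components are F-tested (1 numerator df) against
#' the regression residual mean square. "Model lack-of-fit" is the test on the
#' total, `F = (SS_total/n) / MSE` with `(n, n - 2)` df. Because a 1-df F test
#' of the residual SS against its own mean square is vacuous, the p-value
#' attached to the regression lack-of-fit component comes from a curvature
#' test: the F test of a quadratic term added to the obs-on-pred regression.
#'
#' @inheritParams obs_vs_pred
#' @return Tibble with one row per component (`model_lack_of_fit`, `bias`,
#'   `consistency`, `regression_lack_of_fit`): `ss`, `statistic`, `df1`,
#'   `df2`, `p_value`. The last three `ss` sum to the first.
#' @export
theil_decomposition <- function(obs, pred) {
  if (length(obs) != length(pred)) abort("`obs` and `pred` must have equal length.")
  n <- length(obs)
  if (n <= 3) abort("Theil's decomposition needs more than 3 pairs.")
  reg <- obs_vs_pred(obs, pred)
  ss_total <- sum((obs - pred)^2)
  ss_bias <- n * (mean(obs) - mean(pred))^2
  sxx <- sum((pred - mean(pred))^2)
  ss_consistency <- (reg$slope - 1)^2 * sxx
  ss_reg <- sum(residuals(reg$lm)^2)
  mse <- ss_reg / (n - 2)

  f_of <- function(ss, df1) {
    if (mse <= 0) {
      stat <- if (ss < 1e-12) 0 else Inf
    } else {
      stat <- (ss / df1) / mse
    }
    c(stat, pf(stat, df1, n - 2, lower.tail = FALSE))
  }
  tot <- f_of(ss_total, n)
  bia <- f_of(ss_bias, 1)
  con <- f_of(ss_consistency, 1)

  # curvature test for non-linear deviation about the fitted line
  quad <- lm(obs ~ pred + I(pred^2))
  sse_q <- sum(residuals(quad)^2)
  if (n > 3 && sse_q > 0 && (ss_reg - sse_q) >= 0) {
    f_curv <- (ss_reg - sse_q) / (sse_q / (n - 3))
    p_curv <- pf(f_curv, 1, n - 3, lower.tail = FALSE)
  } else {
    f_curv <- 0; p_curv <- 1
  }

  tibble(
    component = c("model_lack_of_fit", "bias", "consistency",
                  "regression_lack_of_fit"),
    ss = c(ss_total, ss_bias, ss_consistency, ss_reg),
    statistic = c(tot[1], bia[1], con[1], f_curv),
    df1 = c(n, 1, 1, 1),
    df2 = c(n - 2, n - 2, n - 2, n - 3),
    p_value = c(tot[2], bia[2], con[2], p_curv)
  )
}

#' @importFrom stats residuals
NULL
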