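#' Fit a height-diameter model by nonlinear least squares
#'
#' Minimises the residual sum of squares of measured height on the
#' untransformed height scale (every candidate form carries additive error)
#' with the Levenberg-Marquardt algorithm, starting from deterministic
#' data-driven initial values and restarting from jittered starts on
#' non-convergence. Parameter standard errors come from the Gauss-Newton
#' approximation to the Hessian at the optimum.
#'
#' @param data Tibble with `dbh` (cm) and `height` (m) columns; rows with
#'   missing height are dropped.
#' @param model Model name (see [hd_models()]) or an `hd_model_spec`.
#' @param min_dbh Optional minimum DBH (cm) filter applied before fitting.
#' @param options Fit options from [fit_options()].
#' @return An `hd_fit` object. Use [tidy()] for coefficients, [glance()] for
#'   fit statistics (`rse`, `adj_pseudo_r2`, `aic`), [predict_height()] for
#'   predictions and [autoplot()] to plot the curve over the data.
#' @export
#' @examples
#' sim <- generate_stand(stand_preset("varzea_like", n_trees = 300, seed = 1))
#' fit <- fit_hd(sim$data, "michaelis_menten")
#' glance(fit)
fit_hd <- function(data, model, min_dbh = NULL, options = fit_options()) {
  spec <- if (inherits(model, "hd_model_spec")) model else hd_model(model)
  check_columns(data, c("dbh", "height"), "fit_hd")
  keep <- !is.na(data$dbh) & !is.na(data$height)
  if (!is.null(min_dbh)) keep <- keep & data$dbh >= min_dbh
  dbh <- data$dbh[keep]
  height <- data$height[keep]
  n <- length(dbh)
  if (n < spec$arity + 2) {
    abort(sprintf("Fitting '%s' needs at least %d trees with DBH and height; got %d.",
                  spec$name, spec$arity + 2, n))
  }
  if (any(height <= 0)) abort("All heights must be strictly positive.")
  if (sd(height) == 0) {
    abort("Heights are constant; the height-diameter relationship is degenerate.")
  }

  start <- spec$start(dbh, height)
  resid_fn <- function(p) height - spec$fn(p, dbh)
  jac_fn <- function(p) -spec$grad(p, dbh) # residual Jacobian

  run_lm <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = options$max_iter, ptol = options$tol, ftol = options$tol^2)
      ),
      error = function(e) NULL
    )
  }

  is_ok <- function(res) {
    !is.null(res) && res$info %in% 1:4 && all(is.finite(unlist(res$par)))
  }

  best <- run_lm(start)
  if (!is_ok(best) || best$deviance > sum((height - mean(height))^2)) {
    # jittered restarts, reproducible under the options seed
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(options$seed)
    for (i in seq_len(options$restarts)) {
      jitter <- exp(rnorm(spec$arity, 0, 0.25))
      cand <- run_lm(start * jitter)
      if (is_ok(cand) && (!is_ok(best) || cand$deviance < best$deviance)) best <- cand
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  if (is.null(best)) {
    return(new_hd_fit(spec, params = setNames(rep(NA_real_, spec$arity), names(start)),
                      param_se = NULL, dbh = dbh, height = height,
                      converged = FALSE, message = "optimizer failed"))
  }
  params <- setNames(as.numeric(best$par), names(start))
  converged <- is_ok(best)
  se <- tryCatch({
    J <- spec$grad(params, dbh)
    sigma2 <- best$deviance / (n - spec$arity)
    sqrt(diag(sigma2 * solve(crossprod(J))))
  }, error = function(e) rep(NA_real_, spec$arity))
  new_hd_fit(spec, params, setNames(se, names(start)), dbh, height,
             converged = converged, message = best$message)
}

jacobian_fd <- function(f, p, eps = 1e-7) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

new_hd_fit <- function(spec, params, param_se, dbh, height, converged, message = "") {
  n <- length(dbh)
  k <- spec$arity
  if (converged) {
    fitted <- spec$fn(params, dbh)
    residuals <- height - fitted
    sse <- sum(residuals^2)
    sst <- sum((height - mean(height))^2)
    rse <- sqrt(sse / (n - k))
    r2 <- 1 - sse / sst
  } else {
    fitted <- residuals <- rep(NA_real_, n)
    sse <- sst <- rse <- r2 <- NA_real_
  }
  fit <- structure(
    list(spec = spec, params = params, param_se = param_se,
         n = n, k = k, sse = sse, sst = sst, rse = rse, r2 = r2,
         fitted = fitted, residuals = residuals,
         data = tibble(dbh = dbh, height = height),
         converged = converged, message = message),
    class = "hd_fit"
  )
  fit$adj_pseudo_r2 <- if (converged) adj_pseudo_r2(fit) else NA_real_
  fit$aic <- if (converged) hd_aic(fit) else NA_real_
  fit
}

#' @export
print.hd_fit <- function(x, ...) {
  cat(sprintf("<hd_fit> %s, n = %d%s\n", x$spec$name, x$n,
              if (!x$converged) " (NOT converged)" else ""))
  if (x$converged) {
    cat("  params:", paste(sprintf("%s = %.5g", names(x$params), x$params),
                           collapse = ", "), "\n")
    cat(sprintf("  RSE = %.4g m, adj. pseudo-R2 = %.4g, AIC = %.6g\n",
                x$rse, x$adj_pseudo_r2, x$aic))
  }
  invisible(x)
}

#' Nonlinear fit options
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Convergence tolerance on relative parameter change. The tight
#'   default lets linear special cases (log-linear) reproduce their
#'   closed-form least-squares solution to 1e-8.
#' @param restarts Number of jittered restarts attempted on non-convergence.
#' @param seed Seed for the restart jitter (restarts are reproducible).
#' @return List of options for [fit_hd()].
#' @export
fit_options <- function(max_iter = 300, tol = 1e-10, restarts = 5, seed = 1) {
  list(max_iter = max_iter, tol = tol, restarts = restarts, seed = seed)
}

#' Akaike information criterion of a height-diameter fit
#'
#' `AIC = 2k - 2 ln L` with the Gaussian likelihood of the residuals,
#' `ln L = -n/2 (ln 2pi + ln(SSE/n) + 1)`. By default `k` counts the
#' regression parameters plus the error variance (the convention of
#' mainstream statistical software); set `count_sigma = FALSE` to count
#' regression parameters only.
#'
#' @param fit A converged `hd_fit`.
#' @param count_sigma Include the error variance in the parameter count?
#' @return AIC (unitless).
#' @export
hd_aic <- function(fit, count_sigma = TRUE) {
  if (!fit$converged) abort("AIC is undefined for a non-converged fit.")
  k <- fit$k + if (count_sigma) 1L else 0L
  n <- fit$n
  loglik <- -n / 2 * (log(2 * pi) + log(fit$sse / n) + 1)
  2 * k - 2 * loglik
}

#' Adjusted pseudo-R-squared of a height-diameter fit
#'
#' `R2 = 1 - SSE/SST` (SST about the mean height), adjusted for the number of
#' regression parameters K: `R2_adj = R2 - ((K - 1)/(N - K)) (1 - R2)`.
#'
#' @param fit A converged `hd_fit`.
#' @return Adjusted pseudo-R-squared (unitless).
#' @export
adj_pseudo_r2 <- function(fit) {
  if (!fit$converged) abort("Adjusted pseudo-R2 is undefined for a non-converged fit.")
  if (fit$sst == 0) abort("Heights are constant (SST = 0); R2 is degenerate.")
  r2 <- fit$r2
  r2 - ((fit$k - 1) / (fit$n - fit$k)) * (1 - r2)
}

#' @exportS3Method generics::tidy
tidy.hd_fit <- function(x, ...) {
  tibble(
    model = x$spec$name,
    term = names(x$params),
    estimate = as.numeric(x$params),
    std_error = if (is.null(x$param_se)) NA_real_ else as.numeric(x$param_se)
  )
}

#' @exportS3Method generics::glance
glance.hd_fit <- function(x, ...) {
  tibble(
    model = x$spec$name, n = x$n, k = x$k,
    rse = x$rse, adj_pseudo_r2 = x$adj_pseudo_r2, aic = x$aic,
    converged = x$converged
  )
}

#' Fit all (or a subset of) candidate height-diameter models
#'
#' @inheritParams fit_hd
#' @param models Character vector of model names; defaults to all ten.
#' @return Tibble with one row per model: selection statistics plus the fit
#'   object in the `fit` list-column. Pass to [rank_hd_models()].
#' @export
fit_hd_models <- function(data, models = hd_models()$name, min_dbh = NULL,
                          options = fit_options()) {
  fits <- purrr::map(models, function(m) {
    tryCatch(fit_hd(data, m, min_dbh = min_dbh, options = options),
             error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) abort("No model could be fitted to these data.")
  fits <- fits[keep]
  out <- purrr::map_dfr(fits, glance)
  out$fit <- fits
  out
}

#' Rank fitted height-diameter models
#'
#' Ranks lexicographically: adjusted pseudo-R-squared descending, then RSE
#' ascending, then AIC ascending. Non-converged fits are ranked last and kept
#' visible (never silently dropped).
#'
#' @param fits Tibble from [fit_hd_models()], or a list of `hd_fit` objects.
#' @return The input tibble arranged by rank, with a `rank` column prepended.
#' @export
rank_hd_models <- function(fits) {
  if (!is.data.frame(fits)) {
    if (length(fits) == 0) abort("`fits` is empty; nothing to rank.")
    tbl <- purrr::map_dfr(fits, glance)
    tbl$fit <- fits
    fits <- tbl
  }
  if (nrow(fits) == 0) abort("`fits` is empty; nothing to rank.")
  fits$rank <- NULL # re-ranking an already-ranked table is fine
  ord <- order(!fits$converged,
               -ifelse(is.na(fits$adj_pseudo_r2), -Inf, fits$adj_pseudo_r2),
               ifelse(is.na(fits$rse), Inf, fits$rse),
               ifelse(is.na(fits$aic), Inf, fits$aic))
  out <- fits[ord, ]
  dplyr::bind_cols(tibble(rank = seq_len(nrow(out))), out)
}

#' Export a model-selection table
#'
#' Writes a CSV with one row per parameter (model, parameter, estimate,
#' standard error) alongside each model's RSE, adjusted pseudo-R-squared and
#' AIC, mirroring the conventional layout of height-model selection tables.
#'
#' @param ranked Result of [rank_hd_models()].
#' @param path Optional CSV path; when `NULL` only the tibble is returned.
#' @return The long-format tibble, invisibly when `path` is given.
#' @export
hd_selection_table <- function(ranked, path = NULL) {
  out <- purrr::map_dfr(seq_len(nrow(ranked)), function(i) {
    fit <- ranked$fit[[i]]
    td <- tidy(fit)
    tibble(
      rank = ranked$rank[i], model = td$model, parameter = td$term,
      estimate = td$estimate, se = td$std_error,
      rse = fit$rse, adj_pseudo_r2 = fit$adj_pseudo_r2, aic = fit$aic,
      n = fit$n, converged = fit$converged
    )
  })
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}
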