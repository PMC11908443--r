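#' Total, systematic and random estimation error
#'
#' Decomposes per-tree estimation errors `est - meas` into:
#' \describe{
#'   \item{TE}{total error, the root mean square error
#'     `sqrt(mean((est - meas)^2))`}
#'   \item{SE}{systematic error, the signed mean error `mean(est - meas)`}
#'   \item{RE}{random error, the sample standard deviation of the errors
#'     (denominator `n - 1`)}
#' }
#' and, because absolute errors grow with tree size, the same three metrics on
#' per-observation proportional errors `(est - meas)/meas` (CVTE, CVSE, CVRE).
#' Proportional errors are computed per tree and then aggregated, never as a
#' ratio of aggregates. The three metrics obey the algebraic identity
#' `TE^2 = SE^2 + ((n - 1)/n) RE^2`.
#'
#' @param est Estimated values (heights in m, or biomass in kg).
#' @param meas Measured (reference) values, same length and units; must be
#'   strictly positive for the proportional metrics.
#' @param size_class Label attached to the summary row.
#' @return One-row tibble: `size_class`, `n`, `te`, `se`, `re`, `cvte`,
#'   `cvse`, `cvre`. With `n = 1`, `re` and `cvre` are `NA` (undefined, not
#'   zero); with `n = 0` every metric is `NA`.
#' @export
#' @examples
#' error_summary(est = c(11, 22), meas = c(10, 20)) # CVSE 0.10, CVRE 0
error_summary <- function(est, meas, size_class = "all") {
  if (length(est) != length(meas)) {
    abort("`est` and `meas` must have the same length.")
  }
  n <- length(est)
  if (n == 0) {
    return(tibble(size_class = size_class, n = 0L, te = NA_real_, se = NA_real_,
                  re = NA_real_, cvte = NA_real_, cvse = NA_real_, cvre = NA_real_))
  }
  check_numeric(est, "est"); check_numeric(meas, "meas")
  if (any(meas <= 0)) {
    abort("`meas` must be strictly positive for the proportional error metrics.")
  }
  err <- est - meas
  rel <- err / meas
  te <- sqrt(mean(err^2))
  se <- mean(err)
  re <- if (n >= 2) sqrt(sum((err - se)^2) / (n - 1)) else NA_real_
  cvte <- sqrt(mean(rel^2))
  cvse <- mean(rel)
  cvre <- if (n >= 2) sqrt(sum((rel - cvse)^2) / (n - 1)) else NA_real_
  tibble(size_class = size_class, n = n, te = te, se = se, re = re,
         cvte = cvte, cvse = cvse, cvre = cvre)
}

#' Error summaries stratified by tree-size class
#'
#' Splits trees into DBH classes at the given breakpoints (half-open
#' intervals `[low, high)`) and returns one [error_summary()] row per class
#' plus an `"all"` row. The default single breakpoint at 30 cm separates
#' "small" from "large" trees.
#'
#' @param data Inventory tibble with a `dbh` column (and the measured values
#'   when `meas` is a column name).
#' @param est Estimated values, one per row of `data`.
#' @param meas Measured values, one per row of `data`; defaults to
#'   `data$height`.
#' @param breaks Strictly increasing DBH breakpoints (cm); `numeric(0)` for a
#'   single "all" summary.
#' @return Tibble of error summaries, one row per size class plus `"all"`.
#' @export
stratified_errors <- function(data, est, meas = data$height, breaks = 30) {
  check_columns(data, "dbh", "stratified_errors")
  if (length(est) != nrow(data) || length(meas) != nrow(data)) {
    abort("`est` and `meas` must have one value per row of `data`.")
  }
  breaks <- sort(unique(breaks))
  if (length(breaks) > 0 && any(diff(breaks) <= 0)) {
    abort("`breaks` must be strictly increasing.")
  }
  keep <- !is.na(est) & !is.na(meas)
  data <- data[keep, ]; est <- est[keep]; meas <- meas[keep]
  edges <- c(0, breaks, Inf)
  out <- purrr::map_dfr(seq_len(length(edges) - 1), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    inside <- data$dbh >= lo & data$dbh < hi
    label <- if (is.infinite(hi)) sprintf("[%g, Inf)", lo) else sprintf("[%g, %g)", lo, hi)
    error_summary(est[inside], meas[inside], size_class = label)
  })
  if (length(breaks) == 0) {
    return(error_summary(est, meas, size_class = "all"))
  }
  dplyr::bind_rows(out, error_summary(est, meas, size_class = "all"))
}

#' Compare local and published height models against measured heights
#'
#' For each fitted local model and each requested published model, predicts
#' height for every tree and summarises estimation errors by size class
#' (Eqs for TE/SE/RE and their proportional analogues). The best local model
#' according to [rank_hd_models()] is flagged in the output.
#'
#' @param data Inventory tibble with `dbh` and measured `height`.
#' @param fits Tibble from [fit_hd_models()] (local fits), or `NULL`.
#' @param published Character vector of published model names (see
#'   [published_height_model()]), or `NULL`.
#' @param E Environmental-stress index for the pantropical model.
#' @param breaks DBH size-class breakpoints (cm).
#' @return Tibble of stratified error summaries with `model` and `best_local`
#'   columns, mirroring a TE/SE/RE x model x size-class comparison table.
#' @export
compare_height_models <- function(data, fits = NULL,
                                  published = c("guyana_shield", "pantropical"),
                                  E = NULL, breaks = 30) {
  check_columns(data, c("dbh", "height"), "compare_height_models")
  if (all(is.na(data$height))) abort("Measured heights are required for comparison.")
  rows <- list()
  best <- NA_character_
  if (!is.null(fits) && nrow(fits) > 0) {
    ranked <- rank_hd_models(fits)
    best <- ranked$model[1]
    for (i in seq_len(nrow(ranked))) {
      fit <- ranked$fit[[i]]
      if (!fit$converged) next
      est <- predict_height(fit, data$dbh)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        stratified_errors(data, est, data$height, breaks),
        model = fit$spec$name, .before = 1)
    }
  }
  for (pm in published %||% character(0)) {
    model <- published_height_model(pm)
    if (model$requires_E && is.null(E)) {
      abort(sprintf("Model '%s' requires `E`.", pm))
    }
    est <- predict_height(model, data$dbh, E = E)
    rows[[length(rows) + 1]] <- dplyr::mutate(
      stratified_errors(data, est, data$height, breaks),
      model = pm, .before = 1)
  }
  if (length(rows) == 0) abort("Nothing to compare: supply `fits` and/or `published`.")
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, best_local = .data$model == best)
}
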