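#' Log-bias correction factor
#'
#' Regressions fitted on log-transformed biomass underestimate biomass when
#' back-transformed; the standard remedy multiplies predictions by
#' `CF = exp(RSE^2 / 2)` where RSE is the residual standard error of the
#' log-scale regression.
#'
#' @param rse Log-scale residual standard error (>= 0).
#' @return The multiplicative correction factor (>= 1).
#' @export
#' @examples
#' correction_factor(0.394) # ~1.0807
correction_factor <- function(rse) {
  check_numeric(rse, "rse")
  if (any(rse < 0)) abort("`rse` must be non-negative.")
  exp(rse^2 / 2)
}

#' Registry of aboveground biomass equations
#'
#' Six published allometric equations for tree aboveground biomass (kg per
#' tree), as pairs with and without height for each setting:
#' \describe{
#'   \item{tf_H}{terra-firme, with height:
#'     `AGB = exp(-3.04385 + 0.94863 ln(D^2 H)) x 1.08071`}
#'   \item{tf_D}{terra-firme, diameter only:
#'     `AGB = exp(-1.91172 + 2.45043 ln D) x 1.094052`}
#'   \item{varzea_H}{varzea (moist forest), with height and wood density:
#'     `AGB = exp(-3.027 + ln(rho D^2 H)) x 1.051195`}
#'   \item{varzea_D}{varzea, diameter and density:
#'     `AGB = rho exp(-1.349 + 1.980 ln D + 0.207 (ln D)^2 - 0.0281 (ln D)^3) x 1.065419`}
#'   \item{chave_H}{pantropical, with height and density:
#'     `AGB = 0.0673 (rho D^2 H)^0.976`}
#'   \item{chave_D}{pantropical, diameter, density and stress index E:
#'     `AGB = exp(-1.803 - 0.976 E + 0.976 ln(rho) + 2.673 ln D - 0.0299 (ln D)^2) x 1.089027`}
#' }
#' The trailing multiplicative constants are the printed log-bias correction
#' factors ([correction_factor()]). D is DBH in cm, H total height in m, rho
#' wood density in g cm^-3.
#'
#' @return Tibble: `id`, `uses_height`, `uses_density`, `uses_E`,
#'   `correction_factor`.
#' @seealso [tree_agb()]
#' @export
biomass_equations <- function() {
  tibble(
    id = c("tf_H", "tf_D", "varzea_H", "varzea_D", "chave_H", "chave_D"),
    uses_height = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    uses_density = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    uses_E = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    correction_factor = c(1.08071, 1.094052, 1.051195, 1.065419, 1, 1.089027)
  )
}

agb_eval <- function(id, dbh, height, rho, E, strict = FALSE) {
  l <- log(dbh)
  switch(id,
    tf_H = exp(-3.04385 + 0.94863 * log(dbh^2 * height)) * 1.08071,
    tf_D = exp(-1.91172 + 2.45043 * l) * 1.094052,
    varzea_H = if (strict) {
      # literal printed (dimensionally incoherent) form, kept for audit
      -3.027 + log(rho * dbh^2 * height) * 1.051195
    } else {
      exp(-3.027 + log(rho * dbh^2 * height)) * 1.051195
    },
    varzea_D = rho * exp(-1.349 + 1.980 * l + 0.207 * l^2 - 0.0281 * l^3) * 1.065419,
    chave_H = 0.0673 * (rho * dbh^2 * height)^0.976,
    chave_D = exp(-1.8030 - 0.976 * E + 0.976 * log(rho) + 2.673 * l - 0.0299 * l^2) *
      1.089027,
    abort(sprintf("Unknown biomass equation '%s'.", id))
  )
}

#' Tree-level aboveground biomass
#'
#' Evaluates one of the six [biomass_equations()] per tree. Biomass is
#' conventionally computed only for stems with DBH >= 5 cm; smaller trees are
#' returned as `NA` with a message (a visible skip, so height models can still
#' be fitted on the full size range upstream).
#'
#' @param dbh DBH in cm (vector).
#' @param equation Equation id (see [biomass_equations()]).
#' @param height Total height in m; required by the `_H` equations.
#' @param rho Wood density in g cm^-3; required where `uses_density`.
#' @param E Environmental-stress index; required by `chave_D`.
#' @param min_dbh Inclusion threshold in cm (default 5).
#' @param strict For `varzea_H` only: evaluate the literal printed form
#'   instead of its exponentiated correction (see [biomass_equations()]).
#' @return Aboveground biomass in kg per tree (`NA` below `min_dbh`).
#' @export
#' @examples
#' tree_agb(10, "tf_H", height = 13) # ~46.3 kg
tree_agb <- function(dbh, equation, height = NULL, rho = NULL, E = NULL,
                     min_dbh = 5, strict = FALSE) {
  check_numeric(dbh, "dbh", positive = TRUE)
  eqs <- biomass_equations()
  if (!equation %in% eqs$id) {
    abort(sprintf("Unknown biomass equation '%s'. Available: %s.",
                  equation, paste(eqs$id, collapse = ", ")))
  }
  row <- eqs[eqs$id == equation, ]
  if (row$uses_height && is.null(height)) {
    abort(sprintf("Equation '%s' requires `height`.", equation))
  }
  if (row$uses_density && is.null(rho)) {
    abort(sprintf("Equation '%s' requires `rho` (wood density).", equation))
  }
  if (row$uses_E && is.null(E)) {
    abort(sprintf("Equation '%s' requires the environmental-stress index `E`.",
                  equation))
  }
  if (row$uses_height) check_numeric(height, "height", positive = TRUE)
  if (row$uses_density) check_numeric(rho, "rho", positive = TRUE)
  out <- agb_eval(equation, dbh, height, rho, E, strict = strict)
  small <- !is.na(dbh) & dbh < min_dbh
  if (any(small)) {
    inform(sprintf("Excluded %d tree%s with DBH < %g cm from biomass.",
                   sum(small), if (sum(small) > 1) "s" else "", min_dbh))
    out[small] <- NA_real_
  }
  out
}

resolve_heights <- function(data, height_source, fit = NULL, E = NULL) {
  switch(height_source,
    measured = {
      if (all(is.na(data$height))) abort("No measured heights in `data`.")
      data$height
    },
    local_fit = {
      if (is.null(fit)) abort("`height_source = \"local_fit\"` requires `fit`.")
      predict_height(fit, data$dbh)
    },
    guyana_shield = predict_height(published_height_model("guyana_shield"), data$dbh),
    pantropical = {
      if (is.null(E)) abort("The pantropical height model requires `E`.")
      predict_height(published_height_model("pantropical"), data$dbh, E = E)
    },
    none = NULL,
    abort(sprintf("Unknown height source '%s'.", height_source))
  )
}

per_tree_agb <- function(data, equation, height_source, fit, E, min_dbh = 5,
                         quiet = TRUE) {
  row <- biomass_equations()[biomass_equations()$id == equation, ]
  h <- resolve_heights(data, height_source, fit, E)
  rho <- if (row$uses_density) {
    if (!"wood_density" %in% names(data) || any(is.na(data$wood_density))) {
      abort(sprintf("Equation '%s' requires a resolved `wood_density` column (see `assign_wood_density()`).",
                    equation))
    }
    data$wood_density
  } else NULL
  f <- function() tree_agb(data$dbh, equation, height = h, rho = rho, E = E,
                           min_dbh = min_dbh)
  if (quiet) suppressMessages(f()) else f()
}

#' Plot-level aboveground biomass
#'
#' Computes per-tree biomass with the chosen equation and height source, sums
#' it per plot, and scales by plot area to Mg per hectare. When the inventory
#' carries per-tree `expansion_factor` weights from a size-stratified sampling
#' design, each tree contributes `AGB x expansion_factor` to the plot total.
#'
#' @inheritParams tree_agb
#' @param data Inventory tibble (with `plot_id`, `dbh`, and as needed
#'   `height`, `wood_density`, `expansion_factor`).
#' @param height_source One of `"measured"`, `"local_fit"`, `"guyana_shield"`,
#'   `"pantropical"`, `"none"` (for diameter-only equations).
#' @param fit An `hd_fit`, required when `height_source = "local_fit"`.
#' @param plot_areas Named numeric vector, plot id -> area in ha.
#' @return Tibble with one row per plot: `plot_id`, `n_trees` (included),
#'   `agb_total_mg`, `agb_mg_ha`.
#' @export
plot_biomass <- function(data, equation, height_source = "measured", fit = NULL,
                         E = NULL, plot_areas, min_dbh = 5) {
  check_columns(data, c("plot_id", "dbh"), "plot_biomass")
  agb <- per_tree_agb(data, equation, height_source, fit, E, min_dbh)
  ef <- if ("expansion_factor" %in% names(data)) data$expansion_factor else
    rep(1, nrow(data))
  plots <- unique(data$plot_id)
  missing <- setdiff(plots, names(plot_areas))
  if (length(missing) > 0) {
    abort(sprintf("No area given for plot%s %s.",
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  d <- tibble(plot_id = data$plot_id, agb = agb, ef = ef)
  d <- dplyr::filter(d, !is.na(.data$agb))
  out <- dplyr::summarise(dplyr::group_by(d, .data$plot_id),
                          n_trees = dplyr::n(),
                          agb_total_mg = sum(.data$agb * .data$ef) / 1000,
                          .groups = "drop")
  out$agb_mg_ha <- out$agb_total_mg / unname(plot_areas[out$plot_id])
  out
}

#' Cumulative biomass across tree-size classes
#'
#' Mean per-hectare biomass accumulated over DBH classes (default 10-cm bins),
#' the standard way to visualise where a height source gains or loses biomass
#' relative to measured heights.
#'
#' @inheritParams plot_biomass
#' @param bin_width DBH class width in cm.
#' @return Tibble: `dbh_class_upper` (cm), `agb_mg_ha` (class contribution,
#'   averaged over plots), `agb_cum_mg_ha` (non-decreasing; its last value is
#'   the stand total per ha).
#' @export
cumulative_biomass <- function(data, equation, height_source = "measured",
                               fit = NULL, E = NULL, plot_areas,
                               bin_width = 10, min_dbh = 5) {
  check_columns(data, c("plot_id", "dbh"), "cumulative_biomass")
  agb <- per_tree_agb(data, equation, height_source, fit, E, min_dbh)
  ef <- if ("expansion_factor" %in% names(data)) data$expansion_factor else
    rep(1, nrow(data))
  area <- unname(plot_areas[as.character(data$plot_id)])
  if (any(is.na(area))) abort("Every plot needs an area entry in `plot_areas`.")
  n_plots <- length(unique(data$plot_id))
  keep <- !is.na(agb)
  d <- tibble(dbh = data$dbh[keep],
              contrib = agb[keep] * ef[keep] / 1000 / area[keep] / n_plots)
  upper <- bin_width * ceiling(max(d$dbh) / bin_width)
  edges <- seq(0, upper, by = bin_width)
  d$class_upper <- edges[findInterval(d$dbh, edges, left.open = FALSE,
                                      rightmost.closed = TRUE) + 1]
  out <- dplyr::summarise(dplyr::group_by(d, .data$class_upper),
                          agb_mg_ha = sum(.data$contrib), .groups = "drop")
  out <- dplyr::arrange(out, .data$class_upper)
  tibble(dbh_class_upper = out$class_upper,
         agb_mg_ha = out$agb_mg_ha,
         agb_cum_mg_ha = cumsum(out$agb_mg_ha))
}

#' Compare biomass across height sources against measured-height biomass
#'
#' The reference is per-tree biomass computed from measured heights with the
#' with-height equation. Each comparator (the with-height equation fed by an
#' estimated-height source, plus the diameter-only equation) is summarised
#' against that reference by [stratified_errors()] on per-tree biomass.
#'
#' @inheritParams plot_biomass
#' @param eq_with_H With-height equation id.
#' @param eq_without_H Diameter-only equation id, or `NULL` to skip.
#' @param height_sources Character vector of estimated-height sources to
#'   compare (subset of `"local_fit"`, `"guyana_shield"`, `"pantropical"`).
#' @param breaks DBH size-class breakpoints (cm).
#' @return Tibble of stratified error summaries with a `comparator` column.
#' @export
biomass_error_comparison <- function(data, eq_with_H, eq_without_H = NULL,
                                     height_sources = c("local_fit",
                                                        "guyana_shield",
                                                        "pantropical"),
                                     fit = NULL, E = NULL, breaks = 30,
                                     min_dbh = 5) {
  ref <- per_tree_agb(data, eq_with_H, "measured", fit, E, min_dbh)
  rows <- list()
  for (src in height_sources) {
    est <- per_tree_agb(data, eq_with_H, src, fit, E, min_dbh)
    rows[[length(rows) + 1]] <- dplyr::mutate(
      stratified_errors(data, est, ref, breaks),
      comparator = paste0(eq_with_H, ":", src), .before = 1)
  }
  if (!is.null(eq_without_H)) {
    est <- per_tree_agb(data, eq_without_H, "none", fit, E, min_dbh)
    rows[[length(rows) + 1]] <- dplyr::mutate(
      stratified_errors(data, est, ref, breaks),
      comparator = paste0(eq_without_H, ":none"), .before = 1)
  }
  dplyr::bind_rows(rows)
}

#' Carbon-stock arithmetic for a biomass correction
#'
#' Converts a proportional correction of mean stand biomass over a forest area
#' into a change in carbon stock: `dC = area x mean_agb x correction x
#' carbon_fraction`, reported in petagrams of carbon, and optionally into a
#' monetary value at a given carbon price.
#'
#' @param area_ha Forest area in hectares.
#' @param mean_agb_mg_ha Mean aboveground biomass in Mg per hectare.
#' @param correction Proportional correction (e.g. `0.22` for +22%; may be
#'   negative).
#' @param carbon_fraction Carbon fraction of dry biomass (default 0.485).
#' @param price_usd_per_mg_c Optional carbon price in USD per Mg C.
#' @return One-row tibble: `delta_c_pg` (Pg C) and `value_usd` (`NA` without a
#'   price).
#' @export
#' @examples
#' carbon_accounting(148e6, 299, 0.22) # ~4.7 Pg C
carbon_accounting <- function(area_ha, mean_agb_mg_ha, correction,
                              carbon_fraction = 0.485,
                              price_usd_per_mg_c = NULL) {
  check_numeric(area_ha, "area_ha", positive = TRUE)
  check_numeric(mean_agb_mg_ha, "mean_agb_mg_ha", positive = TRUE)
  check_numeric(carbon_fraction, "carbon_fraction", positive = TRUE)
  delta_mg_c <- area_ha * mean_agb_mg_ha * correction * carbon_fraction
  delta_pg <- delta_mg_c / 1e9
  value <- if (is.null(price_usd_per_mg_c)) NA_real_ else
    delta_mg_c * price_usd_per_mg_c
  tibble(delta_c_pg = delta_pg, value_usd = value)
}
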