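#' Simulate a stand and write it to disk
#'
#' Writes the inventory CSV (in the [read_inventory()] dialect), the
#' ground-truth parameters, the species effects, and the plot areas to
#' `out_dir`. Deterministic given the configuration seed.
#'
#' @param cfg A `stand_config` or a preset name (see [stand_preset()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return The [generate_stand()] result, invisibly.
#' @export
run_simulate <- function(cfg, out_dir, seed = NULL) {
  if (is.character(cfg)) cfg <- stand_preset(cfg, seed = seed %||% 1)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  sim <- generate_stand(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_inventory(sim$data, file.path(out_dir, "inventory.csv"))
  readr::write_csv(
    tibble(parameter = names(sim$truth$true_params),
           value = as.numeric(sim$truth$true_params),
           model = sim$truth$true_model,
           height_noise_sd = sim$truth$height_noise_sd),
    file.path(out_dir, "truth_parameters.csv"))
  readr::write_csv(sim$truth$species_effects,
                   file.path(out_dir, "truth_species_effects.csv"))
  readr::write_csv(tibble(plot_id = names(sim$plot_areas),
                          area_ha = as.numeric(sim$plot_areas)),
                   file.path(out_dir, "plot_areas.csv"))
  invisible(sim)
}

#' Fit and rank all candidate models, writing a selection table
#'
#' @param data Inventory tibble with `dbh` and `height`.
#' @param path Optional CSV path for the selection table.
#' @param models Model names to fit (default: all ten).
#' @param min_dbh Optional minimum DBH filter for fitting.
#' @param options Fit options.
#' @return The ranked tibble from [rank_hd_models()].
#' @export
run_fit_rank <- function(data, path = NULL, models = hd_models()$name,
                         min_dbh = NULL, options = fit_options()) {
  ranked <- rank_hd_models(fit_hd_models(data, models, min_dbh, options))
  if (!is.null(path)) hd_selection_table(ranked, path)
  ranked
}

#' Height and biomass error comparison, with cumulative-biomass series
#'
#' Orchestrates the full comparison for one dataset: fits (or reuses) the
#' local models, summarises height errors per model and size class, biomass
#' errors per comparator and size class, and the cumulative biomass series for
#' every height source. CSVs are written when `out_dir` is given.
#'
#' @param data Inventory tibble (wood density already resolved when the
#'   biomass equations need it).
#' @param plot_areas Named vector plot id -> area (ha).
#' @param eq_with_H,eq_without_H Biomass equation ids.
#' @param E Environmental-stress index (needed by the pantropical models).
#' @param fits Optional precomputed [fit_hd_models()] result.
#' @param breaks DBH size-class breakpoints (cm).
#' @param out_dir Optional output directory.
#' @return List of tibbles: `height_errors`, `biomass_errors`, `cumulative`,
#'   `ranked`.
#' @export
run_compare <- function(data, plot_areas, eq_with_H, eq_without_H = NULL,
                        E = NULL, fits = NULL, breaks = 30, out_dir = NULL) {
  fits <- fits %||% fit_hd_models(data)
  ranked <- rank_hd_models(fits)
  best <- ranked$fit[[1]]
  height_errors <- compare_height_models(data, fits, E = E, breaks = breaks)
  biomass_errors <- biomass_error_comparison(
    data, eq_with_H, eq_without_H, fit = best, E = E, breaks = breaks)
  sources <- c("measured", "local_fit", "guyana_shield", "pantropical")
  if (is.null(E)) sources <- setdiff(sources, "pantropical")
  cumulative <- purrr::map_dfr(sources, function(src) {
    dplyr::mutate(
      cumulative_biomass(data, eq_with_H, src, fit = best, E = E,
                         plot_areas = plot_areas),
      height_source = src, .before = 1)
  })
  if (!is.null(eq_without_H)) {
    cumulative <- dplyr::bind_rows(cumulative, dplyr::mutate(
      cumulative_biomass(data, eq_without_H, "none", plot_areas = plot_areas),
      height_source = "none", .before = 1))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hd_selection_table(ranked, file.path(out_dir, "model_selection.csv"))
    readr::write_csv(height_errors, file.path(out_dir, "height_errors.csv"))
    readr::write_csv(biomass_errors, file.path(out_dir, "biomass_errors.csv"))
    readr::write_csv(cumulative, file.path(out_dir, "cumulative_biomass.csv"))
  }
  list(height_errors = height_errors, biomass_errors = biomass_errors,
       cumulative = cumulative, ranked = ranked)
}

#' Carbon accounting table
#'
#' Applies [carbon_accounting()] to one or more scenarios and optionally
#' writes the result.
#'
#' @param scenarios Tibble with columns `label`, `area_ha`, `mean_agb_mg_ha`,
#'   `correction` and optionally `carbon_fraction`, `price_usd_per_mg_c`.
#' @param path Optional CSV path.
#' @return Tibble of scenarios with `delta_c_pg` and `value_usd` appended.
#' @export
run_carbon <- function(scenarios, path = NULL) {
  check_columns(scenarios, c("label", "area_ha", "mean_agb_mg_ha", "correction"),
                "run_carbon")
  out <- purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios[i, ]
    cf <- if ("carbon_fraction" %in% names(s) && !is.na(s$carbon_fraction))
      s$carbon_fraction else 0.485
    pr <- if ("price_usd_per_mg_c" %in% names(s) && !is.na(s$price_usd_per_mg_c))
      s$price_usd_per_mg_c else NULL
    dplyr::bind_cols(s, carbon_accounting(s$area_ha, s$mean_agb_mg_ha,
                                          s$correction, cf, pr))
  })
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
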