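test_that("the log-bias correction factor is exp(rse^2/2)", {
  expect_equal(correction_factor(0), 1)
  expect_equal(correction_factor(1), exp(0.5))
  # the factor printed in the terra-firme with-height equation
  expect_equal(correction_factor(0.394), 1.08071, tolerance = 1e-4)
  expect_error(correction_factor(-0.1), "non-negative")
})

test_that("tree biomass matches hand evaluation of each closed form", {
  expect_equal(tree_agb(10, "tf_H", height = 13),
               exp(-3.04385 + 0.94863 * log(100 * 13)) * 1.08071,
               tolerance = 1e-12)
  expect_equal(tree_agb(10, "tf_H", height = 13), 46.3, tolerance = 1e-2)
  expect_equal(tree_agb(10, "tf_D"), 45.6, tolerance = 1e-2)
  # unit argument: rho D^2 H = 1 collapses the pantropical form to its constant
  expect_equal(tree_agb(10, "chave_H", height = 1 / (0.5 * 100), rho = 0.5),
               0.0673, tolerance = 1e-12)
})

test_that("equations demand their covariates by name", {
  expect_error(tree_agb(10, "tf_H"), "height")
  expect_error(tree_agb(10, "varzea_H", height = 12), "rho")
  expect_error(tree_agb(10, "chave_D", rho = 0.6), "E")
})

test_that("trees below 5 cm DBH are skipped visibly, not silently", {
  expect_message(out <- tree_agb(c(3, 10), "tf_D"), "DBH < 5")
  expect_true(is.na(out[1]))
  expect_false(is.na(out[2]))
})

test_that("the moist-forest with-height equation is exponentiated, with the printed form behind strict", {
  rho <- 0.7; d <- 20; h <- 18
  expect_equal(tree_agb(d, "varzea_H", height = h, rho = rho),
               exp(-3.027 + log(rho * d^2 * h)) * 1.051195, tolerance = 1e-12)
  expect_equal(tree_agb(d, "varzea_H", height = h, rho = rho, strict = TRUE),
               -3.027 + log(rho * d^2 * h) * 1.051195, tolerance = 1e-12)
})

test_that("every equation increases in each covariate it uses", {
  eqs <- biomass_equations()
  for (i in seq_len(nrow(eqs))) {
    id <- eqs$id[i]
    args0 <- list(dbh = 20, equation = id)
    if (eqs$uses_height[i]) args0$height <- 18
    if (eqs$uses_density[i]) args0$rho <- 0.6
    if (eqs$uses_E[i]) args0$E <- 0.02
    base <- do.call(tree_agb, args0)
    up_d <- args0; up_d$dbh <- 25
    expect_gt(do.call(tree_agb, up_d), base, label = paste(id, "dbh"))
    if (eqs$uses_height[i]) {
      up_h <- args0; up_h$height <- 22
      expect_gt(do.call(tree_agb, up_h), base, label = paste(id, "height"))
    }
    if (eqs$uses_density[i]) {
      up_r <- args0; up_r$rho <- 0.8
      expect_gt(do.call(tree_agb, up_r), base, label = paste(id, "rho"))
    }
  }
})

test_that("removing the printed correction factor rescales biomass exactly", {
  eqs <- biomass_equations()
  cf <- eqs$correction_factor[eqs$id == "tf_D"]
  expect_equal(tree_agb(30, "tf_D") / cf, exp(-1.91172 + 2.45043 * log(30)),
               tolerance = 1e-12)
})

test_that("plot biomass scales by area and is order-invariant", {
  d <- tibble::tibble(plot_id = "P1", tag = "1", dbh = 10, height = 13)
  # force a known per-tree biomass: 500 kg on a 0.5-ha plot is 1 Mg/ha
  agb <- tree_agb(10, "tf_H", height = 13)
  pb <- plot_biomass(d, "tf_H", "measured", plot_areas = c(P1 = 0.5))
  expect_equal(pb$agb_mg_ha, (agb / 1000) / 0.5)
  sim <- small_varzea_sim(seed = 13)
  fwd <- plot_biomass(sim$data, "varzea_H", "measured", plot_areas = sim$plot_areas)
  rev <- plot_biomass(sim$data[rev(seq_len(nrow(sim$data))), ], "varzea_H",
                      "measured", plot_areas = sim$plot_areas)
  expect_equal(dplyr::arrange(fwd, plot_id), dplyr::arrange(rev, plot_id))
  expect_error(plot_biomass(d, "tf_H", "measured", plot_areas = c(P9 = 1)),
               "No area")
})

test_that("cumulative curves are monotone and conserve the stand total", {
  sim <- small_varzea_sim(seed = 13)
  cb <- cumulative_biomass(sim$data, "varzea_H", "measured",
                           plot_areas = sim$plot_areas)
  expect_true(all(diff(cb$agb_cum_mg_ha) >= -1e-12))
  pb <- plot_biomass(sim$data, "varzea_H", "measured", plot_areas = sim$plot_areas)
  expect_equal(dplyr::last(cb$agb_cum_mg_ha), mean(pb$agb_mg_ha),
               tolerance = 1e-9)
})

test_that("comparing a height source against itself gives identically zero error", {
  sim <- small_varzea_sim(seed = 13)
  be <- biomass_error_comparison(sim$data, "varzea_H", height_sources = "local_fit",
                                 fit = fit_hd(sim$data, "michaelis_menten"))
  ref <- biomass_error_comparison(sim$data, "varzea_H",
                                  height_sources = character(0),
                                  eq_without_H = "varzea_D")
  self <- stratified_errors(
    sim$data,
    est = suppressMessages(tree_agb(sim$data$dbh, "varzea_H",
                                    height = sim$data$height,
                                    rho = sim$data$wood_density)),
    meas = suppressMessages(tree_agb(sim$data$dbh, "varzea_H",
                                     height = sim$data$height,
                                     rho = sim$data$wood_density)))
  expect_equal(self$te[self$size_class == "all"], 0)
  expect_equal(self$cvse[self$size_class == "all"], 0)
  # a no-height comparator is noisier than a local-fit comparator
  expect_gt(ref$cvre[ref$size_class == "all"],
            0)
  expect_true(all(c("varzea_H:local_fit") %in% be$comparator))
})

test_that("carbon accounting reproduces the REDD+ worked arithmetic", {
  up <- carbon_accounting(148e6, 299, 0.22)
  expect_equal(up$delta_c_pg, 148e6 * 299 * 0.22 * 0.485 / 1e9,
               tolerance = 1e-12)
  expect_equal(up$delta_c_pg, 4.72, tolerance = 0.01)
  down <- carbon_accounting(2.5e6, 266.6, -0.13)
  expect_equal(down$delta_c_pg, -0.042, tolerance = 1e-3)
  priced <- carbon_accounting(1, 1, 4.7e9, carbon_fraction = 1,
                              price_usd_per_mg_c = 7.13)
  expect_equal(priced$value_usd, 33.511e9, tolerance = 1e-4)
  zero <- carbon_accounting(100, 200, 0)
  expect_equal(zero$delta_c_pg, 0)
})
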