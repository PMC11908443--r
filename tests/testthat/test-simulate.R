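test_that("generation is bit-identical under a fixed seed", {
  a <- generate_stand(stand_preset("varzea_like", seed = 5, n_trees = 150))
  b <- generate_stand(stand_preset("varzea_like", seed = 5, n_trees = 150))
  expect_identical(a$data, b$data)
  expect_identical(a$truth$species_effects, b$truth$species_effects)
  c <- generate_stand(stand_preset("varzea_like", seed = 6, n_trees = 150))
  expect_false(identical(a$data$dbh, c$data$dbh))
})

test_that("zero noise and no species effect put every height on the true curve", {
  cfg <- stand_config(
    forest_type = "varzea", n_trees = 80, dbh_range = c(5, 140),
    dbh_mean = 24.5, true_model = "michaelis_menten",
    true_params = c(a = 33.09269, b = 18.42734), height_noise_sd = 0,
    species_pool = make_species_pool(5), wd_mean = 0.7, wd_sd = 0.14,
    species_intercept_sd = 0, seed = 2
  )
  sim <- generate_stand(cfg)
  expected <- hd_model("michaelis_menten")$fn(c(33.09269, 18.42734),
                                              sim$data$dbh)
  expect_equal(sim$data$height, pmax(expected, 1.2), tolerance = 1e-12)
})

test_that("heights respect the 1.2 m floor and stay positive", {
  cfg <- stand_config(
    forest_type = "terra_firme", n_trees = 400, dbh_range = c(1, 110),
    dbh_mean = 10, true_model = "log_linear",
    true_params = c(a = -2.70755, b = 8.65375), height_noise_sd = 6,
    species_pool = make_species_pool(10), wd_mean = 0.7, wd_sd = 0.14, seed = 3
  )
  sim <- generate_stand(cfg)
  expect_true(all(sim$data$height >= 1.2))
})

test_that("empirical species abundances match the configured pool", {
  cfg <- stand_config(
    forest_type = "varzea", n_trees = 5000, dbh_range = c(5, 140),
    dbh_mean = 24.5, true_model = "michaelis_menten",
    true_params = c(a = 33, b = 18), height_noise_sd = 4,
    species_pool = make_species_pool(10, dominant_abundance = 0.36),
    wd_mean = 0.73, wd_sd = 0.14, seed = 11
  )
  sim <- generate_stand(cfg)
  counts <- table(factor(sim$data$species, levels = cfg$species_pool$species))
  gof <- suppressWarnings(
    stats::chisq.test(as.numeric(counts), p = cfg$species_pool$abundance))
  expect_gt(gof$p.value, 0.01)
  dominant <- max(counts) / sum(counts)
  expect_equal(unname(dominant), 0.36, tolerance = 0.05)
})

test_that("the stratified design records expansion factors consistent with inclusion", {
  sim <- generate_stand(stand_preset("terra_firme_like", seed = 9))
  d <- sim$data
  expect_true("expansion_factor" %in% names(d))
  # full-plot stratum (>= 30 cm) has factor 1; smallest trees the largest factor
  expect_equal(unique(d$expansion_factor[d$dbh >= 30]), 1)
  expect_equal(unique(d$expansion_factor[d$dbh < 10]), 0.5 / 0.0125)
  expect_equal(unique(d$expansion_factor[d$dbh >= 10 & d$dbh < 30]), 2)
  # included sample size lands near the configured target
  expect_gt(nrow(d), 0.8 * 1156)
  expect_lt(nrow(d), 1.3 * 1156)
})

test_that("generated diameters honour their truncation range and target mean", {
  sim <- generate_stand(stand_preset("varzea_like", seed = 30, n_trees = 4000))
  expect_true(all(sim$data$dbh >= 5 & sim$data$dbh <= 140))
  expect_equal(mean(sim$data$dbh), 24.5, tolerance = 0.75)
})

test_that("phylogeny generation is deterministic, ultrametric and binary", {
  sp <- paste0("sp", 1:12)
  t1 <- generate_phylogeny(sp, seed = 4)
  t2 <- generate_phylogeny(sp, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_true(all(t1$edge.length > 0))
  pair <- generate_phylogeny(c("A sp", "B sp"), seed = 1)
  depths <- ape::node.depth.edgelength(pair)
  expect_equal(depths[1], depths[2]) # a single cherry with equal tip depths
  expect_error(generate_phylogeny(c("A", "A")), "unique")
  expect_error(generate_phylogeny("A"), "At least 2")
})

test_that("wood-density tables cover the pool unless species are held out", {
  pool <- make_species_pool(40)
  full <- generate_wood_density_table(pool, seed = 6)
  expect_equal(nrow(full$species), 40)
  half <- generate_wood_density_table(pool, seed = 6, holdout = 0.5)
  expect_equal(nrow(half$species), 20)
  # the law's sample mean converges: 300 species at N(0.70, 0.14)
  big <- generate_wood_density_table(make_species_pool(300), wd_mean = 0.70,
                                     wd_sd = 0.14, seed = 7)
  expect_equal(mean(big$species$wood_density), 0.70, tolerance = 0.02)
})

test_that("infeasible configurations are rejected early", {
  pool <- make_species_pool(5)
  expect_error(stand_config("varzea", 10, c(140, 5), 24, "michaelis_menten",
                            c(a = 33, b = 18), 4, pool, 0.7, 0.14),
               "increasing")
  expect_error(stand_config("varzea", 10, c(5, 140), 130, "michaelis_menten",
                            c(a = 33, b = 18), 4, pool, 0.7, 0.14),
               "infeasible")
  expect_error(stand_config("varzea", 10, c(5, 140), 24, "michaelis_menten",
                            c(a = 33), 4, pool, 0.7, 0.14), "2 values")
  bad_pool <- pool
  bad_pool$abundance <- bad_pool$abundance * 2
  expect_error(stand_config("varzea", 10, c(5, 140), 24, "michaelis_menten",
                            c(a = 33, b = 18), 4, bad_pool, 0.7, 0.14),
               "sum to 1")
})
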