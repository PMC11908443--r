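# Small in-code fixtures shared across test files.

tiny_inventory <- function() {
  tibble::tibble(
    plot_id = c("P1", "P1", "P1", "P2", "P2", "P2"),
    tag = as.character(1:6),
    family = c("Fabaceae", "Fabaceae", "Lecythidaceae", "Fabaceae",
               "indet", "Meliaceae"),
    genus = c("Mora", "Mora", "Eschweilera", "Pentaclethra",
              "indet", "Carapa"),
    species = c("Mora paraensis", "Mora paraensis", "Eschweilera coriacea",
                "Pentaclethra macroloba", "indet", "Carapa guianensis"),
    dbh = c(12.5, 33.1, 8.0, 51.2, 15.0, 24.3),
    height = c(14.2, 24.0, 9.5, 29.1, 16.0, 21.5),
    forest_type = "varzea"
  )
}

tiny_wd_table <- function() {
  hdallom::wood_density_table(tibble::tibble(
    family = c("Fabaceae", "Fabaceae", "Lecythidaceae"),
    genus = c("Mora", "Pentaclethra", "Eschweilera"),
    species = c("Mora paraensis", "Pentaclethra macroloba",
                "Eschweilera coriacea"),
    wood_density = c(0.86, 0.60, 0.78)
  ))
}

write_tiny_inventory_csv <- function(path) {
  writeLines(c(
    "plot_id,tree_tag,family,genus,species,dbh_cm,height_m,forest_type",
    "P1,1,Fabaceae,Mora,Mora paraensis,12.5,14.2,varzea",
    "P1,2,Fabaceae,Mora,Mora paraensis,33.1,24.0,varzea",
    "P2,3,Meliaceae,Carapa,Carapa guianensis,24.3,21.5,varzea"
  ), path)
  path
}

# Representative parameter sets for each registry model, in realistic
# height/diameter ranges, used by recovery and oracle tests.
representative_params <- function() {
  list(
    quadratic = c(a = 0.63296, b = 1.11213, c = -0.09504),
    michaelis_menten = c(a = 51.09644, b = 25.11112),
    weibull = c(a = 42.84443, b = 0.05836, c = 0.84815),
    exp3 = c(a = 38.97337, b = 37.80493, c = 0.04184),
    exp2 = c(a = 37.81206, b = 0.0465),
    gompertz = c(a = 34.67709, b = 2.28522, c = 0.08633),
    power = c(a = 4.14876, b = 0.54281),
    mod_exp2 = c(a = 39.41123, b = -9.87593),
    logistic = c(a = 32.81866, b = 6.2464, c = 0.13849),
    log_linear = c(a = -2.70755, b = 8.65375)
  )
}

# Smallest-footprint stand for tests that only need plausible structure.
small_varzea_sim <- function(seed = 1, n = 250) {
  hdallom::generate_stand(hdallom::stand_preset("varzea_like", seed = seed,
                                                n_trees = n))
}
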