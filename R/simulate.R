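#' Configure a synthetic forest stand
#'
#' Bundles the generative parameters for [generate_stand()]: a truncated
#' exponential diameter distribution (the right-skewed form typical of natural
#' stands), a true height-diameter law from the model registry, additive
#' Gaussian height noise on the natural scale, a species pool with fixed
#' relative abundances, per-species random height intercepts, a truncated
#' normal wood-density law, and an optional size-stratified subplot sampling
#' design with recorded expansion factors.
#'
#' @param forest_type `"terra_firme"` or `"varzea"`.
#' @param n_trees Target number of inventoried (included) trees.
#' @param dbh_range Diameter truncation range in cm, within (0, 500).
#' @param dbh_mean Target mean diameter (cm) of the population on `dbh_range`;
#'   the exponential rate is solved from it.
#' @param true_model Name of the generating height-diameter model.
#' @param true_params Named parameter vector for `true_model`.
#' @param height_noise_sd Residual height SD in m (>= 0).
#' @param species_pool Tibble with `species`, `genus`, `family`, `abundance`
#'   (abundances summing to 1), e.g. from [make_species_pool()].
#' @param wd_mean,wd_sd Wood-density law (g cm^-3), truncated above 0.05.
#' @param species_intercept_sd SD (m) of the per-species random height
#'   intercept.
#' @param sampling_design `NULL`, or a tibble with `min_dbh` (cm, increasing)
#'   and `area_ha`: trees are included with probability `area_ha /
#'   plot_area_ha` of their size stratum and carry the reciprocal as
#'   `expansion_factor`.
#' @param n_plots,plot_area_ha Plot layout.
#' @param seed Integer seed; every stage of the generator draws from a stream
#'   derived from it, so repeated calls are bit-identical.
#' @return A `stand_config` list, validated.
#' @seealso [stand_preset()] for ready-made configurations.
#' @export
stand_config <- function(forest_type, n_trees, dbh_range, dbh_mean,
                         true_model, true_params, height_noise_sd,
                         species_pool, wd_mean, wd_sd,
                         species_intercept_sd = 1,
                         sampling_design = NULL,
                         n_plots = 4, plot_area_ha = 0.5, seed = 1) {
  if (!forest_type %in% c("terra_firme", "varzea")) {
    abort("`forest_type` must be 'terra_firme' or 'varzea'.")
  }
  if (length(dbh_range) != 2 || dbh_range[1] <= 0 || dbh_range[2] >= 500 ||
      dbh_range[1] >= dbh_range[2]) {
    abort("`dbh_range` must be increasing and within (0, 500) cm.")
  }
  if (dbh_mean <= dbh_range[1] || dbh_mean >= mean(dbh_range)) {
    abort("`dbh_mean` is infeasible for a right-skewed law on `dbh_range`.")
  }
  if (height_noise_sd < 0) abort("`height_noise_sd` must be >= 0.")
  check_columns(species_pool, c("species", "genus", "family", "abundance"),
                "stand_config")
  if (abs(sum(species_pool$abundance) - 1) > 1e-8) {
    abort("Species abundances must sum to 1.")
  }
  if (!is.null(sampling_design)) {
    check_columns(sampling_design, c("min_dbh", "area_ha"), "stand_config")
    if (any(diff(sampling_design$min_dbh) <= 0)) {
      abort("`sampling_design$min_dbh` must be strictly increasing.")
    }
    if (any(sampling_design$area_ha > plot_area_ha)) {
      abort("Subplot areas cannot exceed the plot area.")
    }
  }
  spec <- hd_model(true_model) # validates the name
  if (length(true_params) != spec$arity) {
    abort(sprintf("`true_params` must have %d values for '%s'.",
                  spec$arity, true_model))
  }
  structure(list(
    forest_type = forest_type, n_trees = as.integer(n_trees),
    dbh_range = dbh_range, dbh_mean = dbh_mean,
    true_model = true_model, true_params = true_params,
    height_noise_sd = height_noise_sd, species_pool = species_pool,
    wd_mean = wd_mean, wd_sd = wd_sd,
    species_intercept_sd = species_intercept_sd,
    sampling_design = sampling_design,
    n_plots = as.integer(n_plots), plot_area_ha = plot_area_ha,
    seed = as.integer(seed)
  ), class = "stand_config")
}

#' @export
print.stand_config <- function(x, ...) {
  cat(sprintf("<stand_config> %s: ~%d trees, %s law, noise sd %.3g m, seed %d\n",
              x$forest_type, x$n_trees, x$true_model, x$height_noise_sd, x$seed))
  invisible(x)
}

#' Synthetic species pool
#'
#' Builds a species pool with geometric rank-abundance structure (each species
#' a fixed fraction less abundant than the previous), optionally forcing the
#' most abundant species to a given share - seasonally flooded stands are
#' often strongly dominated by a single species.
#'
#' @param n_species Number of species.
#' @param n_families Number of families the genera are spread over.
#' @param dominant_abundance Optional share of the top species (e.g. 0.36).
#' @param decay Geometric decay of the remaining abundances.
#' @return Tibble: `species`, `genus`, `family`, `abundance` (sums to 1).
#' @export
make_species_pool <- function(n_species, n_families = max(2, n_species %/% 5),
                              dominant_abundance = NULL, decay = 0.92) {
  if (n_species < 1) abort("`n_species` must be >= 1.")
  ab <- decay^(seq_len(n_species) - 1)
  ab <- ab / sum(ab)
  if (!is.null(dominant_abundance)) {
    if (n_species < 2) abort("A dominant species needs at least 2 species.")
    rest <- ab[-1] / sum(ab[-1]) * (1 - dominant_abundance)
    ab <- c(dominant_abundance, rest)
  }
  idx <- sprintf("%03d", seq_len(n_species))
  genus <- paste0("Genus", sprintf("%03d", ((seq_len(n_species) - 1) %% max(n_species %/% 2, 1)) + 1))
  family <- paste0("Family", sprintf("%02d", ((seq_len(n_species) - 1) %% n_families) + 1))
  tibble(
    species = paste0(genus, " species", idx),
    genus = genus, family = family, abundance = ab
  )
}

#' Preset stand configurations
#'
#' Two ready-made configurations emulating the contrasting study conditions of
#' Northeastern Amazonian inventories:
#' \describe{
#'   \item{terra_firme_like}{1,156 trees, DBH 1-110 cm, quadratic true law
#'     (a = 0.63296, b = 1.11213, c = -0.09504), residual SD 4.018 m, 150
#'     species, wood density ~ N(0.70, 0.14), five 0.5-ha plots with the
#'     size-stratified subplot design (DBH >= 1 cm on 0.0125 ha, >= 10 cm on
#'     0.25 ha, >= 30 cm on the full plot).}
#'   \item{varzea_like}{806 trees, DBH 5-140 cm, Michaelis-Menten true law
#'     (a = 33.09269, b = 18.42734), residual SD 4.164 m, 65 species with a
#'     36% dominant, wood density ~ N(0.73, 0.14), four 0.5-ha plots, all
#'     trees >= 5 cm on the full plot.}
#' }
#' The true laws and noise levels are the best-fit local models and their
#' residual errors for each forest type, so pipelines run on these presets
#' face realistic signal-to-noise.
#'
#' @param name Preset name.
#' @param seed Seed forwarded to [stand_config()].
#' @param n_trees Optional override of the target tree count.
#' @return A `stand_config`.
#' @export
stand_preset <- function(name = c("terra_firme_like", "varzea_like"), seed = 1,
                         n_trees = NULL) {
  name <- match.arg(name)
  if (name == "terra_firme_like") {
    stand_config(
      forest_type = "terra_firme",
      n_trees = n_trees %||% 1156,
      dbh_range = c(1, 110), dbh_mean = 15,
      true_model = "quadratic",
      true_params = c(a = 0.63296, b = 1.11213, c = -0.09504),
      height_noise_sd = 4.018,
      species_pool = make_species_pool(150, n_families = 30, decay = 0.97),
      wd_mean = 0.70, wd_sd = 0.14, species_intercept_sd = 1,
      sampling_design = tibble(min_dbh = c(1, 10, 30),
                               area_ha = c(0.0125, 0.25, 0.5)),
      n_plots = 5, plot_area_ha = 0.5, seed = seed
    )
  } else {
    stand_config(
      forest_type = "varzea",
      n_trees = n_trees %||% 806,
      dbh_range = c(5, 140), dbh_mean = 24.5,
      true_model = "michaelis_menten",
      true_params = c(a = 33.09269, b = 18.42734),
      height_noise_sd = 4.164,
      species_pool = make_species_pool(65, n_families = 15,
                                       dominant_abundance = 0.3598, decay = 0.9),
      wd_mean = 0.73, wd_sd = 0.14, species_intercept_sd = 1,
      sampling_design = NULL,
      n_plots = 4, plot_area_ha = 0.5, seed = seed
    )
  }
}

# Truncated exponential: rate solved so the mean on [lo, hi] hits the target.
truncexp_rate <- function(lo, hi, target_mean) {
  w <- hi - lo
  mean_at <- function(r) {
    if (r < 1e-12) return(lo + w / 2)
    lo + 1 / r - w * exp(-r * w) / (1 - exp(-r * w))
  }
  stats::uniroot(function(r) mean_at(r) - target_mean,
                 lower = 1e-9, upper = 5, tol = 1e-12)$root
}

rtruncexp <- function(n, lo, hi, rate) {
  u <- runif(n)
  w <- hi - lo
  lo - log(1 - u * (1 - exp(-rate * w))) / rate
}

# Named random streams derived from one seed keep the generator's stages
# independently reproducible.
stream_seed <- function(seed, stage) {
  offsets <- c(dbh = 11L, species = 23L, effects = 37L, noise = 53L,
               plots = 67L, inclusion = 79L, wd = 97L, phylo = 113L)
  (seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Generate a synthetic forest inventory
#'
#' Draws a stand from a [stand_config()]: diameters from the truncated
#' exponential law, species from the pool's fixed abundances, heights as
#' `true_law(DBH) + species intercept + Gaussian noise` floored at 1.2 m (the
#' minimum a live measured stem realistically has), per-species wood density
#' from the truncated normal law, and - when a sampling design is configured -
#' size-dependent inclusion with the expansion factor recorded per tree.
#'
#' @param cfg A `stand_config`.
#' @return A list with:
#'   \item{data}{inventory tibble in the [read_inventory()] layout
#'     (plus `expansion_factor` under a sampling design);}
#'   \item{plot_areas}{named vector plot id -> area (ha);}
#'   \item{truth}{ground truth: `true_model`, `true_params`,
#'     `height_noise_sd`, and a `species_effects` tibble.}
#' @export
#' @examples
#' sim <- generate_stand(stand_preset("varzea_like", n_trees = 100, seed = 42))
#' dplyr::glimpse(sim$data)
generate_stand <- function(cfg) {
  if (!inherits(cfg, "stand_config")) abort("`cfg` must be a `stand_config`.")
  lo <- cfg$dbh_range[1]; hi <- cfg$dbh_range[2]
  rate <- truncexp_rate(lo, hi, cfg$dbh_mean)

  # expected inclusion probability sets the superpopulation size
  incl_prob <- function(dbh) {
    if (is.null(cfg$sampling_design)) return(rep(1, length(dbh)))
    idx <- findInterval(dbh, cfg$sampling_design$min_dbh)
    p <- rep(0, length(dbh))
    p[idx > 0] <- cfg$sampling_design$area_ha[idx[idx > 0]] / cfg$plot_area_ha
    p
  }
  n_pop <- if (is.null(cfg$sampling_design)) cfg$n_trees else {
    grid <- seq(lo, hi, length.out = 2048)
    dens <- rate * exp(-rate * (grid - lo)) / (1 - exp(-rate * (hi - lo)))
    p_bar <- sum(incl_prob(grid) * dens) / sum(dens)
    ceiling(cfg$n_trees / p_bar)
  }

  set.seed(stream_seed(cfg$seed, "dbh"))
  dbh <- rtruncexp(n_pop, lo, hi, rate)

  set.seed(stream_seed(cfg$seed, "species"))
  sp_idx <- sample.int(nrow(cfg$species_pool), n_pop, replace = TRUE,
                       prob = cfg$species_pool$abundance)

  set.seed(stream_seed(cfg$seed, "effects"))
  sp_eff <- rnorm(nrow(cfg$species_pool), 0, cfg$species_intercept_sd)

  set.seed(stream_seed(cfg$seed, "noise"))
  spec <- hd_model(cfg$true_model)
  height <- spec$fn(cfg$true_params, dbh) + sp_eff[sp_idx] +
    rnorm(n_pop, 0, cfg$height_noise_sd)
  height <- pmax(height, 1.2)

  set.seed(stream_seed(cfg$seed, "plots"))
  plot_id <- paste0("P", sample.int(cfg$n_plots, n_pop, replace = TRUE))

  set.seed(stream_seed(cfg$seed, "inclusion"))
  p <- incl_prob(dbh)
  included <- runif(n_pop) < p

  set.seed(stream_seed(cfg$seed, "wd"))
  rho <- truncnorm_draw(nrow(cfg$species_pool), cfg$wd_mean, cfg$wd_sd, lo = 0.05)

  pool <- cfg$species_pool
  data <- tibble(
    plot_id = plot_id, tag = as.character(seq_len(n_pop)),
    family = pool$family[sp_idx], genus = pool$genus[sp_idx],
    species = pool$species[sp_idx],
    dbh = dbh, height = height, forest_type = cfg$forest_type,
    wood_density = rho[sp_idx]
  )
  if (!is.null(cfg$sampling_design)) data$expansion_factor <- 1 / pmax(p, 1e-12)
  data <- data[included, ]
  data$tag <- as.character(seq_len(nrow(data)))

  plot_areas <- setNames(rep(cfg$plot_area_ha, cfg$n_plots),
                         paste0("P", seq_len(cfg$n_plots)))
  list(
    data = data,
    plot_areas = plot_areas,
    truth = list(
      true_model = cfg$true_model, true_params = cfg$true_params,
      height_noise_sd = cfg$height_noise_sd,
      species_effects = tibble(species = pool$species, intercept = sp_eff,
                               wood_density = rho),
      config = cfg
    )
  )
}

truncnorm_draw <- function(n, mean, sd, lo = 0.05) {
  out <- rnorm(n, mean, sd)
  bad <- out <= lo
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out <= lo
  }
  out
}

#' Generate a pure-birth phylogeny over a species pool
#'
#' Ultrametric Yule tree (via [ape::rphylo()]) with the given species as tips,
#' for exercising phylogenetic regression without any downloaded megatree.
#'
#' @param species Character vector of unique species names (>= 2).
#' @param seed Integer seed; the returned Newick string is reproducible.
#' @return An `ape::phylo`, ultrametric with positive branch lengths.
#' @export
generate_phylogeny <- function(species, seed = 1) {
  if (length(species) < 2) abort("At least 2 species are required.")
  if (anyDuplicated(species)) abort("Species names must be unique.")
  set.seed(stream_seed(seed, "phylo"))
  tree <- ape::rphylo(length(species), birth = 1, death = 0)
  tree$tip.label <- species
  tree
}

#' Generate a wood-density lookup table for a species pool
#'
#' One truncated-normal density per species, in the [read_wood_density()]
#' layout. A holdout fraction of species can be left out of the table to
#' exercise the genus/family/plot fallbacks of [assign_wood_density()].
#'
#' @param species_pool Tibble with `species`, `genus`, `family`.
#' @param wd_mean,wd_sd Density law in g cm^-3 (truncated above 0.05).
#' @param seed Integer seed.
#' @param holdout Fraction (0-1) of species dropped from the table.
#' @param drop_taxonomy With `holdout = 1`, also returns an empty table so
#'   every assignment falls through to the plot mean.
#' @return A `wood_density_table`.
#' @export
generate_wood_density_table <- function(species_pool, wd_mean = 0.7,
                                        wd_sd = 0.14, seed = 1, holdout = 0) {
  check_columns(species_pool, c("species", "genus", "family"),
                "generate_wood_density_table")
  if (holdout < 0 || holdout > 1) abort("`holdout` must be in [0, 1].")
  set.seed(stream_seed(seed, "wd"))
  rho <- truncnorm_draw(nrow(species_pool), wd_mean, wd_sd, lo = 0.05)
  df <- tibble(family = species_pool$family, genus = species_pool$genus,
               species = species_pool$species, wood_density = rho)
  if (holdout > 0) {
    n_drop <- round(holdout * nrow(df))
    drop_idx <- sample.int(nrow(df), n_drop)
    df <- df[-drop_idx, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    return(structure(list(
      species = tibble(species = character(), wood_density = numeric()),
      genus = tibble(genus = character(), wood_density = numeric()),
      family = tibble(family = character(), wood_density = numeric())
    ), class = "wood_density_table"))
  }
  wood_density_table(df)
}
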