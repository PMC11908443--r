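#' Height-diameter mixed model with a species random intercept
#'
#' Fits a linear mixed model of height on `ln D` (log-linear form) or
#' `ln D + (ln D)^2` (quadratic form) with a species random intercept by REML
#' (via \pkg{lme4}), and reports the marginal and conditional R-squared
#' separating the variance explained by the fixed diameter terms from that
#' explained by species identity:
#' `R2m = var_fixed / (var_fixed + var_species + var_resid)` and
#' `R2c = (var_fixed + var_species) / (same denominator)`, where `var_fixed`
#' is the variance of the fixed-effect predictions (the Nakagawa-Schielzeth
#' formulation for Gaussian responses).
#'
#' @param data Inventory tibble with `dbh`, `height` and `species` columns.
#' @param form `"log_linear"` or `"quadratic_lnD"`.
#' @return A `species_mixed_fit`: fixed-effect estimates, variance components
#'   (`sigma_species`, `sigma_resid` as SDs), `r2_marginal`, `r2_conditional`,
#'   `aic`, `n`, `n_species`, and the underlying `lmerMod` in `$model`.
#' @export
fit_species_mixed <- function(data, form = c("log_linear", "quadratic_lnD")) {
  form <- match.arg(form)
  check_columns(data, c("dbh", "height", "species"), "fit_species_mixed")
  d <- dplyr::filter(data, !is.na(.data$dbh), !is.na(.data$height),
                     !is.na(.data$species))
  counts <- table(d$species)
  if (sum(counts >= 2) < 2) {
    abort(paste0("At least 2 species with >= 2 trees each are required; ",
                 "use a fixed-effects fit (`fit_hd()`) for single-species data."))
  }
  d$lnD <- log(d$dbh)
  fml <- if (form == "log_linear") {
    height ~ lnD + (1 | species)
  } else {
    height ~ lnD + I(lnD^2) + (1 | species)
  }
  fit <- lme4::lmer(fml, data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_species <- vc$vcov[vc$grp == "species"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  denom <- var_fixed + var_species + var_resid
  structure(list(
    form = form,
    fixed = tibble(term = names(lme4::fixef(fit)),
                   estimate = as.numeric(lme4::fixef(fit))),
    sigma_species = sqrt(var_species), sigma_resid = sqrt(var_resid),
    var_fixed = var_fixed,
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + var_species) / denom,
    aic = AIC(fit), n = nrow(d), n_species = length(counts),
    model = fit
  ), class = "species_mixed_fit")
}

#' @export
print.species_mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<species_mixed_fit> %s, n = %d trees, %d species\n  sigma_species = %.3g m, sigma_resid = %.3g m\n  R2 marginal = %.3f, conditional = %.3f\n",
    x$form, x$n, x$n_species, x$sigma_species, x$sigma_resid,
    x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.species_mixed_fit <- function(x, ...) {
  tibble(form = x$form, n = x$n, n_species = x$n_species,
         sigma_species = x$sigma_species, sigma_resid = x$sigma_resid,
         r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
         aic = x$aic)
}

#' Per-species maximum height and diameter
#'
#' Extracts each species' maximum observed DBH and maximum observed height
#' (maxima are per trait, not necessarily from the same tree). Unidentified
#' records (species missing or "indet") are excluded.
#'
#' @param data Inventory tibble with `species`, `dbh`, `height`.
#' @return Tibble with `species`, `n`, `dmax` (cm), `hmax` (m).
#' @export
taxon_maxima <- function(data) {
  check_columns(data, c("species", "dbh", "height"), "taxon_maxima")
  d <- dplyr::filter(data,
    !is.na(.data$species), !grepl("indet", .data$species, ignore.case = TRUE),
    !is.na(.data$dbh), !is.na(.data$height))
  dplyr::summarise(dplyr::group_by(d, .data$species),
                   n = dplyr::n(), dmax = max(.data$dbh), hmax = max(.data$height),
                   .groups = "drop")
}

#' Phylogenetic generalized least squares of Hmax on Dmax
#'
#' Fits `Hmax ~ ln Dmax + (ln Dmax)^2` (or the log-linear form) by GLS with a
#' Brownian-motion phylogenetic covariance (shared path length to the root,
#' from the supplied tree's branch lengths; \pkg{nlme} + \pkg{ape}), and by
#' ordinary least squares for comparison. With `method = "lambda"`, Pagel's
#' lambda is estimated by maximum likelihood instead of being fixed at the
#' Brownian value of 1. Both fits use ML estimation so AICs are comparable.
#'
#' @param maxima Tibble from [taxon_maxima()] (`species`, `dmax`, `hmax`).
#' @param tree An `ape::phylo` with all species as tips and positive branch
#'   lengths.
#' @param form `"quadratic_lnD"` or `"log_linear"`.
#' @param method `"brownian"` (lambda fixed at 1) or `"lambda"` (ML).
#' @return A `pgls_fit`: `coefficients`, `rse`, `adj_pseudo_r2`, `aic`,
#'   `lambda` (when estimated) and a `comparison` tibble of the PGLS versus
#'   OLS statistics.
#' @export
pgls_fit <- function(maxima, tree, form = c("quadratic_lnD", "log_linear"),
                     method = c("brownian", "lambda")) {
  form <- match.arg(form)
  method <- match.arg(method)
  check_columns(maxima, c("species", "dmax", "hmax"), "pgls_fit")
  if (!inherits(tree, "phylo")) abort("`tree` must be an `ape::phylo` object.")
  missing <- setdiff(maxima$species, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("Taxa missing from the phylogeny: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("The phylogeny must have non-negative branch lengths.")
  }
  tree <- ape::keep.tip(tree, maxima$species)
  d <- as.data.frame(maxima)
  rownames(d) <- d$species
  d$lnD <- log(d$dmax)
  fml <- if (form == "quadratic_lnD") hmax ~ lnD + I(lnD^2) else hmax ~ lnD
  corr <- if (method == "brownian") {
    ape::corBrownian(1, phy = tree, form = ~species)
  } else {
    ape::corPagel(0.5, phy = tree, form = ~species, fixed = FALSE)
  }
  gls_fit <- nlme::gls(fml, data = d, correlation = corr, method = "ML")
  ols_fit <- nlme::gls(fml, data = d, method = "ML")

  k <- length(coef(gls_fit))
  n <- nrow(d)
  stats_of <- function(fit) {
    res <- d$hmax - as.numeric(predict(fit))
    sse <- sum(res^2)
    sst <- sum((d$hmax - mean(d$hmax))^2)
    r2 <- 1 - sse / sst
    c(rse = sqrt(sse / (n - k)),
      adj_pseudo_r2 = r2 - ((k - 1) / (n - k)) * (1 - r2),
      aic = AIC(fit))
  }
  sg <- stats_of(gls_fit); so <- stats_of(ols_fit)
  lambda <- if (method == "lambda") {
    as.numeric(coef(gls_fit$modelStruct$corStruct, unconstrained = FALSE))
  } else {
    NA_real_
  }
  structure(list(
    form = form, method = method,
    coefficients = tibble(term = names(coef(gls_fit)),
                          estimate = as.numeric(coef(gls_fit)),
                          std_error = sqrt(diag(vcov(gls_fit)))),
    ols_coefficients = tibble(term = names(coef(ols_fit)),
                              estimate = as.numeric(coef(ols_fit)),
                              std_error = sqrt(diag(vcov(ols_fit)))),
    rse = unname(sg["rse"]), adj_pseudo_r2 = unname(sg["adj_pseudo_r2"]),
    aic = unname(sg["aic"]), lambda = lambda, n = n,
    comparison = tibble(
      model = c("pgls", "ols"),
      rse = c(sg["rse"], so["rse"]),
      adj_pseudo_r2 = c(sg["adj_pseudo_r2"], so["adj_pseudo_r2"]),
      aic = c(sg["aic"], so["aic"])),
    model = gls_fit, ols_model = ols_fit
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> %s (%s), n = %d taxa\n", x$form, x$method, x$n))
  if (!is.na(x$lambda)) cat(sprintf("  Pagel's lambda = %.3f\n", x$lambda))
  print(x$comparison)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.pgls_fit <- function(x, ...) {
  tibble(form = x$form, method = x$method, n = x$n, rse = x$rse,
         adj_pseudo_r2 = x$adj_pseudo_r2, aic = x$aic, lambda = x$lambda)
}

#' Phylogenetic signal of a continuous trait
#'
#' Pagel's lambda by maximum likelihood (via \pkg{phytools}): 0 means no
#' phylogenetic structure in the trait, 1 matches Brownian motion on the tree.
#'
#' @param trait Named numeric vector (names are tip labels).
#' @param tree An `ape::phylo` containing those tips.
#' @return One-row tibble: `lambda`, `loglik`, `p_value` (likelihood-ratio
#'   test against lambda = 0).
#' @export
phylo_signal <- function(trait, tree) {
  if (is.null(names(trait))) abort("`trait` must be named by tip label.")
  res <- phytools::phylosig(tree, trait, method = "lambda", test = TRUE)
  tibble(lambda = res$lambda, loglik = res$logL, p_value = res$P)
}
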