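# hdallom

Height–diameter allometry and biomass uncertainty for tropical forest
inventories.

## The problem

Plot-level aboveground biomass (AGB) in tropical forests is predicted, tree
by tree, from diameter at breast height (DBH, cm), total height (m) and wood
density (g cm⁻³) through published allometric equations. Height is the weak
link: it is expensive to measure, so it is usually itself predicted from DBH
— either by a locally fitted height–diameter model or by a published
regional/pantropical equation. Whether that substitution biases the biomass
totals (and by how much, and for which tree sizes) is the question this
package answers quantitatively, for inventories of the kind collected in
Amazonian terra-firme (non-flooded) and várzea (seasonally flooded) forests.

`hdallom` provides:

- **Ten candidate height–diameter models** (Michaelis–Menten
  *H = aD/(b+D)*, Weibull *H = a(1−e^(−bD^c))*, Gompertz, logistic,
  exponentials, power, log-linear, and a log-quadratic), fitted by
  Levenberg–Marquardt nonlinear least squares with additive error on the
  height scale, and ranked by adjusted pseudo-R², RSE = √(SSE/(n−K)) and
  AIC = 2k − 2 ln L.
- **Validation diagnostics**: observed-vs-predicted regression with
  Graybill's joint F test of (intercept, slope) = (0, 1) and Theil's exact
  partition of Σ(o−p)² into bias, consistency and lack-of-fit components;
  species random-intercept mixed models with marginal/conditional R²
  (Nakagawa–Schielzeth); phylogenetic GLS of per-species maximum height on
  maximum diameter with Brownian or Pagel-λ covariance.
- **Published height models** as drop-in predictors: the regional
  Guyana-shield Weibull (fixed coefficients 42.845, 0.0433, 0.9372) and the
  pantropical climate model *H = exp(0.893 − E + 0.760 ln D − 0.0340 ln²D)*.
- **Biomass propagation**: six published AGB equations (with/without height;
  with/without wood density) including their log-bias correction factors
  CF = exp(RSE²/2); wood-density assignment with species → genus → family →
  plot-mean fallback; per-plot Mg ha⁻¹ totals with sampling-design expansion
  factors; cumulative biomass by DBH class; REDD+ carbon-stock arithmetic.
- **Error decomposition** per comparison and tree-size class: total
  TE = RMSE, systematic SE = mean error, random RE = SD of errors, and their
  per-tree proportional analogues CVTE/CVSE/CVRE, obeying
  TE² = SE² + ((n−1)/n)·RE².
- **A synthetic stand generator** (`generate_stand()`) with known ground
  truth — truncated-exponential diameters, species pools with fixed
  abundances, species random intercepts, truncated-normal wood density, and
  size-stratified subplot sampling with expansion factors — so the whole
  pipeline is testable without field data.

## Worked example

Simulate a várzea-like stand (806 trees, Michaelis–Menten true law with
residual SD 4.16 m, one species at 36% dominance), fit and rank all ten
models, and compare height sources:

```r
library(hdallom)

sim <- generate_stand(stand_preset("varzea_like", seed = 7))
ranked <- rank_hd_models(fit_hd_models(sim$data))
ranked[1:4, c("rank", "model", "rse", "adj_pseudo_r2", "aic")]
#>    rank model              rse adj_pseudo_r2   aic
#> 1     1 michaelis_menten  4.33         0.612 4654.
#> 2     2 quadratic         4.33         0.611 4656.
#> 3     3 weibull           4.33         0.611 4656.
#> 4     4 exp3              4.33         0.611 4657.

tidy(ranked$fit[[1]])
#>   model            term  estimate std_error
#> 1 michaelis_menten a         33.0     0.898
#> 2 michaelis_menten b         20.3     1.26
```

The generating model tops the ranking and its true parameters (a = 33.09,
b = 18.43) sit within about two reported standard errors of the estimates.
The fitted RSE (4.33 m) reflects the configured 4.16 m residual noise plus
the 1 m species-intercept spread.

```r
cmp <- compare_height_models(sim$data, ranked, E = 0.04)
dplyr::filter(cmp, size_class == "all")[, c("model", "cvse")]
#>   model              cvse
#> 1 michaelis_menten  0.197
#> 2 guyana_shield     0.583
#> 3 pantropical       0.285
```

The regional Guyana-shield model (asymptote 42.8 m) badly overpredicts
heights in this short-statured stand, the local fit is closest, and the
pantropical model sits between — the ordering the error-decomposition
machinery is designed to expose. (On synthetic stands the *proportional*
errors are inflated for the smallest stems by the generator's homoscedastic
noise; see the methods vignette.)

Carbon arithmetic for a 22% upward biomass correction over the Guyana
shield's 148 Mha of terra-firme forest at 299 Mg ha⁻¹ and 48.5% carbon:

```r
carbon_accounting(148e6, 299, 0.22, price_usd_per_mg_c = 7.13)
#>   delta_c_pg   value_usd
#> 1       4.72 33665638292
```

about 4.7 Pg C, worth ≈ $33.7 billion at $7.13 per Mg C.

Each result type plots itself: `autoplot(fit)` for a fitted curve over the
data, `plot_hd_fits()` to overlay the best models, `plot_error_summary()`
for CVSE/CVTE bars by size class, `plot_cumulative_biomass()` for
cumulative Mg ha⁻¹ by DBH class and height source.

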