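---
title: "Height-diameter allometry and biomass uncertainty: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height-diameter allometry and biomass uncertainty: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdallom)
```

## The problem

Tropical forest carbon accounting rests on allometric chains: diameter at
breast height (DBH, cm) is cheap to measure; total height (m) is expensive and
error-prone; aboveground biomass (AGB, kg per tree) is almost never measured
directly. Plot-level biomass is therefore predicted, tree by tree, from DBH,
height and wood density through published regression equations — and every
substitution of a modelled height for a measured one propagates error into the
biomass totals on which REDD+-style carbon payments are negotiated.

`hdallom` implements that chain end to end for inventories of the kind
collected in Amazonian terra-firme (non-flooded upland) and várzea (seasonally
flooded floodplain) forests: fitting and ranking candidate height-diameter
curves, validating them, comparing them against regional and pantropical
published height models, propagating all of them into biomass, and
decomposing the resulting error into systematic and random parts by tree-size
class. A synthetic stand generator with known ground truth makes every stage
testable without field data.

## Height-diameter models

Ten candidate forms are registered (`hd_models()`), all with additive error on
the natural height scale:

| name | form | parameters |
|---|---|---|
| quadratic | $H = e^{a + b\ln D + c\ln^2 D}$ | 3 |
| michaelis_menten | $H = aD/(b + D)$ | 2 |
| weibull | $H = a(1 - e^{-bD^c})$ | 3 |
| exp3 | $H = a - b e^{-cD}$ | 3 |
| exp2 | $H = a(1 - e^{-bD})$ | 2 |
| gompertz | $H = a e^{-b e^{-cD}}$ | 3 |
| power | $H = aD^b$ | 2 |
| mod_exp2 | $H = a e^{b/D}$ | 2 |
| logistic | $H = a/(1 + b e^{-cD})$ | 3 |
| log_linear | $H = a + b\ln D$ | 2 |

Most are asymptotic: $a$ is an interpretable maximum height, and for the
Michaelis-Menten form $b$ is the diameter at half-maximum height. The
quadratic form (with $c < 0$) is asymptotic in behaviour over the observed
range but eventually turns over at $D = e^{-b/(2c)}$
(`quadratic_turning_point()`), which is why predictions outside the fitted
diameter range should not be trusted.

### Fitting

`fit_hd()` minimises $\sum_i (H_i - f(\theta, D_i))^2$ on the *untransformed*
height scale for every form, including the two log-scale ones — the additive
error is part of each model's definition here, and fitting the quadratic by
OLS on $\ln H$ would estimate a different (multiplicative-error) model.
Numerical choices:

* **Optimizer**: Levenberg-Marquardt (`minpack.lm::nls.lm`) with analytic
  Jacobians for all ten forms. The convergence tolerance on relative
  parameter change is `1e-10`; this is deliberately tight so that the linear
  special case (log_linear) reproduces its closed-form OLS solution to
  `1e-8`, a property the test suite asserts against `lm()` directly.
* **Starting values** are deterministic and data-driven: asymptotes start at
  $1.05 \max H$; Michaelis-Menten uses the Lineweaver-Burk linearisation;
  Weibull, Gompertz, logistic and the exponentials log-linearise their rate
  parameters; quadratic, power, mod_exp2 and log_linear start at the OLS
  solution on the transformed scale. Log-linearisations clamp their arguments
  away from zero.
* **Restarts**: on non-convergence, up to 5 restarts from log-normally
  jittered starts (25% scale), under a fixed seed from `fit_options()`, so a
  refit is reproducible. Non-converged fits are returned flagged, ranked
  last, never dropped silently.
* **Standard errors** come from the Gauss-Newton approximation
  $\hat\sigma^2 (J^\top J)^{-1}$ at the optimum.

### Selection statistics

With $K$ regression parameters, $N$ trees, SSE the residual sum of squares and
SST the total sum of squares about the mean height:

* $\mathrm{RSE} = \sqrt{\mathrm{SSE}/(N - K)}$ (m);
* adjusted pseudo-$R^2$: $R^2 - \frac{K-1}{N-K}(1 - R^2)$ with
  $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$;
* $\mathrm{AIC} = 2k - 2\ln L$ with the Gaussian likelihood
  $\ln L = -\frac{N}{2}(\ln 2\pi + \ln(\mathrm{SSE}/N) + 1)$. By default $k$
  counts the error variance as an estimated parameter ($k = K + 1$), the
  convention of mainstream statistical software; `hd_aic(fit, count_sigma =
  FALSE)` gives the $k = K$ variant, since published AIC tables do not always
  let one confirm which convention was used.

`rank_hd_models()` orders lexicographically: adjusted pseudo-$R^2$ descending,
then RSE ascending, then AIC ascending.

A caution about interpreting ranks: when data are generated from one
asymptotic form at realistic noise (residual SD about 4 m at $n \approx 800$),
several other asymptotic forms approximate the generating curve to well within
that noise, and the adjusted-$R^2$ penalty for one extra parameter almost
exactly offsets the expected chance improvement from fitting it. The winner
among the shape-equivalent forms is then close to a coin flip, while the
asymptotic *family* tops the ranking very reliably. The test suite therefore
checks family-level recovery (a height-saturating form ranks first) plus
parameter-level recovery of the generating form (estimates within three
reported standard errors of truth), rather than demanding that one specific
label win.

## Validation diagnostics

`obs_vs_pred()` regresses observed on predicted values. Two complementary
tests are built on it, and they answer different questions:

* **Graybill's test** (`graybill_test()`): the simultaneous F test of
  $H_0: (\alpha, \beta) = (0, 1)$,
  $F = (\hat\beta - \theta)^\top X^\top X (\hat\beta - \theta) / (2\,\mathrm{MSE})$
  on $(2, n-2)$ df. Being a joint test with a very precise null at large $n$,
  it can reject decisively even when each coefficient individually looks
  compatible with the 1:1 line.
* **Theil's decomposition** (`theil_decomposition()`): the exact partition
  $\sum(o_i - p_i)^2 = n(\bar o - \bar p)^2 + (\hat\beta - 1)^2 S_{pp} +
  \mathrm{SSE}_{\mathrm{reg}}$, i.e. bias ("no bias"), consistency (slope),
  and regression lack-of-fit components. Bias and consistency are F-tested
  (1 df) against the regression residual mean square; "model lack-of-fit" is
  the test on the total, $F = (\mathrm{SS}_{\mathrm{tot}}/n)/\mathrm{MSE}$ on
  $(n, n-2)$ df. Because F-testing the residual SS against its own mean
  square is vacuous, the p-value attached to the regression lack-of-fit
  component comes from a 1-df curvature test (a quadratic term added to the
  obs-on-pred regression), which is what "non-linear deviation" means
  operationally. Several textbook variants of this decomposition exist; this
  construction was chosen because it yields exactly these four named
  components with an exact sum identity, which the tests verify to $10^{-9}$
  relative.

The two can disagree — a joint Graybill rejection alongside individually
non-significant bias and consistency components is a property of the tests,
not a contradiction; both are reported.

## Taxonomic and phylogenetic structure

`fit_species_mixed()` adds a species random intercept to the linear forms
($H \sim \ln D$ or $H \sim \ln D + \ln^2 D$), fitted by REML (`lme4`). The
marginal and conditional $R^2$ follow the Nakagawa-Schielzeth variance
decomposition: $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_s + \sigma^2_e)$
and $R^2_c = (\sigma^2_f + \sigma^2_s) / (\cdot)$, with $\sigma^2_f$ the
variance of the fixed-effect predictions. $R^2_c \ge R^2_m$ always, with
equality exactly when the species variance vanishes.

`pgls_fit()` regresses per-species maximum height on log maximum diameter
(`taxon_maxima()`, maxima per trait, unidentified records excluded) by
generalized least squares with a Brownian-motion covariance from the
phylogeny's branch lengths (`nlme::gls` + `ape::corBrownian`), against an OLS
reference fit; both use ML so AICs are comparable. With a star phylogeny the
covariance is the identity and PGLS reproduces OLS exactly (tested to
$10^{-8}$). Phylogenetic signal is summarised as Pagel's $\lambda$ by maximum
likelihood (`phylo_signal()`, via `phytools::phylosig`); $\lambda$ was chosen
over Blomberg's K because it plugs directly into the same GLS machinery
(`method = "lambda"` in `pgls_fit()`).

## Height prediction and error decomposition

Two published models are wired in as fixed-coefficient predictors
(`published_height_model()`): the regional Guyana-shield Weibull
$H = 42.845(1 - e^{-0.0433 D^{0.9372}})$, evaluated *through the registry
Weibull form* so the two code paths are identical by construction, and the
pantropical form $H = e^{0.893 - E + 0.760\ln D - 0.0340 \ln^2 D}$, which
needs the scalar environmental-stress index $E$ (a climate covariate,
typically between $-0.2$ and $0.2$; $0.015$ is a representative terra-firme
value). $E$ is supplied by the caller — raster extraction is out of scope.

`error_summary()` computes, for per-tree errors $e_i = \hat h_i - h_i$:

$$\mathrm{TE} = \sqrt{\tfrac1n \sum e_i^2}, \qquad
  \mathrm{SE} = \tfrac1n \sum e_i, \qquad
  \mathrm{RE} = \sqrt{\tfrac{1}{n-1} \sum (e_i - \mathrm{SE})^2},$$

and the proportional analogues CVTE/CVSE/CVRE on $e_i / h_i$, computed per
tree then aggregated (never as a ratio of aggregates). The algebraic identity
$\mathrm{TE}^2 = \mathrm{SE}^2 + \frac{n-1}{n}\mathrm{RE}^2$ is asserted
property-style in the tests. With $n = 1$ the random components are reported
as `NA` — undefined, not zero. `stratified_errors()` splits by DBH class on
half-open intervals $[d_{\mathrm{lo}}, d_{\mathrm{hi}})$; the default single
breakpoint at 30 cm separates "small" from "large" trees, a conventional
boundary for these forests, and is configurable.

## Biomass

`tree_agb()` evaluates six published equations (three with height, three
without; see `biomass_equations()`), each carrying its printed multiplicative
log-bias correction factor $CF = e^{\mathrm{RSE}^2/2}$
(`correction_factor()`), with DBH in cm, height in m and wood density $\rho$
in g cm$^{-3}$ (no unit auto-conversion). Two deliberate choices:

* The printed moist-forest with-height equation
  ($AGB = -3.027 + \ln(\rho D^2 H) \times 1.051195$) is dimensionally
  incoherent as written — it returns a log-scale quantity plus an additive
  constant. It is implemented in exponentiated form,
  $AGB = e^{-3.027 + \ln(\rho D^2 H)} \times 1.051195$, matching the
  log-linear moist-forest family it derives from and the package-wide CF
  convention; the literal printed form remains available behind
  `strict = TRUE` for auditability.
* Biomass is computed only for stems with DBH $\ge$ 5 cm, and this filter is
  applied at biomass time (visibly — skipped trees are `NA` with a message),
  not at data load, so height models can still use smaller trees.

Wood density is resolved per tree by `assign_wood_density()`: species mean,
else genus mean, else family mean, else the unweighted arithmetic mean of the
already-resolved trees in the same plot. Matching is exact after
whitespace-trim and case-fold (no fuzzy matching — it would be untestable).
The plot-mean fallback runs *after* all taxonomic matches, so it averages over
every tree that could be resolved taxonomically; the alternative ordering
(plot mean before genus/family fallback) would use a smaller basis and was
rejected for that reason. A plot with zero resolvable trees is an error, not a
guess.

`plot_biomass()` aggregates to Mg ha$^{-1}$ using per-tree expansion factors
when the inventory came from a size-stratified design, and
`cumulative_biomass()` accumulates over 10-cm DBH classes (configurable),
which is the standard way to see *where* along the size axis a height source
gains or loses biomass. `carbon_accounting()` turns a proportional correction
of mean stand biomass over an area into Pg C (and USD at a given price),
using a default carbon fraction of 0.485 of dry biomass.

## The synthetic stand generator

`generate_stand()` draws inventories with known ground truth from a
`stand_config()`:

* **Diameters**: truncated exponential, the right-skewed shape of natural
  size distributions; the rate is solved so the population mean hits a target
  (24.5 cm on 5-140 cm for the várzea-like preset).
* **Heights**: true curve + per-species Gaussian intercept + homoscedastic
  Gaussian noise, floored at 1.2 m.
* **Species**: fixed relative abundances with geometric rank-abundance
  structure; the várzea-like preset forces a 36% single-species dominant.
* **Wood density**: truncated normal per species (0.70-0.73 mean, 0.14 SD).
* **Sampling design**: optional size-stratified subplot inclusion (the
  terra-firme-like preset inventories stems $\ge$ 1 cm on 0.0125 ha,
  $\ge$ 10 cm on 0.25 ha, $\ge$ 30 cm on the full 0.5-ha plot), with the
  reciprocal inclusion probability recorded per tree as its expansion factor.
* **Reproducibility**: every stage draws from a named stream derived from one
  seed, so repeated generation is bit-identical.

The two presets wire the best-fit local laws as truth: quadratic
$(0.63296, 1.11213, -0.09504)$ with residual SD 4.018 m for the
terra-firme-like stand ($n \approx 1156$), Michaelis-Menten
$(33.09269, 18.42734)$ with residual SD 4.164 m for the várzea-like stand
($n = 806$). The species-intercept SD defaults to 1 m, consistent with
species identity explaining only a few percent of height variance within a
forest type.

**What the generator does not emulate.** Real height residuals are
heteroscedastic — small trees scatter a metre or two around the curve, tall
trees several metres. The generator's homoscedastic noise (as the additive
error terms of the candidate models assume) gives the smallest stems
unrealistically large *relative* errors, which inflates the proportional
error metrics (CVSE, CVRE) computed on synthetic stands well above what the
same pipeline reports on field data; absolute metrics and all structural
conclusions (which model family wins, the direction and ordering of
published-model biases, error identities) are unaffected. The generator also
has no spatial structure, no crown or competition dynamics, and no
measurement-instrument error model. Passing tests on synthetic stands
therefore demonstrate the correctness of the estimators and the pipeline, not
the field accuracy of any particular published equation.

## Problem sizes and test design

The test suite generates everything it needs at run time. The heavier
property checks use: 100 stand replicates at $n = 806$ for
coverage-and-ranking recovery (truth within three reported SEs; an asymptotic
form ranks first); a 20-per-dimension brute-force parameter grid as an
independent oracle that the nonlinear optimum must beat, on 50-tree
instances for each of the ten models; and 100 replicates of a 1500-tree,
30-species mixed-model simulation for variance-component recovery (intercept
SD 2 m, residual SD 4 m, both recovered within 20% on average). These sizes
were chosen to make the Monte Carlo assertions stable at the stated
thresholds.

## Limitations

* Height models are only trustworthy inside the fitted diameter range; the
  asymptotic forms in particular understate the height of trees much larger
  than any in the data, and the quadratic form eventually turns over.
* No uncertainty is propagated from the published biomass equations'
  coefficients (out of scope); errors reported here isolate the
  height-source contribution.
* The wood-density fallback is taxonomic and exact-match only; name
  harmonisation against external services is out of scope.
* PGLS assumes the supplied tree's branch lengths are meaningful; building
  the phylogeny is the caller's problem (`generate_phylogeny()` exists for
  testing, not inference).
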