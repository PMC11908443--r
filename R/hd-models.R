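#' The ten candidate height-diameter models
#'
#' Registry of the ten functional forms commonly used for tropical
#' height-diameter allometry. Each model predicts total height H (m) from
#' diameter at breast height D (cm) with additive error on the natural height
#' scale; all fitting in this package minimises squared error on untransformed
#' heights, including for the two log-scale forms (quadratic, log-linear).
#'
#' The forms are:
#' \describe{
#'   \item{quadratic}{`H = exp(a + b ln D + c (ln D)^2)`}
#'   \item{michaelis_menten}{`H = a D / (b + D)`; `a` is the asymptotic
#'     maximum height and `b` the diameter at half-maximum height}
#'   \item{weibull}{`H = a (1 - exp(-b D^c))`}
#'   \item{exp3}{three-parameter exponential `H = a - b exp(-c D)`}
#'   \item{exp2}{two-parameter exponential `H = a (1 - exp(-b D))`}
#'   \item{gompertz}{`H = a exp(-b exp(-c D))`}
#'   \item{power}{`H = a D^b`}
#'   \item{mod_exp2}{modified two-parameter exponential `H = a exp(b / D)`}
#'   \item{logistic}{`H = a / (1 + b exp(-c D))`}
#'   \item{log_linear}{`H = a + b ln D`}
#' }
#'
#' @return `hd_models()` returns a tibble with one row per model: `name`,
#'   `arity` (number of regression parameters) and `equation` (display form).
#' @seealso [hd_model()], [fit_hd()]
#' @export
#' @examples
#' hd_models()
#' mm <- hd_model("michaelis_menten")
#' mm$fn(c(a = 30, b = 15), dbh = 15) # half-saturation: a/2
hd_models <- function() {
  tibble(
    name = vapply(hd_registry(), `[[`, character(1), "name"),
    arity = vapply(hd_registry(), `[[`, integer(1), "arity"),
    equation = vapply(hd_registry(), `[[`, character(1), "equation")
  )
}

#' Retrieve one height-diameter model specification
#'
#' @param name One of the ten names listed by [hd_models()].
#' @return An `hd_model_spec`: a list with `name`, `arity`, `equation`,
#'   `fn(params, dbh)` evaluating the curve, `grad(params, dbh)` its analytic
#'   Jacobian, and `start(dbh, height)` giving deterministic data-driven
#'   initial values.
#' @export
hd_model <- function(name) {
  reg <- hd_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("Unknown height-diameter model '%s'. Available: %s.",
                  name, paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

hd_registry <- function() {
  if (is.null(.hd_cache$registry)) .hd_cache$registry <- build_hd_registry()
  .hd_cache$registry
}
.hd_cache <- new.env(parent = emptyenv())

new_hd_spec <- function(name, arity, equation, fn, grad, start, monotone_domain) {
  raw_fn <- fn
  raw_grad <- grad
  structure(
    list(name = name, arity = as.integer(arity), equation = equation,
         # strip parameter names so predictions come back as bare numerics
         fn = function(p, dbh) raw_fn(as.numeric(p), dbh),
         grad = function(p, dbh) raw_grad(as.numeric(p), dbh),
         start = start, monotone_domain = monotone_domain),
    class = "hd_model_spec"
  )
}

#' @export
print.hd_model_spec <- function(x, ...) {
  cat(sprintf("<hd_model_spec> %s (%d parameters): %s\n",
              x$name, x$arity, x$equation))
  invisible(x)
}

# Deterministic, data-driven starting values. Asymptote guesses use
# 1.05 * max(H); log-linearisations clamp their arguments away from 0.
build_hd_registry <- function() {
  clamp <- function(x, lo = 1e-6, hi = Inf) pmin(pmax(x, lo), hi)

  list(
    quadratic = new_hd_spec(
      "quadratic", 3L, "H = exp(a + b*ln(D) + c*ln(D)^2)",
      fn = function(p, dbh) exp(p[1] + p[2] * log(dbh) + p[3] * log(dbh)^2),
      grad = function(p, dbh) {
        l <- log(dbh); h <- exp(p[1] + p[2] * l + p[3] * l^2)
        cbind(h, h * l, h * l^2)
      },
      start = function(dbh, height) {
        l <- log(dbh)
        co <- coef(lm(log(clamp(height)) ~ l + I(l^2)))
        c(a = unname(co[1]), b = unname(co[2]), c = unname(co[3]))
      },
      monotone_domain = "D <= exp(-b/(2c)) when c < 0; all D when c >= 0"
    ),
    michaelis_menten = new_hd_spec(
      "michaelis_menten", 2L, "H = a*D/(b + D)",
      fn = function(p, dbh) p[1] * dbh / (p[2] + dbh),
      grad = function(p, dbh) {
        cbind(dbh / (p[2] + dbh), -p[1] * dbh / (p[2] + dbh)^2)
      },
      start = function(dbh, height) {
        # Lineweaver-Burk: 1/H = 1/a + (b/a)*(1/D)
        co <- coef(lm(I(1 / clamp(height)) ~ I(1 / dbh)))
        a0 <- 1 / clamp(co[1], 1e-4)
        c(a = unname(a0), b = unname(clamp(co[2] * a0, 0.5)))
      },
      monotone_domain = "all D > 0"
    ),
    weibull = new_hd_spec(
      "weibull", 3L, "H = a*(1 - exp(-b*D^c))",
      fn = function(p, dbh) p[1] * (1 - exp(-p[2] * dbh^p[3])),
      grad = function(p, dbh) {
        e <- exp(-p[2] * dbh^p[3])
        cbind(1 - e, p[1] * e * dbh^p[3], p[1] * e * p[2] * dbh^p[3] * log(dbh))
      },
      start = function(dbh, height) {
        a0 <- 1.05 * max(height)
        z <- -log(clamp(1 - height / a0, 1e-6, 1 - 1e-6))
        co <- coef(lm(log(z) ~ log(dbh)))
        c(a = a0, b = unname(clamp(exp(co[1]), 1e-6)), c = unname(clamp(co[2], 0.05, 3)))
      },
      monotone_domain = "all D > 0"
    ),
    exp3 = new_hd_spec(
      "exp3", 3L, "H = a - b*exp(-c*D)",
      fn = function(p, dbh) p[1] - p[2] * exp(-p[3] * dbh),
      grad = function(p, dbh) {
        e <- exp(-p[3] * dbh)
        cbind(rep(1, length(dbh)), -e, p[2] * dbh * e)
      },
      start = function(dbh, height) {
        a0 <- 1.05 * max(height)
        co <- coef(lm(log(clamp(a0 - height)) ~ dbh))
        c(a = a0, b = unname(clamp(exp(co[1]), 1e-6)), c = unname(clamp(-co[2], 1e-4)))
      },
      monotone_domain = "all D > 0 (b, c > 0)"
    ),
    exp2 = new_hd_spec(
      "exp2", 2L, "H = a*(1 - exp(-b*D))",
      fn = function(p, dbh) p[1] * (1 - exp(-p[2] * dbh)),
      grad = function(p, dbh) {
        e <- exp(-p[2] * dbh)
        cbind(1 - e, p[1] * dbh * e)
      },
      start = function(dbh, height) {
        a0 <- 1.05 * max(height)
        z <- -log(clamp(1 - height / a0, 1e-6, 1 - 1e-6))
        c(a = a0, b = unname(clamp(median(z / dbh), 1e-4)))
      },
      monotone_domain = "all D > 0"
    ),
    gompertz = new_hd_spec(
      "gompertz", 3L, "H = a*exp(-b*exp(-c*D))",
      fn = function(p, dbh) p[1] * exp(-p[2] * exp(-p[3] * dbh)),
      grad = function(p, dbh) {
        e <- exp(-p[3] * dbh); h <- p[1] * exp(-p[2] * e)
        cbind(h / p[1], -h * e, h * p[2] * dbh * e)
      },
      start = function(dbh, height) {
        a0 <- 1.05 * max(height)
        z <- -log(clamp(height / a0, 1e-6, 1 - 1e-6))
        co <- coef(lm(log(clamp(z)) ~ dbh))
        c(a = a0, b = unname(clamp(exp(co[1]), 1e-6)), c = unname(clamp(-co[2], 1e-4)))
      },
      monotone_domain = "all D > 0 (b, c > 0)"
    ),
    power = new_hd_spec(
      "power", 2L, "H = a*D^b",
      fn = function(p, dbh) p[1] * dbh^p[2],
      grad = function(p, dbh) {
        cbind(dbh^p[2], p[1] * dbh^p[2] * log(dbh))
      },
      start = function(dbh, height) {
        co <- coef(lm(log(clamp(height)) ~ log(dbh)))
        c(a = unname(exp(co[1])), b = unname(co[2]))
      },
      monotone_domain = "all D > 0 (b > 0)"
    ),
    mod_exp2 = new_hd_spec(
      "mod_exp2", 2L, "H = a*exp(b/D)",
      fn = function(p, dbh) p[1] * exp(p[2] / dbh),
      grad = function(p, dbh) {
        e <- exp(p[2] / dbh)
        cbind(e, p[1] * e / dbh)
      },
      start = function(dbh, height) {
        co <- coef(lm(log(clamp(height)) ~ I(1 / dbh)))
        c(a = unname(exp(co[1])), b = unname(co[2]))
      },
      monotone_domain = "all D > 0 (b < 0)"
    ),
    logistic = new_hd_spec(
      "logistic", 3L, "H = a/(1 + b*exp(-c*D))",
      fn = function(p, dbh) p[1] / (1 + p[2] * exp(-p[3] * dbh)),
      grad = function(p, dbh) {
        e <- exp(-p[3] * dbh); q <- 1 + p[2] * e
        cbind(1 / q, -p[1] * e / q^2, p[1] * p[2] * dbh * e / q^2)
      },
      start = function(dbh, height) {
        a0 <- 1.05 * max(height)
        z <- clamp(a0 / clamp(height) - 1, 1e-6)
        co <- coef(lm(log(z) ~ dbh))
        c(a = a0, b = unname(clamp(exp(co[1]), 1e-6)), c = unname(clamp(-co[2], 1e-4)))
      },
      monotone_domain = "all D > 0 (b, c > 0)"
    ),
    log_linear = new_hd_spec(
      "log_linear", 2L, "H = a + b*ln(D)",
      fn = function(p, dbh) p[1] + p[2] * log(dbh),
      grad = function(p, dbh) {
        cbind(rep(1, length(dbh)), log(dbh))
      },
      start = function(dbh, height) {
        co <- coef(lm(height ~ log(dbh)))
        c(a = unname(co[1]), b = unname(co[2]))
      },
      monotone_domain = "all D > 0 (b > 0)"
    )
  )
}

#' Diameter at which the quadratic form turns over
#'
#' The quadratic form `exp(a + b ln D + c (ln D)^2)` is non-decreasing only up
#' to `D = exp(-b / (2c))` when `c < 0`; beyond it predicted height declines.
#'
#' @param params Named vector with elements `b` and `c`.
#' @return Turning-point diameter in cm, or `Inf` when `c >= 0`.
#' @export
quadratic_turning_point <- function(params) {
  b <- params[["b"]]; cc <- params[["c"]]
  if (cc >= 0) return(Inf)
  exp(-b / (2 * cc))
}
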