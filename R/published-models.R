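#' Published height-diameter models
#'
#' Two fixed-coefficient height models from the literature, usable wherever a
#' locally fitted model is:
#' \describe{
#'   \item{guyana_shield}{regional Weibull form
#'     `H = 42.845 (1 - exp(-0.0433 D^0.9372))`; no covariates beyond DBH.}
#'   \item{pantropical}{climate-adjusted form
#'     `H = exp(0.893 - E + 0.760 ln D - 0.0340 (ln D)^2)` where `E` is a
#'     scalar environmental-stress index (temperature seasonality, climatic
#'     water deficit, precipitation seasonality) supplied by the caller.}
#' }
#' The Guyana-shield model is evaluated through the registry Weibull form at
#' its printed coefficients, so the two code paths are identical by
#' construction.
#'
#' @param name `"guyana_shield"` or `"pantropical"`.
#' @return A `published_hd_model` object.
#' @seealso [predict_height()]
#' @export
#' @examples
#' predict_height(published_height_model("guyana_shield"), dbh = 10)
#' predict_height(published_height_model("pantropical"), dbh = 25, E = 0.015)
published_height_model <- function(name = c("guyana_shield", "pantropical")) {
  name <- match.arg(name)
  if (name == "guyana_shield") {
    wb <- hd_model("weibull")
    structure(list(
      name = "guyana_shield", requires_E = FALSE,
      coefficients = c(a = 42.845, b = 0.0433, c = 0.9372),
      fn = function(dbh, E = NULL) wb$fn(c(42.845, 0.0433, 0.9372), dbh)
    ), class = "published_hd_model")
  } else {
    structure(list(
      name = "pantropical", requires_E = TRUE,
      coefficients = c(b0 = 0.893, b_lnD = 0.760, b_lnD2 = -0.0340),
      fn = function(dbh, E) {
        exp(0.893 - E + 0.760 * log(dbh) - 0.0340 * log(dbh)^2)
      }
    ), class = "published_hd_model")
  }
}

#' @export
print.published_hd_model <- function(x, ...) {
  cat(sprintf("<published_hd_model> %s%s\n", x$name,
              if (x$requires_E) " (requires environmental-stress index E)" else ""))
  invisible(x)
}

#' Predict tree height from diameter
#'
#' Evaluates a fitted local model, a published model, or a raw model
#' specification with explicit parameters, at the given diameters.
#'
#' @param object An `hd_fit`, `published_hd_model`, or `hd_model_spec`.
#' @param dbh Diameters at breast height (cm), strictly positive.
#' @param ... Passed to methods.
#' @return Predicted total heights (m), one per diameter.
#' @export
predict_height <- function(object, dbh, ...) {
  UseMethod("predict_height")
}

#' @rdname predict_height
#' @export
predict_height.hd_fit <- function(object, dbh, ...) {
  check_numeric(dbh, "dbh", positive = TRUE)
  if (!object$converged) abort("Cannot predict from a non-converged fit.")
  object$spec$fn(object$params, dbh)
}

#' @rdname predict_height
#' @param E Environmental-stress index, required by the pantropical model
#'   (dimensionless, typically in -0.2 to 0.2).
#' @export
predict_height.published_hd_model <- function(object, dbh, E = NULL, ...) {
  check_numeric(dbh, "dbh", positive = TRUE)
  if (object$requires_E) {
    if (is.null(E)) {
      abort(sprintf("Model '%s' requires the environmental-stress index `E`.",
                    object$name))
    }
    object$fn(dbh, E)
  } else {
    object$fn(dbh)
  }
}

#' @rdname predict_height
#' @param params Named parameter vector for an `hd_model_spec`.
#' @export
predict_height.hd_model_spec <- function(object, dbh, params, ...) {
  check_numeric(dbh, "dbh", positive = TRUE)
  object$fn(params, dbh)
}
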