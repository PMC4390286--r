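#' Convert breast-height age to growth time above breast height
#'
#' Breast-height age is the ring count at 1.3 m.  Because the height reached
#' at breast-height age 1 represents, on average, half a year of growth above
#' breast height, the growth time entering the height-age functions is the
#' breast-height age minus one half year.
#'
#' @param bh_age Numeric vector of breast-height ages (years, >= 0.5).
#' @return Numeric vector of growth times `t = bh_age - 0.5` (years).
#' @examples
#' bh_age_to_t(50)   # 49.5, the reference age for site index
#' @export
bh_age_to_t <- function(bh_age) {
  if (!is.numeric(bh_age)) abort("`bh_age` must be numeric.")
  if (any(bh_age < 0.5, na.rm = TRUE))
    abort("`bh_age` must be >= 0.5: growth time above breast height would be negative.")
  bh_age - 0.5
}

#' Base height-age model parameters
#'
#' Bundles the three parameters of one of the base height-age functions:
#'
#' * `CR` (Chapman-Richards): `y = 1.3 + a0 * (1 - exp(a1 * t))^a2` with
#'   asymptote `a0` (m), rate `a1` (1/yr, negative) and shape `a2` (positive).
#' * `HIV` (modified Hossfeld IV):
#'   `y = 1.3 + (b0 * t^b1 / (b2 + t^(b1 - 1)))^(1/3)`.  The exponent
#'   `b1 - 1` in the denominator removes the asymptote of the classical
#'   Hossfeld IV form (`y` grows like `(b0 * t)^(1/3)` at old ages); `b0` is
#'   still referred to as the asymptote-like parameter.
#' * `SCH` (Schumacher): `y = 1.3 + exp(c0 + c1 * t^c2)` with `c1 < 0` and
#'   `c2 < 0`; `exp(c0)` is the asymptote.
#'
#' @param family `"CR"`, `"HIV"` or `"SCH"`.
#' @param ... The three named parameters of the declared family, e.g.
#'   `base_params("CR", a0 = 37.8, a1 = -0.0118, a2 = 1.51)`.
#' @return An object of class `base_params`: a named list with fields
#'   `family` and the three parameter values.
#' @export
base_params <- function(family, ...) {
  fam <- match_family(family)
  dots <- list(...)
  wanted <- .si_par_names[[fam]]
  if (!setequal(names(dots), wanted))
    abort(sprintf("family \"%s\" needs exactly the parameters %s.",
                  fam, paste0("`", wanted, "`", collapse = ", ")))
  vals <- vapply(dots[wanted], function(x) as.numeric(x)[1], numeric(1))
  if (fam == "SCH" && vals[["c2"]] >= 0)
    warn("SCH shape parameter `c2` >= 0: curve is not admissible as a height-age model.")
  structure(c(list(family = fam), as.list(vals)), class = "base_params")
}

#' @export
print.base_params <- function(x, ...) {
  cat(sprintf("<base_params> %s: %s\n", x$family,
              paste(sprintf("%s = %.6g", setdiff(names(x), "family"),
                            unlist(x[setdiff(names(x), "family")])),
                    collapse = ", ")))
  invisible(x)
}

# Vectorized curve evaluation with per-observation parameter vectors.
# Inadmissible combinations yield NaN; no errors are raised here so the
# fitting machinery can penalize them.
.h_pred <- function(family, p0, p1, p2, t) {
  switch(family,
    CR = {
      x <- 1 - exp(p1 * t)
      x[which(x < 0)] <- NaN
      BH + p0 * x^p2
    },
    HIV = {
      den <- p2 + t^(p1 - 1)
      fr <- p0 * t^p1 / den
      fr[which(den <= 0 | fr < 0)] <- NaN
      BH + fr^(1 / 3)
    },
    SCH = {
      BH + exp(p0 + p1 * t^p2)
    }
  )
}

.params_vec <- function(params) {
  unlist(params[.si_par_names[[params$family]]], use.names = FALSE)
}

#' Predict height from a base height-age function
#'
#' Evaluates the noise-free height-age curve of `params` at growth times `t`
#' (years above breast height, see [bh_age_to_t()]).
#'
#' @param params A [base_params()] object.
#' @param t Numeric vector of growth times (years, >= 0).
#' @return Numeric vector of total heights (m).
#' @examples
#' p <- base_params("CR", a0 = 37.819, a1 = -0.01183, a2 = 1.5097)
#' predict_height(p, c(0, 49.5))
#' @export
predict_height <- function(params, t) {
  stopifnot(inherits(params, "base_params"))
  if (any(t < 0, na.rm = TRUE)) abort("`t` must be non-negative.")
  pv <- .params_vec(params)
  h <- .h_pred(params$family, pv[1], pv[2], pv[3], t)
  if (params$family == "HIV" && anyNA(h)) {
    bad <- t[is.na(h)]
    abort(sprintf(
      "HIV curve is inadmissible (denominator b2 + t^(b1-1) <= 0 or negative cube-root argument) at t = %s.",
      paste(signif(head(bad, 5), 6), collapse = ", ")))
  }
  h
}

#' Site index of a height-age curve
#'
#' The site index convention used throughout the package is the height at
#' breast-height age 50, i.e. at growth time `t = 49.5`.
#'
#' @inheritParams predict_height
#' @return Height (m) at `t = 49.5`.
#' @export
site_index <- function(params) {
  predict_height(params, bh_age_to_t(50))
}

#' Scan a height-age curve for admissibility violations
#'
#' Evaluates the base curve of `params` on a grid of growth times and reports
#' every violation of the family's admissibility conditions: a negative
#' asymptote-like parameter or a non-positive denominator `b2 + t^(b1-1)`
#' for HIV, a non-negative rate `a1` or non-positive asymptote for CR, and a
#' non-negative shape `c2` for SCH, as well as any non-finite or decreasing
#' predicted height.
#'
#' @inheritParams predict_height
#' @param t_range Length-2 numeric range of growth times to scan.
#' @param n_grid Number of grid points.
#' @return A list with elements `pass` (logical) and `reasons` (character
#'   vector, empty when `pass` is `TRUE`).
#' @export
admissible_prediction_check <- function(params, t_range = c(0.5, 250), n_grid = 500) {
  stopifnot(inherits(params, "base_params"))
  fam <- params$family
  pv <- .params_vec(params)
  reasons <- character()
  if (fam == "CR") {
    if (pv[1] <= 0) reasons <- c(reasons, "non-positive asymptote parameter a0")
    if (pv[2] >= 0) reasons <- c(reasons, "non-negative rate parameter a1")
    if (pv[3] <= 0) reasons <- c(reasons, "non-positive shape parameter a2")
  } else if (fam == "HIV") {
    if (pv[1] <= 0) reasons <- c(reasons, "negative asymptote-like parameter b0")
    if (pv[2] <= 0) reasons <- c(reasons, "non-positive exponent parameter b1")
  } else {
    if (pv[2] >= 0) reasons <- c(reasons, "non-negative slope parameter c1")
    if (pv[3] >= 0) reasons <- c(reasons, "non-negative shape parameter c2")
  }
  tg <- seq(t_range[1], t_range[2], length.out = n_grid)
  h <- .h_pred(fam, pv[1], pv[2], pv[3], tg)
  if (fam == "HIV") {
    den <- pv[3] + tg^(pv[2] - 1)
    if (any(den <= 0))
      reasons <- c(reasons, sprintf("denominator b2 + t^(b1-1) <= 0 at t in [%.3g, %.3g]",
                                    min(tg[den <= 0]), max(tg[den <= 0])))
  }
  if (any(!is.finite(h)))
    reasons <- c(reasons, sprintf("non-finite prediction at %d grid point(s)", sum(!is.finite(h))))
  else if (any(diff(h) < -1e-10))
    reasons <- c(reasons, "predicted height is not monotone increasing on the grid")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
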