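#' Global parameters of a GADA dynamic site equation
#'
#' In the GADA construction the two local parameters of a base function are
#' replaced by functions of an unobservable growth-intensity factor `chi`,
#' introducing new global parameters:
#'
#' * `CR`:  `a0 = exp(chi)`, `a2 = a20 + a21 / chi`; globals `a1, a20, a21`.
#' * `HIV`: `b0 = b00 + chi`, `b2 = 0.5 * b20 / chi`; globals `b00, b1, b20`.
#' * `SCH`: `c0 = c00 + chi`, `c1 = c10 + c11 * chi`; globals `c10, c11, c2`.
#'   The additive constant `c00` is not identifiable together with the
#'   per-tree `chi` and is fixed at 0; the object records this explicitly.
#'
#' @param family `"CR"`, `"HIV"` or `"SCH"`.
#' @param ... The three named global parameters of the family (see above).
#' @return An object of class `gada_globals`.
#' @export
gada_globals <- function(family, ...) {
  fam <- match_family(family)
  wanted <- .gada_par_names[[fam]]
  dots <- list(...)
  if (!setequal(names(dots), wanted))
    abort(sprintf("GADA %s needs exactly the globals %s.", fam,
                  paste0("`", wanted, "`", collapse = ", ")))
  vals <- vapply(dots[wanted], function(x) as.numeric(x)[1], numeric(1))
  out <- c(list(family = fam), as.list(vals))
  if (fam == "SCH") out$c00_dropped <- TRUE
  structure(out, class = "gada_globals")
}

.gada_par_names <- list(
  CR  = c("a1", "a20", "a21"),
  HIV = c("b00", "b1", "b20"),
  SCH = c("c10", "c11", "c2")
)

#' Global parameters of a g-GADA model
#'
#' The g-GADA expresses the remaining local parameter(s) of a base function
#' directly as functions of a single driving local parameter, without the
#' growth-intensity factor.  Two relations are supported:
#'
#' `relation = "gada_equivalent"` reproduces the GADA model exactly (same
#' globals as [gada_globals()]), with driving local `a0` (CR), `b0` (HIV) or
#' `c0` (SCH):
#' * `CR`:  `a2 = a20 + a21 / log(a0)`
#' * `HIV`: `b2 = 0.5 * b20 / (b0 - b00)`
#' * `SCH`: `c1 = c10 + c11 * c0`
#'
#' `relation = "optimal"` uses the flexible relations selected from
#' indicator-variable local-parameter scatter plots:
#' * `CR`:  `a2 = a20 + a21 * log(a0) + a22 * log(a0)^2`; globals
#'   `a1, a20, a21, a22`, local `a0`.
#' * `HIV`: `b1 = b10 * exp(b11 * b0)` and `b2 = b20 + b21 * b0`; globals
#'   `b10, b11, b20, b21`, local `b0`.
#' * `SCH`: `c0 = c00 + c01 * log(-c2)`; globals `c00, c01, c1`, local `c2`.
#'
#' @inheritParams gada_globals
#' @param relation `"gada_equivalent"` or `"optimal"`.
#' @return An object of class `ggada_globals`.
#' @export
ggada_globals <- function(family, relation = c("gada_equivalent", "optimal"), ...) {
  fam <- match_family(family)
  relation <- arg_match(relation)
  wanted <- .ggada_par_names(fam, relation)
  dots <- list(...)
  if (!setequal(names(dots), wanted))
    abort(sprintf("g-GADA %s (%s) needs exactly the globals %s.", fam, relation,
                  paste0("`", wanted, "`", collapse = ", ")))
  vals <- vapply(dots[wanted], function(x) as.numeric(x)[1], numeric(1))
  structure(c(list(family = fam, relation = relation), as.list(vals)),
            class = "ggada_globals")
}

.ggada_par_names <- function(family, relation) {
  if (relation == "gada_equivalent") return(.gada_par_names[[family]])
  switch(family,
    CR  = c("a1", "a20", "a21", "a22"),
    HIV = c("b10", "b11", "b20", "b21"),
    SCH = c("c00", "c01", "c1"))
}

.ggada_local_name <- function(family, relation) {
  if (relation == "optimal" && family == "SCH") return("c2")
  switch(family, CR = "a0", HIV = "b0", SCH = "c0")
}

# chi0 solutions, vectorized over y0.  `root` selects the branch of the
# quadratic for CR and HIV; the "+" branch is the standard published choice.
.chi0_vec <- function(g, t0, y0, root = "positive") {
  fam <- g$family
  sgn <- if (root == "positive") 1 else -1
  r <- log(y0 - BH)
  if (fam == "CR") {
    L0 <- log(1 - exp(g$a1 * t0))
    b <- r - g$a20 * L0
    disc <- b^2 - 4 * g$a21 * L0
    chi <- (b + sgn * sqrt(pmax(disc, 0))) / 2
    chi[disc < 0] <- NaN
    chi
  } else if (fam == "HIV") {
    z0 <- (y0 - BH)^3
    b <- z0 / t0 - g$b00
    disc <- b^2 + 2 * g$b20 * z0 * t0^(-g$b1)
    chi <- (b + sgn * sqrt(pmax(disc, 0))) / 2
    chi[disc < 0] <- NaN
    chi
  } else {
    s0 <- t0^g$c2
    den <- 1 + g$c11 * s0
    if (abs(den) < 1e-12) return(rep(NaN, length(y0)))
    (r - g$c10 * s0) / den
  }
}

# Base parameters implied by chi0, vectorized over chi0.
.gada_pvec <- function(g, chi0) {
  switch(g$family,
    CR  = list(p0 = exp(chi0), p1 = rep(g$a1, length(chi0)),
               p2 = g$a20 + g$a21 / chi0),
    HIV = list(p0 = g$b00 + chi0, p1 = rep(g$b1, length(chi0)),
               p2 = 0.5 * g$b20 / chi0),
    SCH = list(p0 = chi0, p1 = g$c10 + g$c11 * chi0,
               p2 = rep(g$c2, length(chi0))))
}

# g-GADA relation, vectorized over the driving local.  Domain violations
# yield NaN components (penalized during fitting).
.ggada_pvec <- function(g, local) {
  fam <- g$family
  relation <- g$relation %||% "gada_equivalent"
  n <- length(local)
  safelog <- function(x) {
    out <- rep(NaN, length(x)); pos <- is.finite(x) & x > 0
    out[pos] <- log(x[pos]); out
  }
  if (relation == "gada_equivalent") {
    switch(fam,
      CR = {
        la <- safelog(local)
        la[abs(la) < 1e-12] <- NaN
        list(p0 = local, p1 = rep(g$a1, n), p2 = g$a20 + g$a21 / la)
      },
      HIV = {
        d <- local - g$b00
        d[abs(d) < 1e-12] <- NaN
        list(p0 = local, p1 = rep(g$b1, n), p2 = 0.5 * g$b20 / d)
      },
      SCH = list(p0 = local, p1 = g$c10 + g$c11 * local, p2 = rep(g$c2, n)))
  } else {
    switch(fam,
      CR = {
        la <- safelog(local)
        list(p0 = local, p1 = rep(g$a1, n),
             p2 = g$a20 + g$a21 * la + g$a22 * la^2)
      },
      HIV = list(p0 = local, p1 = g$b10 * exp(g$b11 * local),
                 p2 = g$b20 + g$b21 * local),
      SCH = {
        lc <- safelog(-local)
        list(p0 = g$c00 + g$c01 * lc, p1 = rep(g$c1, n), p2 = local)
      })
  }
}

#' Solve for the growth-intensity factor of a GADA curve
#'
#' Given the global parameters and an initial condition `(t0, y0)` -- a
#' known height `y0` (m) at growth time `t0` (years above breast height) --
#' returns the growth intensity `chi0` such that the base curve with local
#' parameters reconstructed from `chi0` passes exactly through `(t0, y0)`.
#' For CR and HIV `chi0` solves a quadratic and the positive ("+") branch is
#' taken by default; for SCH the solution is linear in `chi0`.
#'
#' @param globals A [gada_globals()] object.
#' @param t0,y0 Initial condition: growth time (years, > 0) and height (m,
#'   > 1.3).  `y0` may be a vector.
#' @param root Quadratic branch, `"positive"` (default, as published) or
#'   `"negative"` (exposed for root screening).
#' @return Numeric vector of `chi0` values.
#' @examples
#' g <- gada_globals("CR", a1 = -0.00955, a20 = -1.7580, a21 = 11.6209)
#' solve_chi0(g, t0 = 49.5, y0 = 20)  # ~ 4.0285
#' @export
solve_chi0 <- function(globals, t0, y0, root = c("positive", "negative")) {
  stopifnot(inherits(globals, "gada_globals"))
  root <- arg_match(root)
  if (any(t0 <= 0)) abort("`t0` must be positive.")
  if (any(y0 <= BH))
    abort("`y0` must exceed 1.3 m: log(y0 - 1.3) is undefined otherwise.")
  chi <- .chi0_vec(globals, t0, y0, root)
  if (anyNA(chi))
    abort("no real root for chi0: the quadratic discriminant is negative (or the SCH denominator vanishes) for some y0.")
  if (globals$family == "CR" && any(abs(chi) < 1e-12))
    abort("degenerate root chi0 = 0 for the CR family (chi0 appears in a denominator).")
  chi
}

#' Predict height from a GADA dynamic equation
#'
#' Evaluates the self-referencing GADA curve anchored at the initial
#' condition `(t0, y0)`.  The prediction equals the base-function prediction
#' with local parameters reconstructed from `chi0 = solve_chi0(...)`; in
#' particular the curve returns exactly `y0` at `t = t0`, and re-anchoring
#' at any other point of the same curve reproduces it (base-age invariance).
#'
#' @inheritParams solve_chi0
#' @param t Numeric vector of growth times (years).
#' @return Numeric vector of heights (m).
#' @export
gada_predict <- function(globals, t, t0, y0, root = c("positive", "negative")) {
  root <- arg_match(root)
  chi0 <- solve_chi0(globals, t0, y0, root)
  if (length(chi0) != 1L)
    abort("`y0` must be a single value in gada_predict().")
  p <- .gada_pvec(globals, chi0)
  .h_pred(globals$family, p$p0, p$p1, p$p2, t)
}

#' Reconstruct full base parameters from a g-GADA driving local parameter
#'
#' Applies the configured relation between local parameters (see
#' [ggada_globals()]) to a value of the driving local parameter and returns
#' the full three-parameter set of the base function.
#'
#' @param local Value of the driving local parameter: `a0` (CR), `b0` (HIV),
#'   `c0` (SCH, gada-equivalent relation) or `c2` (SCH, optimal relation).
#' @param globals A [ggada_globals()] object, or a [gada_globals()] object
#'   (interpreted with the gada-equivalent relation).
#' @return A [base_params()] object.
#' @examples
#' g <- ggada_globals("CR", "optimal",
#'                    a1 = -0.00921, a20 = -9.6725, a21 = 6.7925, a22 = -1.0247)
#' ggada_local_to_params(30, g)  # a2 ~ 1.576
#' @export
ggada_local_to_params <- function(local, globals) {
  if (inherits(globals, "gada_globals")) {
    globals <- unclass(globals)
    globals$relation <- "gada_equivalent"
    class(globals) <- "ggada_globals"
  }
  stopifnot(inherits(globals, "ggada_globals"))
  fam <- globals$family
  relation <- globals$relation
  if (length(local) != 1L) abort("`local` must be a single value.")
  if (fam == "CR" && local <= 0)
    abort(sprintf("relation %s for CR requires a0 > 0.", relation))
  if (fam == "CR" && relation == "gada_equivalent" && abs(local - 1) < 1e-12)
    abort("relation gada_equivalent for CR is undefined at a0 = 1 (log(a0) = 0).")
  if (fam == "HIV" && relation == "gada_equivalent" && abs(local - globals$b00) < 1e-12)
    abort("relation gada_equivalent for HIV is undefined at b0 = b00.")
  if (fam == "SCH" && relation == "optimal" && local >= 0)
    abort("relation optimal for SCH requires c2 < 0.")
  p <- .ggada_pvec(globals, local)
  if (any(!is.finite(c(p$p0, p$p1, p$p2))))
    abort(sprintf("relation %s produced non-finite parameters at local = %g.", relation, local))
  nm <- .si_par_names[[fam]]
  do.call(base_params, c(list(family = fam),
                         setNames(list(p$p0, p$p1, p$p2), nm)))
}
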