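# Calibration: localizing a fitted population model to a new tree from one
# or more height-age observations.

#' Lightweight site index model specification for calibration
#'
#' Bundles fitted (or published) global parameters with their
#' parameterization so that [calibrate()] can be used without refitting.
#' `as_si_model()` extracts the specification from a fitted object.
#'
#' @param family `"CR"`, `"HIV"` or `"SCH"`.
#' @param parameterization `"indicator"`, `"gada"` or `"ggada"`.
#' @param coef Named vector of global parameter values.
#' @param relation g-GADA relation (`"gada_equivalent"` or `"optimal"`),
#'   required when `parameterization = "ggada"`.
#' @param local_set Local parameters of an indicator model.
#' @param t0 Anchoring growth time of a GADA model.
#' @return An object of class `si_model`.
#' @export
si_model <- function(family, parameterization, coef, relation = NULL,
                     local_set = NULL, t0 = 49.5) {
  family <- match_family(family)
  parameterization <- arg_match(parameterization,
                                c("indicator", "gada", "ggada"))
  need <- switch(parameterization,
    indicator = setdiff(.si_par_names[[family]],
                        local_set %||% .default_local_set[[family]]),
    gada = .gada_par_names[[family]],
    ggada = .ggada_par_names(family, relation %||%
                               abort("`relation` is required for a g-GADA model.")))
  if (!all(need %in% names(coef)))
    abort(sprintf("`coef` must contain %s.", paste0("`", need, "`", collapse = ", ")))
  structure(list(family = family, parameterization = parameterization,
                 relation = relation,
                 local_set = local_set %||% .default_local_set[[family]],
                 coef = coef[need], t0 = t0),
            class = "si_model")
}

#' @rdname si_model
#' @param fit An `si_fit` object.
#' @export
as_si_model <- function(fit) {
  stopifnot(inherits(fit, "si_fit"))
  si_model(fit$family, fit$parameterization, fit$coef,
           relation = fit$relation, local_set = fit$local_set,
           t0 = fit$t0 %||% 49.5)
}

#' Screen candidate local-parameter solutions
#'
#' Calibration of GADA/g-GADA models can produce several roots; the wrong
#' one is usually revealed by an inadmissible local parameter (for example
#' a negative asymptote), by a local value far outside the range observed
#' when the model was fitted, or by an inadmissible predicted curve.  This
#' screens a set of candidates against configurable bounds and the curve
#' admissibility check, breaking ties by smallest calibration residual.
#'
#' @param candidates Numeric vector of candidate driving-local values.
#' @param globals A [gada_globals()] or [ggada_globals()] object used to
#'   reconstruct the full curve per candidate (may be `NULL` to screen on
#'   bounds only).
#' @param bounds Length-2 admissible interval for the local parameter;
#'   `NULL` uses the package's default admissible ranges
#'   (`a0` in \[12.1933, 58.3228\], `b0` in \[63.5669, 433.68\],
#'   `c2` in \[-0.6133, -0.2371\]) when the driving local is one of these,
#'   otherwise no bound is applied.
#' @param residuals Optional calibration residuals (same length as
#'   `candidates`) used for tie-breaking.
#' @param t_range Age range (growth time) for the curve admissibility scan.
#' @return A tibble with one row per candidate: `value`, `residual`,
#'   `in_bounds`, `admissible`, `reason`, `selected`.
#' @export
screen_roots <- function(candidates, globals = NULL, bounds = NULL,
                         residuals = NULL, t_range = c(0.5, 250)) {
  if (length(candidates) < 1L) abort("at least one candidate is required.")
  residuals <- residuals %||% rep(0, length(candidates))
  local_nm <- NULL
  if (!is.null(globals)) {
    relation <- if (inherits(globals, "gada_globals")) "gada_equivalent"
                else globals$relation
    local_nm <- .ggada_local_name(globals$family, relation)
  }
  if (is.null(bounds) && !is.null(local_nm)) {
    rng <- .si_local_range[[globals$family]]
    if (local_nm %in% names(rng)) bounds <- unname(rng)
  }
  rows <- purrr::map2_dfr(candidates, residuals, function(v, r) {
    in_b <- is.null(bounds) || (v >= bounds[1] && v <= bounds[2])
    adm <- TRUE; reason <- ""
    if (!is.finite(v)) { adm <- FALSE; reason <- "non-finite candidate" }
    else if (!is.null(globals)) {
      pr <- tryCatch(ggada_local_to_params(v, globals), error = function(e) NULL)
      if (is.null(pr)) { adm <- FALSE; reason <- "relation undefined at candidate" }
      else {
        chk <- admissible_prediction_check(pr, t_range)
        if (!chk$pass) { adm <- FALSE; reason <- paste(chk$reasons, collapse = "; ") }
      }
    }
    if (adm && !in_b) reason <- "outside admissible local-parameter range"
    tibble(value = v, residual = r, in_bounds = in_b,
           admissible = adm && in_b, reason = reason)
  })
  rows$curve_admissible <- rows$admissible | (!rows$in_bounds &
    rows$reason == "outside admissible local-parameter range")
  rows$selected <- FALSE
  ok <- which(rows$admissible)
  if (length(ok) == 0L) {
    # the published local ranges are advisory; fall back to candidates whose
    # curves are admissible, with a warning
    ok <- which(rows$curve_admissible)
    if (length(ok) == 0L)
      abort(paste("no admissible candidate local parameter; candidates:",
                  paste(sprintf("%.4g (%s)", rows$value, rows$reason),
                        collapse = ", ")))
    warn(paste("all candidate local parameters fall outside the admissible",
               "range observed in fitting; selecting the best",
               "curve-admissible candidate -- inspect the predicted curve."))
  }
  rows$selected[ok[which.min(rows$residual[ok])]] <- TRUE
  rows
}

#' Calibrate a fitted site index model to a new tree
#'
#' Estimates the local parameter(s) of a new tree from one or more observed
#' height-age pairs, using the fitted global parameters:
#'
#' * GADA models with a single observation use the closed-form
#'   growth-intensity solution (the curve is anchored exactly through the
#'   point); with several observations the initial height `y0` is estimated
#'   by least squares over all points.
#' * g-GADA models solve a one-dimensional least-squares problem in the
#'   driving local parameter (a dense grid of starts across the admissible
#'   range followed by local polishing; all local minima are retained as
#'   candidates and screened with [screen_roots()]).  Multiple observations
#'   enter the same objective, making this a multipoint method.
#' * Indicator models need at least as many observations as local
#'   parameters (one pair per parameter to estimate) and solve a per-tree
#'   least-squares problem.
#' * Mixed-effects models delegate to [predict_random_effects()].
#'
#' @param data Data frame of calibration observations with columns `bh_age`
#'   (years) and `height` (m).
#' @param model An `si_fit`, `si_mixed_fit` or [si_model()] object.
#' @param bounds Optional length-2 search/screening interval for the
#'   driving local parameter (defaults to the package's admissible ranges).
#' @param root For single-point GADA calibration: which branch(es) of the
#'   growth-intensity quadratic to consider.
#' @param n_grid Grid resolution of the g-GADA start search.
#' @return An object of class `si_calibration`.
#' @export
calibrate <- function(data, model, bounds = NULL,
                      root = c("positive", "both", "negative"), n_grid = 101) {
  root <- arg_match(root)
  if (inherits(model, "si_mixed_fit")) {
    eb <- predict_random_effects(model, data)
    return(structure(list(
      local = eb$u, params = eb$params, method = "empirical_bayes",
      candidates = tibble(value = NA_real_, residual = NA_real_,
                          in_bounds = NA, admissible = TRUE,
                          reason = "", selected = TRUE),
      obs = as_tibble(data[c("bh_age", "height")]), model = model$family),
      class = "si_calibration"))
  }
  if (inherits(model, "si_fit")) model <- as_si_model(model)
  stopifnot(inherits(model, "si_model"))
  if (!all(c("bh_age", "height") %in% names(data)))
    abort("`data` needs columns `bh_age` and `height`.")
  obs <- tibble(bh_age = data$bh_age, height = data$height)
  t_obs <- bh_age_to_t(obs$bh_age)
  fam <- model$family

  if (model$parameterization == "indicator") {
    k <- length(model$local_set)
    if (nrow(obs) < k)
      abort(sprintf(
        "indicator calibration needs at least %d observations (one per local parameter), got %d.",
        k, nrow(obs)))
    dat1 <- .si_data(tibble(tree_id = "cal", bh_age = obs$bh_age,
                            height = obs$height), min_obs = k)
    m <- .model_indicator(dat1, fam, model$local_set)
    g <- as.list(model$coef)
    objf <- function(tt) m$sse(g, m$theta_inv(tt, g))$sse
    th0 <- m$theta_fwd(m$theta_init, g)
    res <- .newton_vec(objf, th0, m$theta_lower, m$theta_upper,
                       maxit = 80, tol = 1e-11)
    fin <- m$sse(g, m$theta_inv(res$theta, g))
    locals <- setNames(numeric(0), character(0))
    for (j in seq_along(m$nonlin)) locals[m$nonlin[j]] <- m$theta_inv(res$theta, g)[1, j]
    if (m$profile_scale) locals[.scale_par[[fam]]] <- fin$scale[1]
    pv <- c(unlist(g), locals)[.si_par_names[[fam]]]
    params <- do.call(base_params, c(list(family = fam), as.list(pv)))
    return(structure(list(
      local = locals, params = params, method = "nonlinear",
      candidates = tibble(value = unname(locals[1]), residual = fin$sse[1],
                          in_bounds = NA, admissible = TRUE, reason = "",
                          selected = TRUE),
      obs = obs, model = fam), class = "si_calibration"))
  }

  if (model$parameterization == "gada") {
    g <- do.call(gada_globals, c(list(family = fam), as.list(model$coef)))
    if (nrow(obs) == 1L) {
      roots <- if (root == "both") c("positive", "negative") else root
      cand <- vapply(roots, function(rt)
        tryCatch(solve_chi0(g, t_obs, obs$height, root = rt),
                 error = function(e) NA_real_), numeric(1))
      # express candidates as the driving local of the equivalent relation
      loc_of_chi <- switch(fam, CR = exp(cand), HIV = g$b00 + cand, SCH = cand)
      resid <- vapply(seq_along(cand), function(i) {
        if (!is.finite(cand[i])) return(Inf)
        p <- .gada_pvec(g, cand[i])
        h <- .h_pred(fam, p$p0, p$p1, p$p2, t_obs)
        sum((obs$height - h)^2)
      }, numeric(1))
      scr <- screen_roots(loc_of_chi, g, bounds = bounds, residuals = resid)
      sel <- which(scr$selected)
      chi <- unname(cand[sel])
      p <- .gada_pvec(g, chi)
      nm <- .si_par_names[[fam]]
      params <- do.call(base_params,
                        c(list(family = fam),
                          setNames(list(p$p0, p$p1, p$p2), nm)))
      return(structure(list(
        local = c(chi0 = chi), params = params, method = "closed_form",
        candidates = scr, obs = obs, model = fam), class = "si_calibration"))
    }
    # multipoint: least squares over y0 (anchored at the model's t0)
    sse_y0 <- function(ly) {
      y0 <- BH + exp(ly)
      chi <- tryCatch(solve_chi0(g, model$t0, y0), error = function(e) NA_real_)
      if (!is.finite(chi)) return(.PENALTY)
      p <- .gada_pvec(g, chi)
      h <- .h_pred(fam, p$p0, p$p1, p$p2, t_obs)
      if (any(!is.finite(h))) return(.PENALTY)
      sum((obs$height - h)^2)
    }
    o <- optimize(sse_y0, c(log(0.3), log(90)), tol = 1e-10)
    y0 <- BH + exp(o$minimum)
    chi <- solve_chi0(g, model$t0, y0)
    p <- .gada_pvec(g, chi)
    nm <- .si_par_names[[fam]]
    params <- do.call(base_params,
                      c(list(family = fam), setNames(list(p$p0, p$p1, p$p2), nm)))
    return(structure(list(
      local = c(y0 = y0, chi0 = chi), params = params, method = "nonlinear",
      candidates = tibble(value = y0, residual = o$objective, in_bounds = NA,
                          admissible = TRUE, reason = "", selected = TRUE),
      obs = obs, model = fam), class = "si_calibration"))
  }

  # g-GADA: 1-D least squares in the driving local parameter
  g <- do.call(ggada_globals,
               c(list(family = fam, relation = model$relation),
                 as.list(model$coef)))
  local_nm <- .ggada_local_name(fam, model$relation)
  if (is.null(bounds)) {
    rng <- .si_local_range[[fam]]
    bounds <- if (local_nm %in% names(rng)) unname(rng)
              else switch(fam, CR = c(2, 300), HIV = c(5, 3000), SCH = c(1, 8))
    # widen: fitted trees may sit slightly outside the published range
    bounds <- bounds + c(-0.5, 0.5) * abs(diff(bounds))
    if (fam != "SCH" || local_nm == "c0") bounds[1] <- max(bounds[1], 1e-3)
    if (local_nm == "c2") bounds <- c(min(bounds[1], -1.5), max(bounds[2], -0.05))
  }
  if (local_nm == "c2") bounds <- c(min(bounds), min(max(bounds), -1e-3))
  sse_loc <- function(v) {
    p <- .ggada_pvec(g, v)
    h <- .h_pred(fam, p$p0, p$p1, p$p2, t_obs)
    if (any(!is.finite(h))) return(.PENALTY)
    sum((obs$height - h)^2)
  }
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  fg <- vapply(grid, sse_loc, numeric(1))
  # local minima of the grid profile, polished within their brackets
  is_min <- which(fg < c(Inf, head(fg, -1)) & fg <= c(fg[-1], Inf) & fg < .PENALTY)
  if (length(is_min) == 0L)
    abort("g-GADA calibration found no admissible local parameter in the search range.")
  cand <- vapply(is_min, function(i) {
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, n_grid)]
    optimize(sse_loc, c(lo, hi), tol = 1e-12)$minimum
  }, numeric(1))
  if (nrow(obs) == 1L) {
    # a single point can be matched exactly; refine each candidate to
    # machine precision with a root solve of the anchoring equation
    fdiff <- function(v) {
      p <- .ggada_pvec(g, v)
      h <- .h_pred(fam, p$p0, p$p1, p$p2, t_obs)
      if (!is.finite(h)) NA_real_ else h - obs$height
    }
    stepw <- diff(bounds) / (n_grid - 1)
    cand <- vapply(cand, function(v) {
      lo <- v - stepw; hi <- v + stepw
      flo <- fdiff(lo); fhi <- fdiff(hi)
      if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0)
        tryCatch(uniroot(fdiff, c(lo, hi), tol = 1e-13)$root,
                 error = function(e) v)
      else v
    }, numeric(1))
  }
  cand <- cand[!duplicated(round(cand, 8))]
  resid <- vapply(cand, sse_loc, numeric(1))
  scr <- screen_roots(cand, g, bounds = NULL, residuals = resid)
  sel <- scr$value[scr$selected]
  params <- ggada_local_to_params(sel, g)
  structure(list(
    local = setNames(sel, local_nm), params = params, method = "nonlinear",
    candidates = scr, obs = obs, model = fam), class = "si_calibration")
}

#' @export
print.si_calibration <- function(x, ...) {
  cat(sprintf("<si_calibration> %s (%s): %s\n", x$model, x$method,
              paste(sprintf("%s = %.5g", names(x$local), x$local), collapse = ", ")))
  cat(sprintf("  %d observation(s); %d candidate(s), %d admissible\n",
              nrow(x$obs), nrow(x$candidates), sum(x$candidates$admissible)))
  cat(sprintf("  site index (bh age 50): %.2f m\n", site_index(x$params)))
  invisible(x)
}

#' Predict heights from a calibrated curve
#'
#' @param object An `si_calibration` object.
#' @param bh_age Breast-height ages (years) at which to predict.
#' @param ... Unused.
#' @return A tibble with columns `bh_age` and `height`.
#' @export
predict.si_calibration <- function(object, bh_age = seq(5, 250, 5), ...) {
  tibble(bh_age = bh_age,
         height = predict_height(object$params, bh_age_to_t(bh_age)))
}
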