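# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the global parameter estimates of a site index fit
#'
#' @param x An `si_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.si_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(x$se[names(x$coef)]))
}

#' @rdname tidy.si_fit
#' @export
tidy.si_mixed_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates),
         std.error = unname(x$estimate_se),
         effect = c(rep("fixed", 3),
                    rep("ran_pars", length(x$estimates) - 4), "resid"))
}

#' One-row fit summary
#'
#' @param x An `si_fit` or `si_mixed_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `family`, `parameterization`, `sigma2`,
#'   `logLik`, `AICc`, `k`, `nobs`, `n_trees`, `converged`.
#' @export
glance.si_fit <- function(x, ...) {
  tibble(family = x$family,
         parameterization = if (identical(x$parameterization, "ggada"))
           sprintf("ggada_%s", sub("gada_equivalent", "gada", x$relation))
         else x$parameterization,
         sigma2 = x$sigma2, logLik = x$loglik, AICc = x$aicc,
         k = x$n_params, nobs = x$n_obs, n_trees = x$n_trees,
         converged = x$converged)
}

#' @rdname glance.si_fit
#' @export
glance.si_mixed_fit <- glance.si_fit

#' Observation-level results of a site index fit
#'
#' @param x An `si_fit` or `si_mixed_fit` object.
#' @param ... Unused.
#' @return The model data with `.fitted` (predicted height, `NA` where the
#'   calibrated curve is inadmissible) and `.resid` columns.
#' @export
augment.si_fit <- function(x, ...) x$data

#' @rdname augment.si_fit
#' @export
augment.si_mixed_fit <- function(x, ...) x$data
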