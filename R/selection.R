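# AICc, parameter-count conventions, age-binned error profiles and the
# cross-parameterization comparison table.

#' Finite-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' For the profiled Gaussian fits in this package `-2 logLik` equals
#' `n (log(2 pi sigma2_hat) + 1)` with `sigma2_hat = SSE/n`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (see [count_parameters()] for
#'   the package's counting conventions).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) abort("AICc requires n > k + 1.")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Number of estimated parameters of a fit
#'
#' Counting conventions: the indicator-variable fit counts its globals plus
#' one value per local parameter per tree plus the residual variance; the
#' GADA fit counts its 3 globals, one `y0` per tree, and the variance; the
#' g-GADA fits count their 3 or 4 relation globals, one driving local per
#' tree, and the variance.  Mixed-effects fits count the fixed effects, the
#' free random-effect covariance entries and the residual variance; the
#' per-tree empirical-Bayes values are predictions, not parameters.
#'
#' @param fit An `si_fit` or `si_mixed_fit` object.
#' @return Integer parameter count `k`.
#' @export
count_parameters <- function(fit) {
  stopifnot(inherits(fit, c("si_fit", "si_mixed_fit")))
  fit$n_params
}

#' Age-binned prediction-error profile of a fit
#'
#' Computes residuals (observed minus predicted height) of a fitted model on
#' its own data and summarises them in breast-height-age bins (default 5
#' years, matching the measurement protocol), plus the overall mean error
#' with its standard error and a two-sided one-sample t-test of zero mean.
#' Observations the model cannot predict (inadmissible parameter
#' combinations) are excluded from the summaries and counted.
#'
#' @param fit An `si_fit` or `si_mixed_fit` object.
#' @param bin_width Bin width in years (bins end at multiples of
#'   `bin_width`).
#' @return An object of class `si_error_profile`: a tibble with one row per
#'   age bin (`bh_age` = bin upper end, `mean_error`, `sd_error`, `n`), with
#'   attributes `overall` (mean error, SE, t statistic, p value, n,
#'   n_excluded) and `label`.
#' @export
error_profile <- function(fit, bin_width = 5) {
  stopifnot(inherits(fit, c("si_fit", "si_mixed_fit")))
  d <- fit$data
  excl <- !is.finite(d$.fitted)
  r <- d$.resid[!excl]
  age <- d$bh_age[!excl]
  bin <- bin_width * ceiling(age / bin_width)
  prof <- tibble(bh_age = bin, error = r) %>%
    group_by(.data$bh_age) %>%
    summarise(mean_error = mean(.data$error),
              sd_error = sd(.data$error),
              n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$bh_age)
  tt <- if (length(r) > 1) t.test(r) else list(statistic = NA, p.value = NA)
  attr(prof, "overall") <- list(
    mean_error = mean(r), se = sd(r) / sqrt(length(r)),
    t = unname(tt$statistic), p_value = tt$p.value,
    zero_mean_at_05 = tt$p.value > 0.05,
    n = length(r), n_excluded = sum(excl))
  attr(prof, "label") <- sprintf("%s / %s", fit$family, fit$parameterization)
  class(prof) <- c("si_error_profile", class(prof))
  prof
}

#' @export
print.si_error_profile <- function(x, ...) {
  ov <- attr(x, "overall")
  cat(sprintf("<si_error_profile> %s: overall mean error %.3f m (SE %.3f), n = %d%s\n",
              attr(x, "label"), ov$mean_error, ov$se, ov$n,
              if (ov$n_excluded > 0) sprintf(", %d unpredictable obs excluded", ov$n_excluded) else ""))
  NextMethod()
}

.fit_data_digest <- function(fit) {
  d <- fit$data
  paste(digest_cols <- c(nrow(d),
        format(sum(as.numeric(factor(d$tree_id))), digits = 15),
        format(sum(d$bh_age), digits = 15),
        format(sum(d$height), digits = 15)), collapse = "|")
}

#' Compare fitted parameterizations on a common dataset
#'
#' Tabulates AICc, estimated residual variance (with its large-sample
#' standard error `sigma2 * sqrt(2/n)`), and the mean prediction error
#' (with standard error) for a set of fits, and expresses each fit's
#' variance as a percentage increase over the indicator-variable fit of the
#' same family (the most flexible parameterization, taken as the
#' benchmark): `100 * (sigma2 / sigma2_indicator - 1)`.
#'
#' Fits computed on different datasets are not comparable (a fit on fewer
#' observations realises a lower AICc and possibly a lower variance simply
#' because difficult trees were excluded); mixing datasets is an error.
#'
#' @param ... Two or more `si_fit` / `si_mixed_fit` objects, or a single
#'   list of them.
#' @return An object of class `si_comparison`: a tibble with one row per
#'   fit.
#' @export
comparison_report <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "si_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2L) abort("need at least two fits to compare.")
  ok <- vapply(fits, inherits, logical(1), what = c("si_fit", "si_mixed_fit"))
  if (!all(ok)) abort("all arguments must be si_fit or si_mixed_fit objects.")
  digests <- vapply(fits, .fit_data_digest, character(1))
  if (length(unique(digests)) > 1L)
    abort(paste("fits were computed on different datasets and are not",
                "comparable; compare only fits of the same data."))
  tab <- purrr::map_dfr(fits, function(f) {
    r <- f$data$.resid[is.finite(f$data$.resid)]
    tibble(
      family = f$family,
      parameterization = if (identical(f$parameterization, "ggada"))
        sprintf("ggada_%s", sub("gada_equivalent", "gada", f$relation))
      else f$parameterization,
      aicc = f$aicc,
      sigma2 = f$sigma2,
      sigma2_se = f$sigma2 * sqrt(2 / f$n_obs),
      mean_error = mean(r),
      mean_error_se = sd(r) / sqrt(length(r)),
      n_obs = f$n_obs,
      converged = f$converged)
  })
  tab <- tab %>%
    group_by(.data$family) %>%
    mutate(pct_variance_increase = {
      base <- .data$sigma2[.data$parameterization == "indicator"]
      if (length(base) >= 1) 100 * (.data$sigma2 / base[1] - 1) else NA_real_
    }) %>%
    ungroup() %>%
    arrange(.data$family, .data$aicc)
  class(tab) <- c("si_comparison", class(tab))
  tab
}

#' Percentage variance increase relative to a benchmark variance
#'
#' `100 * (sigma2 / sigma2_ref - 1)`, the summary used to compare the
#' relation-constrained parameterizations against the indicator-variable
#' benchmark.
#'
#' @param sigma2 Variance estimate(s).
#' @param sigma2_ref Benchmark variance.
#' @return Percentage increase(s).
#' @export
variance_increase_pct <- function(sigma2, sigma2_ref) {
  if (any(sigma2_ref <= 0)) abort("`sigma2_ref` must be positive.")
  100 * (sigma2 / sigma2_ref - 1)
}
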