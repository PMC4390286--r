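# ggplot2 graphics for fits, error profiles and local-parameter relations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an age-binned error profile
#'
#' Mean prediction error and standard deviation of the errors against
#' breast-height age, in two panels.
#'
#' @param object An `si_error_profile` from [error_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.si_error_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("mean_error", "sd_error"),
                              names_to = "stat", values_to = "value")
  long$stat <- factor(long$stat, c("mean_error", "sd_error"),
                      c("Mean error (m)", "SD of errors (m)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bh_age, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Breast-height age (years)", y = NULL,
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot observed trajectories with fitted curves
#'
#' @param object An `si_fit` or `si_mixed_fit` object.
#' @param n_trees Number of trees to display (sampled deterministically by
#'   spread of site index).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.si_fit <- function(object, n_trees = 12, ...) {
  d <- object$data
  ids <- unique(d$tree_id)
  if (length(ids) > n_trees)
    ids <- ids[round(seq(1, length(ids), length.out = n_trees))]
  d <- d[d$tree_id %in% ids, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bh_age, group = .data$tree_id)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$height), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "steelblue") +
    ggplot2::labs(x = "Breast-height age (years)", y = "Height (m)",
                  title = sprintf("%s / %s", object$family,
                                  object$parameterization)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.si_mixed_fit <- autoplot.si_fit

#' Plot the relation between per-tree local parameters
#'
#' Scatter of the indicator-variable local-parameter estimates for each
#' tree, with (optionally) the relation implied by a fitted g-GADA model
#' overlaid -- the diagnostic used to choose the optimal g-GADA relation.
#'
#' @param indicator_fit An indicator-parameterization `si_fit` with two
#'   local parameters.
#' @param ggada_fit Optional g-GADA `si_fit` whose relation to overlay.
#' @return A ggplot object.
#' @export
plot_local_relation <- function(indicator_fit, ggada_fit = NULL) {
  stopifnot(inherits(indicator_fit, "si_fit"),
            identical(indicator_fit$parameterization, "indicator"))
  loc <- indicator_fit$locals
  cols <- setdiff(names(loc), "tree_id")
  if (length(cols) < 2)
    abort("the indicator fit must have two local parameters to plot.")
  p <- ggplot2::ggplot(loc, ggplot2::aes(x = .data[[cols[1]]],
                                         y = .data[[cols[2]]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = cols[1], y = cols[2]) +
    ggplot2::theme_minimal()
  if (!is.null(ggada_fit)) {
    stopifnot(inherits(ggada_fit, "si_fit"),
              identical(ggada_fit$parameterization, "ggada"))
    g <- do.call(ggada_globals,
                 c(list(family = ggada_fit$family, relation = ggada_fit$relation),
                   as.list(ggada_fit$coef)))
    xr <- range(loc[[cols[1]]], na.rm = TRUE)
    drv <- seq(xr[1], xr[2], length.out = 200)
    pv <- .ggada_pvec(g, drv)
    nm <- .si_par_names[[ggada_fit$family]]
    rel <- tibble(x = drv,
                  y = list(pv$p0, pv$p1, pv$p2)[[match(cols[2], nm)]])
    p <- p + ggplot2::geom_line(data = rel,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "firebrick")
  }
  p
}
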