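# Run configuration and the one-call analysis pipeline.

#' Configuration of a full model-comparison run
#'
#' Bundles everything needed to reproduce a comparison run: the input (a
#' stem-analysis file, or settings for the synthetic generator), which
#' family x parameterization combinations to fit, optimizer settings, the
#' seed, and an optional output directory.  Configurations serialize
#' losslessly to YAML with [write_run_config()] / [read_run_config()].
#'
#' @param input Path to a delimited stem-analysis file
#'   (see [read_stem_analysis()]), or `NULL` to simulate.
#' @param families Base-function families to fit.
#' @param parameterizations Any of `"indicator"`, `"mixed"`, `"gada"`,
#'   `"ggada_gada"`, `"ggada_optimal"`.  The default reproduces the full
#'   3 x 5 comparison.
#' @param n_trees,sim_parameterization,sigma2 Synthetic-generator settings
#'   (used only when `input` is `NULL`); see [sim_config()].
#' @param seed Seed for simulation and optimizer multi-starts.
#' @param n_starts Multi-start count passed to [si_control()].
#' @param outdir Directory for [write_si_results()] output, or `NULL` to
#'   skip writing.
#' @return A list of class `si_run_config`.
#' @export
si_run_config <- function(input = NULL, families = c("CR", "HIV", "SCH"),
                          parameterizations = c("indicator", "mixed", "gada",
                                                "ggada_gada", "ggada_optimal"),
                          n_trees = 84, sim_parameterization = "indicator",
                          sigma2 = NULL, seed = 20150408, n_starts = 5,
                          outdir = NULL) {
  families <- vapply(families, match_family, character(1))
  bad <- setdiff(parameterizations,
                 c("indicator", "mixed", "gada", "ggada_gada", "ggada_optimal"))
  if (length(bad))
    abort(sprintf("unknown parameterization(s): %s.", paste(bad, collapse = ", ")))
  structure(list(input = input, families = unname(families),
                 parameterizations = parameterizations, n_trees = n_trees,
                 sim_parameterization = sim_parameterization, sigma2 = sigma2,
                 seed = seed, n_starts = n_starts, outdir = outdir),
            class = "si_run_config")
}

#' @rdname si_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(si_run_config, y[!vapply(y, is.null, logical(1))])
}

#' @rdname si_run_config
#' @param config An `si_run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "si_run_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run a family x parameterization comparison in one call
#'
#' Loads (or simulates) a stem-analysis dataset, fits every requested
#' family x parameterization combination, tabulates the comparison, and
#' optionally writes all result files.  Fits that fail are kept as `NULL`
#' with a warning rather than aborting the run.
#'
#' @param config An [si_run_config()] object.
#' @return A list with `data`, `fits` (named list), and `comparison` (a
#'   [comparison_report()] tibble, or `NULL` if fewer than two fits
#'   succeeded).
#' @export
run_comparison <- function(config = si_run_config()) {
  stopifnot(inherits(config, "si_run_config"))
  data <- if (!is.null(config$input)) read_stem_analysis(config$input)
  else simulate_trees(sim_config(n_trees = config$n_trees,
                                 parameterization = config$sim_parameterization,
                                 sigma2 = config$sigma2),
                      seed = config$seed)
  ctrl <- si_control(n_starts = config$n_starts, seed = config$seed)
  fits <- list()
  for (fam in config$families) for (pz in config$parameterizations) {
    tag <- sprintf("%s_%s", tolower(fam), pz)
    fits[[tag]] <- tryCatch(switch(pz,
      indicator = fit_indicator(data, fam, control = ctrl),
      mixed = fit_mixed(data, fam, control = si_control(n_starts = 1,
                                                        seed = config$seed)),
      gada = fit_gada(data, fam, control = ctrl),
      ggada_gada = fit_ggada(data, fam, "gada_equivalent", control = ctrl),
      ggada_optimal = fit_ggada(data, fam, "optimal", control = ctrl)),
      error = function(e) {
        warn(sprintf("fit %s failed: %s", tag, conditionMessage(e)))
        NULL
      })
  }
  ok <- fits[!vapply(fits, is.null, logical(1))]
  comparison <- if (length(ok) >= 2) comparison_report(ok) else NULL
  if (!is.null(config$outdir) && length(ok) >= 1)
    write_si_results(ok, config$outdir)
  list(data = data, fits = fits, comparison = comparison)
}
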