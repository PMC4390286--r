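# Reading stem-analysis data files and writing result tables.

#' Read a stem-analysis height-age file
#'
#' Reads delimited text with header columns `tree_id`, `bh_age` and
#' `height_m` (or `height`); extra columns (e.g. subzone labels) are kept.
#' The file is validated: missing columns, non-numeric fields, heights
#' below 1.3 m at breast-height age >= 1, and duplicated (tree, age)
#' records are errors reporting the offending rows.  Trees whose height
#' decreases between successive ages are loaded but flagged (the analogue
#' of plotting trajectories to screen for suppression or damage) with a
#' warning and a logical `qc_decreasing` column -- never silently dropped.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` guesses from the first line
#'   (comma, tab or semicolon).
#' @return A tibble with columns `tree_id`, `bh_age`, `height`, any extra
#'   columns, and `qc_decreasing`.
#' @export
read_stem_analysis <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    l1 <- readLines(path, n = 1)
    delim <- if (grepl("\t", l1)) "\t" else if (grepl(";", l1)) ";" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  if ("height_m" %in% names(raw) && !"height" %in% names(raw))
    raw <- dplyr::rename(raw, height = "height_m")
  need <- c("tree_id", "bh_age", "height")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(sprintf("missing column(s): %s.", paste(miss, collapse = ", ")))
  for (nm in c("bh_age", "height")) {
    v <- raw[[nm]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !all(is.na(v)))
        abort(sprintf("non-numeric `%s` in row(s) %s.", nm,
                      paste(head(which(is.na(conv) & !is.na(v)), 5), collapse = ", ")))
      raw[[nm]] <- conv
    }
    if (anyNA(raw[[nm]]))
      abort(sprintf("missing `%s` in row(s) %s.", nm,
                    paste(head(which(is.na(raw[[nm]])), 5), collapse = ", ")))
  }
  bad_h <- raw$bh_age >= 1 & raw$height < BH
  if (any(bad_h))
    abort(sprintf("height below 1.3 m at breast-height age >= 1 in row(s) %s.",
                  paste(head(which(bad_h), 5), collapse = ", ")))
  key <- paste(raw$tree_id, raw$bh_age)
  if (anyDuplicated(key))
    abort(sprintf("duplicated (tree_id, bh_age) record in row(s) %s.",
                  paste(head(which(duplicated(key)), 5), collapse = ", ")))
  out <- raw %>%
    group_by(.data$tree_id) %>%
    arrange(.data$bh_age, .by_group = TRUE) %>%
    mutate(qc_decreasing = any(diff(.data$height) < 0)) %>%
    ungroup()
  flagged <- unique(out$tree_id[out$qc_decreasing])
  if (length(flagged))
    warn(sprintf(
      "tree(s) %s have decreasing heights between successive ages (possible suppression or measurement damage); inspect trajectories before fitting.",
      paste(head(flagged, 5), collapse = ", ")))
  out
}

#' Write fitted-model result tables
#'
#' Writes, as headered CSV files into `dir`: a parameter table (one row per
#' global parameter and fit: estimate and standard error), a comparison
#' table from [comparison_report()] when two or more fits share the data,
#' one local-parameter table per fit, and one age-binned error profile per
#' fit.  All files round-trip losslessly through [readr::read_csv()].
#'
#' @param fits A single fit or list of `si_fit` / `si_mixed_fit` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
write_si_results <- function(fits, dir) {
  if (inherits(fits, c("si_fit", "si_mixed_fit"))) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), what = c("si_fit", "si_mixed_fit"))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tag <- function(f) {
    p <- if (identical(f$parameterization, "ggada"))
      sprintf("ggada_%s", sub("gada_equivalent", "gada", f$relation))
    else f$parameterization
    sprintf("%s_%s", tolower(f$family), p)
  }
  paths <- character()
  params <- purrr::map_dfr(fits, function(f) {
    td <- generics::tidy(f)
    td$family <- f$family
    td$parameterization <- tag(f)
    td[c("family", "parameterization", setdiff(names(td), c("family", "parameterization")))]
  })
  p1 <- file.path(dir, "parameters.csv")
  readr::write_csv(params, p1)
  paths <- c(paths, p1)
  if (length(fits) >= 2 &&
      length(unique(vapply(fits, .fit_data_digest, character(1)))) == 1L) {
    p2 <- file.path(dir, "comparison.csv")
    readr::write_csv(as_tibble(comparison_report(fits)), p2)
    paths <- c(paths, p2)
  }
  for (f in fits) {
    if (!is.null(f$locals) || !is.null(f$ranef)) {
      pl <- file.path(dir, sprintf("locals_%s.csv", tag(f)))
      readr::write_csv(f$locals %||% f$ranef, pl)
      paths <- c(paths, pl)
    }
    pe <- file.path(dir, sprintf("error_profile_%s.csv", tag(f)))
    readr::write_csv(as_tibble(error_profile(f)), pe)
    paths <- c(paths, pe)
  }
  invisible(paths)
}
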