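# Readers/writers for fish records, otolith tables and scenario configs,
# plus the end-to-end analysis and validation pipelines.

#' Read and write individual length records
#'
#' Records CSV schema: `date` (ISO `yyyy-mm-dd`), `tl_mm` (total length,
#' mm), optional `sl_mm`, `sex` and any extra columns, which round-trip
#' unchanged. On read, a month `label` (`yyyy-mm`) and a `year_fraction`
#' (365-day convention; see [year_fraction()]) are derived from the date.
#' Rows with non-positive or missing lengths are rejected with a message
#' naming them.
#'
#' @param path File path.
#' @param records A records tibble (from [read_length_records()] or
#'   [simulate_length_records()]).
#' @return `read_length_records()`: a tibble of validated records.
#'   `write_length_records()`: `path`, invisibly.
#' @export
read_length_records <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("date", "tl_mm") %in% names(raw)))
    rlang::abort("records CSV must have `date` and `tl_mm` columns.")
  bad <- which(is.na(raw$tl_mm) | raw$tl_mm <= 0)
  if (length(bad))
    rlang::abort(sprintf(
      "invalid total length in row(s) %s: lengths must be positive.",
      paste(utils::head(bad, 10), collapse = ", ")))
  d <- as.Date(raw$date)
  if (any(is.na(d)))
    rlang::abort(sprintf("unparseable date in row(s) %s.",
                         paste(utils::head(which(is.na(d)), 10), collapse = ", ")))
  doy <- as.integer(strftime(d, "%j"))
  dplyr::mutate(raw,
                date = as.character(d),
                label = strftime(d, "%Y-%m"),
                year_fraction = (pmin(doy, 365L) - 1) / 365)
}

#' @rdname read_length_records
#' @export
write_length_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read an otolith ageing table
#'
#' CSV schema: `fish_id`, `date`, `tl_mm`, `annuli`, and optionally
#' `reader1_age`, `reader2_age` (from which `reader_agreement` is derived
#' by equality) or a `reader_agreement` column directly. A `capture_time`
#' year fraction is derived from the date.
#'
#' @param path File path.
#' @return A tibble ready for [assign_otolith_ages()].
#' @export
read_otoliths <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("fish_id", "date", "tl_mm", "annuli")
  if (!all(need %in% names(raw)))
    rlang::abort(sprintf("otolith CSV must have columns: %s.",
                         paste(need, collapse = ", ")))
  d <- as.Date(raw$date)
  doy <- as.integer(strftime(d, "%j"))
  out <- dplyr::mutate(raw, capture_time = (pmin(doy, 365L) - 1) / 365)
  if (!"reader_agreement" %in% names(out) &&
      all(c("reader1_age", "reader2_age") %in% names(out)))
    out$reader_agreement <- out$reader1_age == out$reader2_age
  if (!"reader_agreement" %in% names(out)) out$reader_agreement <- TRUE
  out
}

#' Save or load a synthetic scenario as JSON
#'
#' A scenario file fully determines a simulation up to the random seed, so
#' a config plus a seed reproduces a run exactly.
#'
#' @param scenario An [lf_scenario()].
#' @param path File path (JSON).
#' @return `write_scenario()`: `path`, invisibly. `read_scenario()`: an
#'   `lf_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "lf_scenario"))
  obj <- list(
    growth = unclass(scenario$growth),
    sigmas = scenario$sigmas,
    months = scenario$months,
    proportions = scenario$proportions,
    birth_date_sd = scenario$birth_date_sd,
    selectivity = scenario$selectivity
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lf_scenario(
    growth = do.call(growth_params, as.list(obj$growth)[c("L_inf", "K", "t0", "C", "t_s", "t_b")]),
    sigmas = obj$sigmas,
    months = tibble::as_tibble(obj$months),
    proportions = tibble::as_tibble(obj$proportions),
    birth_date_sd = obj$birth_date_sd %||% 0,
    selectivity = if (is.null(obj$selectivity) || !length(obj$selectivity)) NULL
                  else as.list(obj$selectivity)
  )
}

#' Fit the candidate set to length records
#'
#' End-to-end analysis: bins the records into monthly histograms, fits each
#' candidate model and tabulates AICc model selection. `L_inf` defaults to
#' the maximum observed length, the usual convention when length data carry
#' little information about asymptotic size.
#'
#' @param records Records tibble (`label`, `tl_mm`, ...), real or
#'   synthetic.
#' @param specs Named list of [lf_model_spec()]s; defaults to the standard
#'   2x2 candidate set with `L_inf` fixed at the maximum observed length.
#' @param grid A [bin_grid()].
#' @param months Optional months tibble; derived from records if `NULL`.
#' @param n_eff Effective sample size for AICc (default histogram cells).
#' @param ... Passed to [fit_lf()] (e.g. `n_starts`, `seed`).
#' @return A list of class `lf_analysis`: `fits` (named list), `selection`
#'   (an [select_models()] table), `histograms`, `months`, `n_records`,
#'   `tl_range`.
#' @export
fit_candidates <- function(records, specs = NULL, grid = bin_grid(),
                           months = NULL, n_eff = NULL, ...) {
  stopifnot(all(c("label", "tl_mm") %in% names(records)))
  if (is.null(specs))
    specs <- candidate_models(L_inf = max(records$tl_mm))
  histograms <- records_to_histograms(records, grid)
  if (is.null(months)) months <- months_from_histograms(histograms)
  fits <- purrr::imap(specs, function(sp, nm) {
    fit_lf(histograms, sp, months = months, grid = grid, ...)
  })
  structure(list(
    fits = fits,
    selection = select_models(fits, n_eff = n_eff),
    histograms = histograms, months = months,
    n_records = nrow(records),
    tl_range = range(records$tl_mm)
  ), class = "lf_analysis")
}

#' @export
print.lf_analysis <- function(x, ...) {
  cat(sprintf("<lf_analysis> %d records, TL %g-%g mm, %d months\n",
              x$n_records, x$tl_range[1], x$tl_range[2], nrow(x$months)))
  print(as.data.frame(x$selection), digits = 6)
  invisible(x)
}

#' Out-of-sample validation of a fitted growth model
#'
#' Predicts length-frequency histograms for holdout months that were not
#' used in fitting: growth parameters and dispersions are held at their
#' fitted values and only the holdout months' proportions-at-age are
#' re-estimated. Reports the bin-wise correlation between predicted and
#' observed counts per month.
#'
#' @param fit A training-set [fit_lf()] result.
#' @param holdout Records tibble for the holdout months.
#' @param grid Bin grid (defaults to the fit's grid).
#' @param ... Passed to the internal refit (e.g. `n_starts`, `seed`).
#' @return A list of class `lf_validation`: `histograms` (observed),
#'   `predicted`, `by_month` (tibble with per-month correlations),
#'   `proportions`.
#' @export
validate_fit <- function(fit, holdout, grid = NULL, ...) {
  stopifnot(inherits(fit, "lf_fit"))
  grid <- grid %||% fit$grid
  histograms <- records_to_histograms(holdout, grid)
  months <- months_from_histograms(histograms)
  fixed <- as.list(fit$theta[setdiff(fit$par_names, grep("^w_", fit$par_names, value = TRUE))])
  refit <- fit_lf(histograms, fit$spec, months = months, grid = grid,
                  fixed = fixed, ...)
  pred <- predict(refit)
  by_month <- dplyr::left_join(
    histograms, dplyr::select(pred, "label", "bin", "expected"),
    by = c("label", "bin")) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = sum(.data$count),
                     correlation = stats::cor(.data$count, .data$expected),
                     .groups = "drop")
  structure(list(histograms = histograms, predicted = pred,
                 by_month = by_month, proportions = refit$proportions),
            class = "lf_validation")
}

#' @export
print.lf_validation <- function(x, ...) {
  cat("<lf_validation>\n")
  print(as.data.frame(x$by_month), digits = 3)
  invisible(x)
}

#' Write paper-style result tables
#'
#' Writes three CSVs to `dir`: the model-selection table, the parameter
#' estimates of each candidate, and the per-month proportions-at-age of the
#' best model with its weighted-mean row.
#'
#' @param analysis An [fit_candidates()] result.
#' @param dir Output directory (created if needed).
#' @return The paths, invisibly.
#' @export
write_fit_tables <- function(analysis, dir) {
  stopifnot(inherits(analysis, "lf_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "model_selection.csv")
  readr::write_csv(tibble::as_tibble(analysis$selection), p1, progress = FALSE)
  pars <- purrr::imap_dfr(analysis$fits, function(f, nm) {
    tibble::tibble(model = nm, !!!as.list(coef(f)),
                   L_inf = f$params$L_inf, neg_log_lik = f$neg_log_lik)
  })
  p2 <- file.path(dir, "parameters.csv")
  readr::write_csv(pars, p2, progress = FALSE)
  best <- analysis$fits[[which.min(analysis$selection$AICc)]]
  p3 <- file.path(dir, "proportions_at_age.csv")
  readr::write_csv(proportions_at_age(best), p3, progress = FALSE)
  invisible(c(p1, p2, p3))
}
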