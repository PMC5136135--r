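# Shared fixtures, all built in code at test time.

# Best-fit growth parameters of the northeast Florida study population.
gp_study <- function() {
  growth_params(L_inf = 448, K = 0.47, t0 = 0, C = 0.61, t_s = 0.21, t_b = 0.41)
}

study_sigmas <- function() c(26.29, 27.48, 24.13, 40.30)

# A reduced scenario that fits in a couple of seconds: three informative
# months, moderate dispersion.
small_scenario <- function(sigmas = c(8, 8, 8, 8)) {
  months <- tibble::tibble(
    label = c("2014-04", "2014-08", "2014-11"),
    year = 2014L, month = c(4L, 8L, 11L),
    sample_time = year_fraction(c(4L, 8L, 11L), 15),
    n = c(400L, 500L, 200L)
  )
  props <- tibble::tibble(
    label = rep(months$label, each = 4),
    age = rep(0:3, 3),
    p = c(0.35, 0.45, 0.15, 0.05,
          0.10, 0.50, 0.30, 0.10,
          0.20, 0.40, 0.30, 0.10)
  )
  lf_scenario(growth = gp_study(), sigmas = sigmas,
              months = months, proportions = props)
}

quiet_hist <- function(records, ...) {
  suppressWarnings(records_to_histograms(records, ...))
}

# One small fitted model, computed once per test run and reused.
.fixture_env <- new.env(parent = emptyenv())
get_small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    recs <- simulate_length_records(small_scenario(), seed = 101)
    .fixture_env$hist <- quiet_hist(recs)
    .fixture_env$fit <- fit_lf(
      .fixture_env$hist, lf_model_spec(TRUE, "variable", L_inf = 448),
      n_starts = 2, seed = 5)
  }
  .fixture_env$fit
}
get_small_hist <- function() {
  invisible(get_small_fit())
  .fixture_env$hist
}
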