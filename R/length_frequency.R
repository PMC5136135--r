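# Length-frequency forward model: fixed 10-mm bin grids, cohort ages at
# sampling dates, normal bin masses and predicted monthly histograms.

#' Length-bin grid
#'
#' Contiguous half-open 10-mm total-length bins `[lower, lower + width)`.
#' The default grid has 46 bins covering 0-460 mm, which comfortably spans
#' observed lionfish lengths (41-448 mm).
#'
#' @param n_bins Number of bins (default 46).
#' @param width Bin width in mm (default 10).
#' @param start Lower edge of the first bin in mm (default 0).
#' @return A tibble with columns `bin`, `bin_lower`, `bin_upper`, of class
#'   `bin_grid`.
#' @examples
#' bin_grid()
#' @export
bin_grid <- function(n_bins = 46, width = 10, start = 0) {
  stopifnot(n_bins >= 1, width > 0)
  lower <- start + width * (seq_len(n_bins) - 1)
  tibble::new_tibble(
    tibble::tibble(bin = seq_len(n_bins), bin_lower = lower, bin_upper = lower + width),
    class = "bin_grid"
  )
}

#' Cohort age at a sampling time
#'
#' Elapsed time since birth for an age class sampled at a given point of the
#' calendar year, under a single annual recruitment pulse at `t_b`. A
#' cohort's age class increments at its birthday, so when the sampling time
#' falls before `t_b` within the year the fractional part wraps: the age is
#' `((sample_time - t_b) mod 1) + age_class`.
#'
#' @param sample_time Sampling time(s) as fraction(s) of the calendar year.
#' @param t_b Cohort birth date (fraction of year).
#' @param age_class Integer age class(es), 0-based.
#' @return Age(s) in years.
#' @examples
#' cohort_age(0.04, 0.41, 0)  # mid-January, young of the year: 0.63 yr
#' @export
cohort_age <- function(sample_time, t_b, age_class) {
  if (any(age_class < 0)) rlang::abort("`age_class` must be >= 0.")
  (sample_time - t_b) %% 1 + age_class
}

#' Probability mass of a normal length distribution on a bin
#'
#' `P(lower <= L < upper)` for `L ~ Normal(mean, sd^2)`, the building block
#' of the mixture prediction. Vectorized over all arguments.
#'
#' @param mean Mean length(s), mm.
#' @param sd Standard deviation(s), mm; must be positive.
#' @param lower,upper Bin edges, mm.
#' @return Probabilities in `[0, 1]`.
#' @export
bin_mass <- function(mean, sd, lower, upper) {
  if (any(sd <= 0)) rlang::abort("`sd` must be positive.")
  stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
}

# Core forward model on matrices, shared by predict_lf() and the likelihood.
# means: n_ages x n_months matrix of mean lengths; sigmas: length n_ages;
# P: n_ages x n_months proportions (columns need not be normalized here);
# N: length n_months totals. Returns n_bins x n_months expected counts.
predict_counts_matrix <- function(means, sigmas, P, N, edges) {
  n_ages <- nrow(means); n_months <- ncol(means); n_bins <- length(edges) - 1L
  out <- matrix(0, n_bins, n_months)
  for (a in seq_len(n_ages)) {
    cdf <- stats::pnorm(outer(edges, means[a, ], "-") / sigmas[a])
    mass <- cdf[-1L, , drop = FALSE] - cdf[-(n_bins + 1L), , drop = FALSE]
    out <- out + mass * rep(P[a, ] * N, each = n_bins)
  }
  out
}

# Normalize a long proportions tibble (label, age, p) into an
# n_ages x n_months matrix aligned with `labels`.
proportions_matrix <- function(proportions, labels, n_ages = 4) {
  stopifnot(all(c("label", "age", "p") %in% names(proportions)))
  P <- matrix(0, n_ages, length(labels), dimnames = list(0:(n_ages - 1), labels))
  for (i in seq_len(nrow(proportions))) {
    lab <- as.character(proportions$label[i])
    if (!lab %in% labels) next
    P[proportions$age[i] + 1L, lab] <- proportions$p[i]
  }
  P
}

#' Predict monthly length-frequency histograms
#'
#' Forward model mapping growth parameters, proportions-at-age and
#' per-age-class length dispersions to expected counts per length bin for
#' each sampling month: the expected number of age-`a` fish in bin `i` of
#' month `t` is `N_t * P_{a,t} * P(bin i | Normal(Lbar_{a,t}, sigma_a^2))`,
#' and bins sum the contributions of all age classes.
#'
#' @param months A tibble with one row per sampling month: columns `label`,
#'   `sample_time` (fraction of year) and `n` (total fish captured).
#' @param params A [growth_params()] object (its `t_b` defines cohort ages).
#' @param proportions Long tibble of proportions-at-age: columns `label`,
#'   `age` (0-based) and `p`. Proportions are normalized within each month.
#' @param sigmas Per-age-class standard deviations (mm); either one value
#'   per age class or a single shared value.
#' @param grid A [bin_grid()].
#' @param seasonal Use the seasonal growth form (default `TRUE`).
#' @param by_age If `TRUE`, return the per-age-class decomposition.
#' @param n_ages Number of age classes (default 4, ages 0-3).
#' @return A tibble with columns `label`, `bin`, `bin_lower`, `bin_upper`,
#'   `expected` (and `age` when `by_age = TRUE`).
#' @examples
#' gp <- growth_params(448, 0.47, C = 0.61, t_s = 0.21, t_b = 0.41)
#' months <- tibble::tibble(label = "2014-04",
#'                          sample_time = year_fraction(4, 15), n = 850)
#' props <- tibble::tibble(label = "2014-04", age = 0:3,
#'                         p = c(0.37, 0.62, 0, 0.02))
#' ph <- predict_lf(months, gp, props, sigmas = c(26.3, 27.5, 24.1, 40.3))
#' sum(ph$expected)  # slightly below 850: normal tail mass outside the grid
#' @export
predict_lf <- function(months, params, proportions, sigmas,
                       grid = bin_grid(), seasonal = TRUE,
                       by_age = FALSE, n_ages = 4) {
  stopifnot(inherits(params, "growth_params"))
  stopifnot(all(c("label", "sample_time", "n") %in% names(months)))
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, n_ages)
  if (length(sigmas) != n_ages)
    rlang::abort("`sigmas` must have one value per age class, or a single shared value.")
  if (any(sigmas <= 0)) rlang::abort("`sigmas` must be positive.")

  labels <- as.character(months$label)
  P <- proportions_matrix(proportions, labels, n_ages)
  csum <- colSums(P)
  P <- sweep(P, 2, ifelse(csum > 0, csum, 1), "/")
  ages <- outer(0:(n_ages - 1), cohort_age(months$sample_time, params$t_b, 0), "+")
  means <- matrix(vbgf_length(params, as.vector(ages), seasonal = seasonal),
                  n_ages, length(labels))
  edges <- c(grid$bin_lower, grid$bin_upper[nrow(grid)])

  if (by_age) {
    res <- purrr::map_dfr(seq_len(n_ages), function(a) {
      cnt <- predict_counts_matrix(means[a, , drop = FALSE], sigmas[a],
                                   matrix(P[a, ], 1), months$n, edges)
      tibble::tibble(
        label = rep(labels, each = nrow(grid)),
        age = a - 1L,
        bin = rep(grid$bin, length(labels)),
        bin_lower = rep(grid$bin_lower, length(labels)),
        bin_upper = rep(grid$bin_upper, length(labels)),
        expected = as.vector(cnt)
      )
    })
    return(res)
  }
  cnt <- predict_counts_matrix(means, sigmas, P, months$n, edges)
  tibble::tibble(
    label = rep(labels, each = nrow(grid)),
    bin = rep(grid$bin, length(labels)),
    bin_lower = rep(grid$bin_lower, length(labels)),
    bin_upper = rep(grid$bin_upper, length(labels)),
    expected = as.vector(cnt)
  )
}

#' Bin individual length records into monthly histograms
#'
#' Aggregates fish records into integer counts on a fixed bin grid, one
#' histogram per sampling month (`label`). Binning is half-open: a length
#' equal to a bin's lower edge belongs to that bin. Lengths outside the grid
#' are reported via a warning and the `n_outside` attribute, never silently
#' dropped.
#'
#' @param records Tibble of fish records with columns `label` (month,
#'   e.g. `"2014-04"`) and `tl_mm` (total length, mm).
#' @param grid A [bin_grid()].
#' @return Long tibble with columns `label`, `bin`, `bin_lower`,
#'   `bin_upper`, `count`; attribute `n_outside` counts out-of-range fish.
#' @export
records_to_histograms <- function(records, grid = bin_grid()) {
  stopifnot(all(c("label", "tl_mm") %in% names(records)))
  edges <- c(grid$bin_lower, grid$bin_upper[nrow(grid)])
  labels <- sort(unique(as.character(records$label)))
  inside <- records$tl_mm >= edges[1] & records$tl_mm < edges[length(edges)]
  n_outside <- sum(!inside)
  if (n_outside > 0)
    rlang::warn(sprintf(
      "%d record(s) fall outside the bin grid [%g, %g) and were excluded from histograms.",
      n_outside, edges[1], edges[length(edges)]))
  kept <- records[inside, ]
  out <- tidyr::crossing(label = labels, bin = grid$bin) |>
    dplyr::left_join(grid, by = "bin")
  idx <- findInterval(kept$tl_mm, edges, rightmost.closed = FALSE)
  tab <- dplyr::count(
    tibble::tibble(label = as.character(kept$label), bin = idx),
    .data$label, .data$bin, name = "count")
  out <- dplyr::left_join(out, tab, by = c("label", "bin")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count))) |>
    dplyr::select("label", "bin", "bin_lower", "bin_upper", "count")
  attr(out, "n_outside") <- n_outside
  out
}

# Derive a months tibble (label, sample_time, n) from a histogram set,
# assuming mid-month sampling when dates are not supplied.
months_from_histograms <- function(histograms) {
  stopifnot(all(c("label", "count") %in% names(histograms)))
  agg <- histograms |>
    dplyr::group_by(label = as.character(.data$label)) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  parts <- strsplit(agg$label, "-", fixed = TRUE)
  mon <- vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  agg |>
    dplyr::mutate(
      year = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
      month = mon,
      sample_time = year_fraction(mon, 15)
    ) |>
    dplyr::select("label", "year", "month", "sample_time", "n")
}
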