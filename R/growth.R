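# Growth kernel: traditional and seasonalized (Somers) von Bertalanffy growth,
# calendar conversions, and annulus-age reconciliation.

#' Von Bertalanffy growth parameters
#'
#' Bundle the parameters of a (seasonalized) von Bertalanffy growth function
#' (VBGF) together with the cohort birth date. The seasonal form follows the
#' Somers convention: growth rate oscillates sinusoidally over the year, is
#' fastest at age-phase `t_s` and slowest half a year later at the winter
#' point `t_w = t_s + 0.5`.
#'
#' Ages are measured from birth (`t0 = 0` by default), so calendar time for a
#' cohort is `t_b + age`; `t_s` is expressed in the same age frame and the
#' calendar date of slowest growth is `(t_s + 0.5 + t_b) mod 1`.
#'
#' @param L_inf Asymptotic total length (mm); must be positive.
#' @param K Brody growth coefficient (1/yr); must be positive.
#' @param t0 Theoretical age at length zero (yr). Defaults to 0: with an
#'   estimated birth date the usual nuisance role of `t0` disappears.
#' @param C Intensity of the seasonal growth oscillation, in `[0, 1]`.
#'   `C = 0` gives the traditional VBGF; `C = 1` implies complete cessation
#'   of growth at the winter point.
#' @param t_s Seasonal phase (fraction of a year, age frame). Reduced
#'   modulo 1 into `[0, 1)`.
#' @param t_b Cohort birth date as a fraction of the calendar year. Reduced
#'   modulo 1 into `[0, 1)`.
#'
#' @return An object of class `growth_params` (a named list).
#' @examples
#' gp <- growth_params(L_inf = 448, K = 0.47, C = 0.61, t_s = 0.21, t_b = 0.41)
#' vbgf_length(gp, age = 1:3, seasonal = FALSE)
#' @export
growth_params <- function(L_inf, K, t0 = 0, C = 0, t_s = 0, t_b = 0) {
  if (!is.numeric(L_inf) || length(L_inf) != 1L || !is.finite(L_inf) || L_inf <= 0)
    rlang::abort("`L_inf` must be a single positive number (mm).")
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    rlang::abort("`K` must be a single positive number (1/yr).")
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C < 0 || C > 1)
    rlang::abort("`C` must lie in [0, 1].")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    rlang::abort("`t0` must be a single finite number (yr).")
  structure(
    list(
      L_inf = as.numeric(L_inf), K = as.numeric(K), t0 = as.numeric(t0),
      C = as.numeric(C), t_s = as.numeric(t_s) %% 1, t_b = as.numeric(t_b) %% 1
    ),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  L_inf = %.4g mm, K = %.4g /yr, t0 = %.4g yr\n", x$L_inf, x$K, x$t0))
  cat(sprintf("  seasonal: C = %.4g, t_s = %.4g (winter point t_w = %.4g)\n",
              x$C, x$t_s, winter_point(x)))
  cat(sprintf("  birth date t_b = %.4g (%s)\n", x$t_b,
              format_calendar(calendar_date(x$t_b))))
  invisible(x)
}

# Somers seasonal modulation term S(t) = (C K / 2 pi) sin(2 pi (t - t_s))
seasonal_term <- function(params, t) {
  (params$C * params$K / (2 * pi)) * sin(2 * pi * (t - params$t_s))
}

#' Mean length at age from the VBGF
#'
#' Evaluates the traditional VBGF
#' `L(t) = L_inf * (1 - exp(-K (t - t0)))` or its seasonalized (Somers) form
#' `L(t) = L_inf * (1 - exp(-(K (t - t0) + S(t) - S(t0))))` with
#' `S(t) = (C K / 2 pi) * sin(2 pi (t - t_s))`. The seasonal form reduces to
#' the traditional one when `C = 0`, and the two coincide at integer ages
#' when `t0 = 0` because the oscillation integrates to zero over whole years.
#'
#' @param params A [growth_params()] object.
#' @param age Age(s) in years; must be `>= t0`.
#' @param seasonal If `TRUE` (default) use the seasonalized form.
#' @return Mean total length(s) in mm.
#' @examples
#' gp <- growth_params(448, 0.47)
#' round(vbgf_length(gp, 1:3, seasonal = FALSE))  # 168 273 339
#' @export
vbgf_length <- function(params, age, seasonal = TRUE) {
  stopifnot(inherits(params, "growth_params"))
  if (any(age < params$t0 - 1e-12))
    rlang::abort("`age` must be >= t0: lengths are undefined before age t0.")
  q <- params$K * (age - params$t0)
  if (seasonal && params$C > 0)
    q <- q + seasonal_term(params, age) - seasonal_term(params, params$t0)
  params$L_inf * (1 - exp(-q))
}

#' Instantaneous growth rate dL/dt
#'
#' Derivative of [vbgf_length()] with respect to age. Under the Somers form
#' the rate is `(K + C K cos(2 pi (t - t_s))) * (L_inf - L(t))`: non-negative
#' for `C <= 1`, and exactly zero at the winter point `t_s + 0.5` (mod 1)
#' when `C = 1`.
#'
#' @inheritParams vbgf_length
#' @return Growth rate(s) in mm/yr.
#' @export
vbgf_rate <- function(params, age, seasonal = TRUE) {
  stopifnot(inherits(params, "growth_params"))
  if (any(age < params$t0 - 1e-12))
    rlang::abort("`age` must be >= t0.")
  k_t <- params$K
  if (seasonal && params$C > 0)
    k_t <- params$K * (1 + params$C * cos(2 * pi * (age - params$t_s)))
  k_t * (params$L_inf - vbgf_length(params, age, seasonal = seasonal))
}

#' Invert the traditional VBGF
#'
#' Closed-form age at which the traditional (non-seasonal) VBGF reaches a
#' given length: `t = t0 - log(1 - L / L_inf) / K`.
#'
#' @inheritParams vbgf_length
#' @param length Total length(s) in mm, with `0 <= length < L_inf`.
#' @return Age(s) in years.
#' @export
vbgf_inverse <- function(params, length) {
  stopifnot(inherits(params, "growth_params"))
  if (any(length < 0) || any(length >= params$L_inf))
    rlang::abort("`length` must satisfy 0 <= length < L_inf (no finite age otherwise).")
  params$t0 - log(1 - length / params$L_inf) / params$K
}

#' Winter point of the seasonal growth cycle
#'
#' The time of slowest growth. `winter_point()` returns it in the age frame
#' (`t_w = (t_s + 0.5) mod 1`); `winter_point_calendar()` shifts it by the
#' birth date onto the calendar (`(t_s + 0.5 + t_b) mod 1`) and renders a
#' month/day under the package's 365-day year convention.
#'
#' @inheritParams vbgf_length
#' @return `winter_point()`: a year fraction in `[0, 1)`.
#'   `winter_point_calendar()`: a one-row tibble with columns
#'   `year_fraction`, `month`, `day`, `label`.
#' @examples
#' gp <- growth_params(448, 0.47, C = 0.61, t_s = 0.21, t_b = 0.41)
#' winter_point_calendar(gp)  # 0.12 -> mid-February
#' @export
winter_point <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  (params$t_s + 0.5) %% 1
}

#' @rdname winter_point
#' @export
winter_point_calendar <- function(params) {
  frac <- (winter_point(params) + params$t_b) %% 1
  cd <- calendar_date(frac)
  tibble::tibble(
    year_fraction = frac, month = cd$month, day = cd$day,
    label = format_calendar(cd)
  )
}

#' Age at annulus formation
#'
#' Reconciles otolith annulus counts with the model chronology. Assuming
#' annuli are deposited at the winter point, the actual age at first-annulus
#' formation is `t_w + 1 - t_b`; each additional annulus adds one year.
#'
#' @inheritParams vbgf_length
#' @param annuli Number of annuli (>= 1).
#' @return Age(s) in years at deposition of the last annulus.
#' @examples
#' gp <- growth_params(448, 0.47, C = 0.61, t_s = 0.21, t_b = 0.41)
#' age_at_first_annulus(gp, 1)  # 1.30
#' age_at_first_annulus(gp, 3)  # 3.30
#' @export
age_at_first_annulus <- function(params, annuli = 1) {
  stopifnot(inherits(params, "growth_params"))
  if (any(annuli < 1)) rlang::abort("`annuli` must be >= 1.")
  winter_point(params) + 1 - params$t_b + (annuli - 1)
}

# ---- calendar plumbing: fixed 365-day (non-leap) year --------------------

.month_lengths <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_starts <- cumsum(c(0L, .month_lengths[-12]))  # day-of-year offset

#' Calendar/year-fraction conversions (365-day convention)
#'
#' The package measures within-year time as `(day_of_year - 1) / 365` under a
#' fixed non-leap calendar. `year_fraction()` maps month/day to a fraction;
#' `calendar_date()` maps a fraction back to the nearest month/day. The
#' round trip is exact; rendering a fraction quoted to two decimals is
#' faithful to about one day.
#'
#' @param month Month 1-12.
#' @param day Day of month.
#' @param year_fraction Fraction(s) of the year; reduced modulo 1.
#' @return `year_fraction()`: numeric fraction(s) in `[0, 1)`.
#'   `calendar_date()`: a tibble with `month` and `day` columns.
#' @examples
#' year_fraction(6, 2)          # early June, about 0.416
#' calendar_date(0.12)          # mid-February
#' @export
year_fraction <- function(month, day) {
  if (any(month < 1 | month > 12)) rlang::abort("`month` must be 1-12.")
  if (any(day < 1 | day > .month_lengths[month]))
    rlang::abort("`day` is outside the given month.")
  doy <- .month_starts[month] + day
  (doy - 1) / 365
}

#' @rdname year_fraction
#' @export
calendar_date <- function(year_fraction) {
  f <- year_fraction %% 1
  doy <- pmin(pmax(round(f * 365) + 1, 1), 365)
  month <- findInterval(doy - 1, .month_starts)
  day <- doy - .month_starts[month]
  tibble::tibble(month = as.integer(month), day = as.integer(day))
}

format_calendar <- function(cd) {
  sprintf("%s %d", month.name[cd$month], cd$day)
}
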