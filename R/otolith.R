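# Otolith validation: reconcile annulus counts with the model chronology
# and quantify agreement between fitted growth and observed size-at-age.

#' Assign model-chronology ages to otolith records
#'
#' Converts annulus counts to fractional ages under the assumption that
#' annuli are deposited at the winter point of the growth cycle. A fish
#' with one annulus was `t_w + 1 - t_b` years old when it formed; each
#' further annulus adds a year; the time elapsed from the most recent
#' winter point to the capture date is then added. Fish without annuli are
#' aged as time elapsed since the cohort birth date. Records whose two
#' independent readers disagreed are excluded (age `NA`, `used = FALSE`).
#'
#' @param otoliths Tibble with columns `capture_time` (fraction of year;
#'   see [year_fraction()]), `annuli` and optionally `reader_agreement`
#'   (default `TRUE`), `fish_id`, `tl_mm`.
#' @param params A [growth_params()] object from the fitted model.
#' @return The input tibble with `age` (yr) and `used` columns added.
#' @examples
#' gp <- growth_params(448, 0.47, C = 0.61, t_s = 0.21, t_b = 0.41)
#' oto <- tibble::tibble(capture_time = c(0.12, 0.12), annuli = c(1, 3))
#' assign_otolith_ages(oto, gp)$age  # 1.30, 3.30
#' @export
assign_otolith_ages <- function(otoliths, params) {
  stopifnot(inherits(params, "growth_params"))
  stopifnot(all(c("capture_time", "annuli") %in% names(otoliths)))
  if (any(otoliths$annuli < 0)) rlang::abort("`annuli` must be >= 0.")
  agree <- if ("reader_agreement" %in% names(otoliths))
    otoliths$reader_agreement else rep(TRUE, nrow(otoliths))
  tw_cal <- (winter_point(params) + params$t_b) %% 1  # calendar date of annuli
  ct <- otoliths$capture_time %% 1
  since_winter <- (ct - tw_cal) %% 1
  since_birth <- (ct - params$t_b) %% 1
  age <- ifelse(
    otoliths$annuli >= 1,
    age_at_first_annulus(params, pmax(otoliths$annuli, 1)) + since_winter,
    since_birth
  )
  out <- otoliths
  out$age <- ifelse(agree, age, NA_real_)
  out$used <- agree
  if (any(!agree))
    rlang::inform(sprintf(
      "%d otolith(s) excluded for reader disagreement; %d used.",
      sum(!agree), sum(agree)))
  out
}

#' Agreement between fitted growth and otolith size-at-age
#'
#' Assigns ages to the otolith set, evaluates the fitted (seasonal) growth
#' curve at those ages and summarises the residuals
#' `observed TL - predicted TL` as mean bias and RMSE.
#'
#' @inheritParams assign_otolith_ages
#' @param seasonal Evaluate the seasonal growth form (default `TRUE`).
#' @return A list of class `lf_agreement`: `records` (with `age`,
#'   `predicted`, `residual`), `n_used`, `n_excluded`, `bias`, `rmse`.
#' @export
growth_agreement <- function(otoliths, params, seasonal = TRUE) {
  stopifnot(all(c("tl_mm") %in% names(otoliths)) || nrow(otoliths) == 0)
  aged <- if (nrow(otoliths)) assign_otolith_ages(otoliths, params) else otoliths
  if (!nrow(otoliths) || !any(aged$used)) {
    return(structure(list(records = aged, n_used = 0L,
                          n_excluded = nrow(otoliths),
                          bias = NA_real_, rmse = NA_real_),
                     class = "lf_agreement"))
  }
  used <- aged[aged$used, ]
  used$predicted <- vbgf_length(params, used$age, seasonal = seasonal)
  used$residual <- used$tl_mm - used$predicted
  structure(list(
    records = used,
    n_used = nrow(used),
    n_excluded = sum(!aged$used),
    bias = mean(used$residual),
    rmse = sqrt(mean(used$residual^2))
  ), class = "lf_agreement")
}

#' @export
print.lf_agreement <- function(x, ...) {
  cat(sprintf("<lf_agreement> %d otoliths used, %d excluded\n",
              x$n_used, x$n_excluded))
  cat(sprintf("  bias = %.2f mm, RMSE = %.2f mm\n", x$bias, x$rmse))
  invisible(x)
}
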