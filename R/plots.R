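# ggplot2 figures: monthly histogram overlays, growth curves, otolith
# agreement.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed versus predicted length frequencies
#'
#' One panel per sampling month: observed counts as bars with the fitted
#' model's expected counts overlaid as a curve.
#'
#' @param object An [fit_lf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lf_fit
#' @export
autoplot.lf_fit <- function(object, ...) {
  obs <- object$data
  pred <- predict(object)
  ggplot2::ggplot(obs, ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70",
                      width = (obs$bin_upper - obs$bin_lower)[1]) +
    ggplot2::geom_line(data = pred, ggplot2::aes(y = .data$expected),
                       linewidth = 0.8) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "Total length (mm)", y = "Number of fish") +
    ggplot2::theme_minimal()
}

#' Growth-curve overlay
#'
#' Seasonal and traditional VBGF mean length-at-age, optionally with
#' otolith size-at-age points from [growth_agreement()].
#'
#' @param params A [growth_params()] object.
#' @param max_age Oldest age to draw (yr).
#' @param agreement Optional [growth_agreement()] result whose aged
#'   otoliths are plotted as points.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(params, max_age = 4, agreement = NULL) {
  ages <- seq(0, max_age, by = 0.01)
  df <- dplyr::bind_rows(
    tibble::tibble(age = ages, form = "seasonal",
                   tl_mm = vbgf_length(params, ages, seasonal = TRUE)),
    tibble::tibble(age = ages, form = "traditional",
                   tl_mm = vbgf_length(params, ages, seasonal = FALSE))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$tl_mm,
                                        linetype = .data$form)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (yr)", y = "Total length (mm)", linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(agreement) && agreement$n_used > 0)
    p <- p + ggplot2::geom_point(
      data = agreement$records,
      ggplot2::aes(.data$age, .data$tl_mm), inherit.aes = FALSE, alpha = 0.6)
  p
}

#' Holdout prediction overlay
#'
#' @param object An [validate_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lf_validation
#' @export
autoplot.lf_validation <- function(object, ...) {
  obs <- object$histograms
  ggplot2::ggplot(obs, ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70",
                      width = (obs$bin_upper - obs$bin_lower)[1]) +
    ggplot2::geom_line(data = object$predicted,
                       ggplot2::aes(y = .data$expected), linewidth = 0.8) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "Total length (mm)", y = "Number of fish") +
    ggplot2::theme_minimal()
}
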