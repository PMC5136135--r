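# Information-theoretic model selection: AIC, AICc, delta-AICc and Akaike
# weights over a candidate set of fits.

#' Akaike information criterion
#'
#' `AIC = 2K + 2(-ln L)`; `AICc` adds the small-sample correction
#' `2K(K + 1) / (n_eff - K - 1)`.
#'
#' @param neg_log_lik Negative log-likelihood at the optimum.
#' @param K_params Number of estimated parameters.
#' @param n_eff Effective sample size; must exceed `K_params + 1`.
#' @return A single number.
#' @examples
#' aic(648.92, 32)          # 1361.84
#' aicc(648.92, 32, 276)    # about 1370.53
#' @export
aic <- function(neg_log_lik, K_params) {
  2 * K_params + 2 * neg_log_lik
}

#' @rdname aic
#' @export
aicc <- function(neg_log_lik, K_params, n_eff) {
  if (any(n_eff <= K_params + 1))
    rlang::abort("`n_eff` must exceed `K_params + 1` for the AICc correction.")
  aic(neg_log_lik, K_params) + 2 * K_params * (K_params + 1) / (n_eff - K_params - 1)
}

#' Akaike weights
#'
#' Relative support for each model in a candidate set:
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` where `delta_i` is
#' each model's AICc difference from the best model. Accepts either raw
#' AICc values or deltas (the weights are invariant to a constant shift).
#'
#' @param delta_aicc Numeric vector of AICc values or AICc differences.
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(0, 12.72, 31.82, 34.07))
#' @export
akaike_weights <- function(delta_aicc) {
  d <- delta_aicc - min(delta_aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-selection table for a candidate set
#'
#' Tabulates `-ln(L)`, parameter count, AIC, AICc, delta-AICc and Akaike
#' weight for a set of fitted candidate models, ordered as given. The
#' effective sample size for AICc defaults to the number of histogram cells
#' (bins x months), the convention under which the candidate-set arithmetic
#' is self-consistent; the total number of fish is an alternative a caller
#' can supply explicitly.
#'
#' @param fits A (named) list of [fit_lf()] results on the same data.
#' @param n_eff Effective sample size for AICc (default: histogram cells).
#' @return A tibble of class `lf_selection` with one row per model.
#' @export
select_models <- function(fits, n_eff = NULL) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "lf_fit")))
  n_eff <- n_eff %||% fits[[1]]$n_eff
  nm <- names(fits) %||% paste0("model_", seq_along(fits))
  tab <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble::tibble(
      model = nm[i],
      seasonal = f$spec$seasonal,
      variance_at_age = f$spec$variance_at_age,
      neg_log_lik = f$neg_log_lik,
      K = f$K_params,
      AIC = aic(f$neg_log_lik, f$K_params),
      AICc = aicc(f$neg_log_lik, f$K_params, n_eff)
    )
  })
  tab <- tab |>
    dplyr::mutate(delta_AICc = .data$AICc - min(.data$AICc),
                  weight = akaike_weights(.data$AICc))
  out <- tibble::new_tibble(tab, class = "lf_selection")
  attr(out, "n_eff") <- n_eff
  out
}
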