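# broom-style tidiers for fitted objects and selection tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted length-based model
#'
#' One row per model parameter (growth, dispersions, and optionally the
#' per-month proportions-at-age), with whether each was estimated or fixed.
#'
#' @param x An [fit_lf()] result.
#' @param proportions Include the per-month proportion parameters
#'   (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `fixed`.
#' @method tidy lf_fit
#' @export
tidy.lf_fit <- function(x, proportions = FALSE, ...) {
  est <- coef(x)
  base <- tibble::tibble(
    term = c("L_inf", "t0", names(est)),
    estimate = c(x$params$L_inf, x$params$t0, unname(est)),
    fixed = c(!x$spec$free_L_inf, TRUE,
              names(est) %in% names(x$fixed))
  )
  if (!proportions) return(base)
  dplyr::bind_rows(base, tibble::tibble(
    term = paste0("p_", x$proportions$label, "_age", x$proportions$age),
    estimate = x$proportions$p,
    fixed = FALSE
  ))
}

#' Glance at a fitted length-based model
#'
#' @param x An [fit_lf()] result.
#' @param n_eff Effective sample size for AICc (default histogram cells).
#' @param ... Unused.
#' @return A one-row tibble: `neg_log_lik`, `K_params`, `AIC`, `AICc`,
#'   `n_eff`, `converged`, `n_evals`, `n_starts`.
#' @method glance lf_fit
#' @export
glance.lf_fit <- function(x, n_eff = NULL, ...) {
  n_eff <- n_eff %||% x$n_eff
  tibble::tibble(
    neg_log_lik = x$neg_log_lik,
    K_params = x$K_params,
    AIC = aic(x$neg_log_lik, x$K_params),
    AICc = aicc(x$neg_log_lik, x$K_params, n_eff),
    n_eff = n_eff,
    converged = x$converged,
    n_evals = x$n_evals,
    n_starts = nrow(x$starts)
  )
}

#' Tidy an otolith growth-agreement summary
#'
#' @param x A [growth_agreement()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_used`, `n_excluded`, `bias`, `rmse`.
#' @method glance lf_agreement
#' @export
glance.lf_agreement <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_excluded = x$n_excluded,
                 bias = x$bias, rmse = x$rmse)
}
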