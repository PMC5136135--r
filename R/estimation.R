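# Maximum-likelihood estimation: candidate model specs, likelihood kernels,
# bounded multi-start optimization, sensitivity and random-start diagnostics.

#' Candidate model specification
#'
#' Describes one member of the candidate set: seasonal versus non-seasonal
#' growth crossed with fixed versus variable variance in size-at-age, plus
#' the fitting choices (likelihood kernel, fixed parameters, age classes).
#' `L_inf` is fixed by default — length data rarely carry information about
#' asymptotic size and unconstrained fits drift to unrealistically large
#' values — and `t0` is fixed at 0 because the estimated birth date `t_b`
#' already plays the role of cohort origin.
#'
#' @param seasonal Logical; seasonalized VBGF if `TRUE`.
#' @param variance_at_age `"variable"` (one sigma per age class) or
#'   `"fixed"` (a single shared sigma).
#' @param objective Likelihood kernel: `"multinomial"` (default; per month
#'   `-sum_i n_i log p_i` with `p` the normalized predicted bin
#'   probabilities), `"poisson"` (independent Poisson counts), or
#'   `"normal"` (concentrated least squares on counts).
#' @param L_inf Asymptotic length to fix (mm); ignored if `free_L_inf`.
#' @param t0 Theoretical age at length 0, fixed (default 0).
#' @param free_L_inf If `TRUE`, estimate `L_inf` rather than fixing it.
#' @param n_ages Number of age classes present (default 4, ages 0-3).
#' @param eps Probability floor applied to predicted bin masses.
#' @return An object of class `lf_model_spec`.
#' @examples
#' lf_model_spec(seasonal = TRUE, variance_at_age = "variable")
#' @export
lf_model_spec <- function(seasonal = TRUE,
                          variance_at_age = c("variable", "fixed"),
                          objective = c("multinomial", "poisson", "normal"),
                          L_inf = 448, t0 = 0, free_L_inf = FALSE,
                          n_ages = 4, eps = 1e-12) {
  variance_at_age <- match.arg(variance_at_age)
  objective <- match.arg(objective)
  structure(
    list(seasonal = isTRUE(seasonal), variance_at_age = variance_at_age,
         objective = objective, L_inf = L_inf, t0 = t0,
         free_L_inf = isTRUE(free_L_inf), n_ages = as.integer(n_ages),
         eps = eps),
    class = "lf_model_spec"
  )
}

#' @export
print.lf_model_spec <- function(x, ...) {
  cat(sprintf(
    "<lf_model_spec> %s growth, %s variance-at-age, %s objective, L_inf %s\n",
    if (x$seasonal) "seasonal" else "non-seasonal", x$variance_at_age,
    x$objective,
    if (x$free_L_inf) "free" else sprintf("fixed at %g mm", x$L_inf)))
  invisible(x)
}

#' The four standard candidate models
#'
#' Seasonal/non-seasonal growth crossed with variable/fixed variance at age,
#' in the conventional order (model 1 = seasonal + variable).
#'
#' @inheritParams lf_model_spec
#' @return A named list of four [lf_model_spec()] objects.
#' @export
candidate_models <- function(objective = "multinomial", L_inf = 448, ...) {
  list(
    seasonal_variable = lf_model_spec(TRUE, "variable", objective, L_inf = L_inf, ...),
    seasonal_fixed = lf_model_spec(TRUE, "fixed", objective, L_inf = L_inf, ...),
    nonseasonal_variable = lf_model_spec(FALSE, "variable", objective, L_inf = L_inf, ...),
    nonseasonal_fixed = lf_model_spec(FALSE, "fixed", objective, L_inf = L_inf, ...)
  )
}

#' Count estimated parameters
#'
#' Parameter-counting convention for information criteria: free growth
#' parameters (seasonal: `K`, `C`, `t_s`, `t_b`; non-seasonal: `K`, `t_b`;
#' plus `L_inf` if freed), one sigma per age class (variable) or one shared
#' sigma (fixed), and one proportion per age class and month.
#'
#' @param spec An [lf_model_spec()].
#' @param n_months Number of sampling months.
#' @return Integer parameter count `K`.
#' @examples
#' count_parameters(lf_model_spec(TRUE, "variable"), n_months = 6)   # 32
#' count_parameters(lf_model_spec(FALSE, "fixed"), n_months = 6)     # 27
#' @export
count_parameters <- function(spec, n_months) {
  stopifnot(inherits(spec, "lf_model_spec"))
  growth <- if (spec$seasonal) 4L else 2L
  if (spec$free_L_inf) growth <- growth + 1L
  sig <- if (spec$variance_at_age == "variable") spec$n_ages else 1L
  growth + sig + spec$n_ages * as.integer(n_months)
}

# ---- parameter packing ----------------------------------------------------

# Free-parameter layout, bounds and defaults for a spec + month set.
par_layout <- function(spec, labels, L_max = NULL) {
  nm <- c("K", if (spec$seasonal) c("C", "t_s"), "t_b",
          if (spec$free_L_inf) "L_inf")
  lo <- c(0.01, if (spec$seasonal) c(0, 0), 0, if (spec$free_L_inf) 50)
  hi <- c(3, if (spec$seasonal) c(1, 1), 1, if (spec$free_L_inf) 2000)
  st <- c(0.5, if (spec$seasonal) c(0.5, 0.25), 0.5,
          if (spec$free_L_inf) max(450, L_max %||% 450))
  n_sig <- if (spec$variance_at_age == "variable") spec$n_ages else 1L
  sig_nm <- if (n_sig == 1L) "sigma" else paste0("sigma_", 0:(spec$n_ages - 1))
  nm <- c(nm, sig_nm)
  lo <- c(lo, rep(1, n_sig)); hi <- c(hi, rep(100, n_sig))
  st <- c(st, rep(25, n_sig))
  w_nm <- as.vector(outer(0:(spec$n_ages - 1), labels,
                          function(a, l) paste0("w_", l, "_", a)))
  nm <- c(nm, w_nm)
  lo <- c(lo, rep(1e-6, length(w_nm))); hi <- c(hi, rep(1, length(w_nm)))
  st <- c(st, rep(1 / spec$n_ages, length(w_nm)))
  names(lo) <- names(hi) <- names(st) <- nm
  list(names = nm, lower = lo, upper = hi, start = st, n_sig = n_sig)
}

# Split a full parameter vector into growth params, sigmas and the
# (column-unnormalized) weight matrix.
unpack_theta <- function(theta, spec, labels) {
  g <- list(L_inf = if (spec$free_L_inf) theta[["L_inf"]] else spec$L_inf,
            K = theta[["K"]], t0 = spec$t0,
            C = if (spec$seasonal) theta[["C"]] else 0,
            t_s = if (spec$seasonal) theta[["t_s"]] else 0,
            t_b = theta[["t_b"]])
  params <- structure(g, class = "growth_params")
  n_sig <- if (spec$variance_at_age == "variable") spec$n_ages else 1L
  sig_idx <- if (n_sig == 1L) "sigma" else paste0("sigma_", 0:(spec$n_ages - 1))
  sigmas <- unname(theta[sig_idx])
  if (n_sig == 1L) sigmas <- rep(sigmas, spec$n_ages)
  W <- matrix(theta[grepl("^w_", names(theta))], spec$n_ages, length(labels))
  list(params = params, sigmas = sigmas, W = W)
}

# Mean length-at-age matrix (ages x months) for a parameter vector.
means_from_theta <- function(theta, spec, s_time) {
  K <- theta[["K"]]; t_b <- theta[["t_b"]]
  L_inf <- if (spec$free_L_inf) theta[["L_inf"]] else spec$L_inf
  ages <- outer(0:(spec$n_ages - 1), (s_time - t_b) %% 1, "+")
  q <- K * (ages - spec$t0)
  if (spec$seasonal && theta[["C"]] > 0) {
    amp <- theta[["C"]] * K / (2 * pi)
    t_s <- theta[["t_s"]]
    q <- q + amp * (sin(2 * pi * (ages - t_s)) - sin(2 * pi * (spec$t0 - t_s)))
  }
  L_inf * (1 - exp(-q))
}

sigmas_from_theta <- function(theta, spec) {
  if (spec$variance_at_age == "variable")
    unname(theta[paste0("sigma_", 0:(spec$n_ages - 1))])
  else rep(unname(theta[["sigma"]]), spec$n_ages)
}

# Per-age in-grid bin-mass matrices: list over months is unnecessary since
# masses depend on (age, month) through the means; returns an
# (n_bins x n_ages x n_months) array.
mass_array <- function(means, sigmas, edges) {
  n_ages <- nrow(means); n_months <- ncol(means); n_bins <- length(edges) - 1L
  arr <- array(0, c(n_bins, n_ages, n_months))
  for (a in seq_len(n_ages)) {
    cdf <- stats::pnorm(outer(edges, means[a, ], "-") / sigmas[a])
    arr[, a, ] <- cdf[-1L, , drop = FALSE] - cdf[-(n_bins + 1L), , drop = FALSE]
  }
  arr
}

# Multinomial-EM estimate of proportions-at-age for one month: maximizes
# sum_i n_i log(mix_i / sum(mix)) over the simplex, accounting for normal
# tail mass outside the grid (truncated-mixture fixed point).
em_weights_month <- function(M, n, max_iter = 300, tol = 1e-9, init = NULL) {
  n_ages <- ncol(M)
  P <- init %||% rep(1 / n_ages, n_ages)
  N <- sum(n)
  if (N <= 0) return(P)
  s <- pmax(colSums(M), 1e-12)
  Ns <- N * s
  for (it in seq_len(max_iter)) {
    mix <- M %*% P + 1e-300
    u <- P * crossprod(M, n / mix)[, 1L]
    P_new <- u * (sum(P * s) / Ns)
    P_new[P_new < 1e-9] <- 1e-9
    P_new <- P_new / sum(P_new)
    delta <- max(abs(P_new - P))
    P <- P_new
    if (delta < tol) break
  }
  P
}

# Concentrated weights for every month given growth/sigma parameters.
# `init` (ages x months) warm-starts the EM, e.g. from the previous
# objective evaluation during optimization.
em_weights <- function(theta, spec, s_time, edges, obs, init = NULL) {
  means <- means_from_theta(theta, spec, s_time)
  sigmas <- sigmas_from_theta(theta, spec)
  arr <- mass_array(means, sigmas, edges)
  vapply(seq_len(ncol(means)),
         function(j) em_weights_month(arr[, , j], obs[, j],
                                      init = if (is.null(init)) NULL else init[, j]),
         numeric(spec$n_ages))
}

# ---- likelihood kernels ---------------------------------------------------

# Negative log-likelihood of an observed count matrix (bins x months) given
# a predicted expected-count matrix, under the chosen kernel. Constant terms
# in the data (log factorials) are dropped throughout.
nll_kernel <- function(obs, pred, N, objective, eps = 1e-12) {
  switch(objective,
    multinomial = {
      val <- 0
      for (j in seq_len(ncol(obs))) {
        if (N[j] <= 0) next
        p <- pred[, j] + eps
        p <- p / sum(p)
        val <- val - sum(obs[, j] * log(p))
      }
      val
    },
    poisson = sum(pred - obs * log(pred + eps)),
    normal = {
      r <- obs - pred
      0.5 * length(r) * log(mean(r^2) + eps)
    },
    rlang::abort("unknown objective"))
}

#' Negative log-likelihood of histograms under a forward prediction
#'
#' Compares observed and predicted histogram sets under the multinomial
#' (default), Poisson or concentrated-normal kernel; additive over months.
#' Data-dependent constants (log factorials) are dropped. Predicted bin
#' masses are floored at `eps` so zero-mass bins with observed counts
#' penalize heavily but never produce non-finite values.
#'
#' @param obs,pred Long histogram tibbles sharing `label`, `bin` and a
#'   `count` / `expected` column, as produced by [records_to_histograms()]
#'   and [predict_lf()].
#' @param objective `"multinomial"`, `"poisson"` or `"normal"`.
#' @param eps Probability floor.
#' @return A single number (negative log-likelihood, up to constants).
#' @export
histogram_nll <- function(obs, pred, objective = c("multinomial", "poisson", "normal"),
                          eps = 1e-12) {
  objective <- match.arg(objective)
  stopifnot(all(c("label", "bin", "count") %in% names(obs)))
  pcol <- if ("expected" %in% names(pred)) "expected" else "count"
  key_o <- paste(obs$label, obs$bin); key_p <- paste(pred$label, pred$bin)
  if (!setequal(key_o, key_p))
    rlang::abort("`obs` and `pred` must cover the same months and bins.")
  pred_match <- pred[[pcol]][match(key_o, key_p)]
  labs <- unique(as.character(obs$label))
  O <- sapply(labs, function(l) obs$count[obs$label == l])
  P <- sapply(labs, function(l) pred_match[obs$label == l])
  O <- matrix(O, ncol = length(labs)); P <- matrix(P, ncol = length(labs))
  nll_kernel(O, P, colSums(O), objective, eps)
}

# Build the fast objective function over the free-parameter vector.
make_objective <- function(obs, months, spec, grid) {
  labels <- as.character(months$label)
  edges <- c(grid$bin_lower, grid$bin_upper[nrow(grid)])
  N <- months$n
  s_time <- months$sample_time
  n_ages <- spec$n_ages
  force(obs)
  function(theta) {
    up <- unpack_theta(theta, spec, labels)
    p <- up$params
    ages <- outer(0:(n_ages - 1), (s_time - p$t_b) %% 1, "+")
    q <- p$K * ages
    if (spec$seasonal && p$C > 0) {
      amp <- p$C * p$K / (2 * pi)
      q <- q + amp * (sin(2 * pi * (ages - p$t_s)) - sin(2 * pi * (0 - p$t_s)))
    }
    means <- p$L_inf * (1 - exp(-q))
    W <- up$W
    cs <- colSums(W)
    W <- sweep(W, 2, ifelse(cs > 0, cs, 1), "/")
    scale_by <- if (spec$objective == "multinomial") rep(1, length(N)) else N
    pred <- predict_counts_matrix(means, up$sigmas, W, scale_by, edges)
    val <- nll_kernel(obs, pred, N, spec$objective, spec$eps)
    if (!is.finite(val)) val <- 1e10
    val
  }
}

# ---- fitting --------------------------------------------------------------

#' Fit a length-based, age-structured model
#'
#' Maximum-likelihood fit of a candidate model to monthly length-frequency
#' histograms. Growth parameters, per-age dispersions and per-month
#' proportions-at-age are estimated jointly by bounded quasi-Newton
#' (`L-BFGS-B`) from multiple starting points; the best local optimum found
#' is returned. Proportions are optimized as non-negative weights and
#' normalized to a simplex within each month, which leaves the multinomial
#' kernel unchanged and yields Table-style proportion outputs.
#'
#' @param histograms Long tibble of observed histograms (`label`, `bin`,
#'   `bin_lower`, `bin_upper`, `count`), e.g. from
#'   [records_to_histograms()].
#' @param spec An [lf_model_spec()].
#' @param months Optional months tibble (`label`, `sample_time`, `n`); when
#'   `NULL` it is derived from the histograms, assuming mid-month sampling.
#' @param n_starts Number of optimizer starts (first from `start` or the
#'   package default, the rest jittered by `jitter`).
#' @param jitter Multiplicative jitter (fraction) applied to generate the
#'   additional starts.
#' @param seed Optional integer seed making the jittered starts (and hence
#'   the whole fit) reproducible.
#' @param start Optional named start vector (see `par_names` of the result).
#' @param fixed Optional named list/vector of parameters to hold fixed,
#'   e.g. `list(K = 0.5)`; used by [sensitivity_fit()].
#' @param grid The [bin_grid()] of the histograms.
#' @param control Passed to [stats::optim()] (`maxit`, `factr` defaults
#'   500 and 1e8).
#' @return An object of class `lf_fit`; see [tidy.lf_fit()],
#'   [glance.lf_fit()], [proportions_at_age()], [autoplot.lf_fit()].
#' @examples
#' \donttest{
#' sc <- lf_scenario()
#' recs <- simulate_length_records(sc, seed = 1)
#' h <- records_to_histograms(recs)
#' fit <- fit_lf(h, lf_model_spec(TRUE, "variable"), n_starts = 3, seed = 1)
#' glance(fit)
#' }
#' @export
fit_lf <- function(histograms, spec = lf_model_spec(), months = NULL,
                   n_starts = 25, jitter = 0.25, seed = NULL, start = NULL,
                   fixed = NULL, grid = NULL, control = list()) {
  stopifnot(inherits(spec, "lf_model_spec"))
  if (is.null(grid)) {
    grid <- histograms |>
      dplyr::distinct(.data$bin, .data$bin_lower, .data$bin_upper) |>
      dplyr::arrange(.data$bin)
  }
  if (is.null(months)) months <- months_from_histograms(histograms)
  if (sum(months$n) <= 0)
    rlang::abort("at least one month must have a positive number of fish.")
  labels <- as.character(months$label)

  # observed counts matrix aligned bins x months
  obs <- matrix(0, nrow(grid), length(labels))
  for (j in seq_along(labels)) {
    hj <- histograms[as.character(histograms$label) == labels[j], ]
    obs[hj$bin, j] <- hj$count
  }

  layout <- par_layout(spec, labels)
  fn_full <- make_objective(obs, months, spec, grid)

  # fixed-parameter mask
  fixed <- unlist(fixed %||% list())
  if (length(fixed) && !all(names(fixed) %in% layout$names))
    rlang::abort("unknown parameter name(s) in `fixed`.")
  free <- setdiff(layout$names, names(fixed))
  base_full <- layout$start
  if (length(fixed)) base_full[names(fixed)] <- fixed
  fn <- function(th_free) {
    full <- base_full
    full[free] <- th_free
    fn_full(full)
  }

  start1 <- layout$start
  if (!is.null(start)) {
    if (is.null(names(start)) && length(start) == length(layout$names))
      names(start) <- layout$names
    start1[names(start)] <- start
  }
  start1 <- pmin(pmax(start1, layout$lower), layout$upper)
  if (length(fixed)) start1[names(fixed)] <- fixed

  draw_starts <- function() {
    lapply(seq_len(max(0, n_starts - 1)), function(i) {
      s <- start1 * stats::runif(length(start1), 1 - jitter, 1 + jitter)
      pmin(pmax(s, layout$lower), layout$upper)
    })
  }
  starts <- c(list(start1),
              if (is.null(seed)) draw_starts()
              else withr::with_seed(seed, draw_starts()))

  # finite-difference steps scaled to each parameter's range
  ndeps_for <- function(names) pmax(1e-6, 1e-4 * (layout$upper[names] - layout$lower[names]))
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e6), control)

  # Two-stage optimization per start: (A) profile the growth/dispersion
  # parameters with the per-month proportions concentrated out by a
  # multinomial EM inner loop, then (B) polish all free parameters jointly
  # under the requested objective.
  w_names <- grep("^w_", layout$names, value = TRUE)
  free_outer <- setdiff(free, w_names)
  edges <- c(grid$bin_lower, grid$bin_upper[nrow(grid)])
  s_time <- months$sample_time

  W_cache <- NULL
  with_em_weights <- function(full) {
    W <- em_weights(full, spec, s_time, edges, obs, init = W_cache)
    W_cache <<- W
    full[w_names] <- as.vector(W)
    full
  }
  fn_profile <- function(th_outer) {
    full <- base_full
    full[free_outer] <- th_outer
    fn_full(with_em_weights(full))
  }

  run_start <- function(s) {
    tryCatch({
      W_cache <<- NULL  # each start concentrates weights afresh
      full <- base_full
      full[free] <- s[free]
      evals <- 0L
      value <- Inf
      stage_b <- NULL
      for (cycle in 1:8) {
        if (length(free_outer)) {
          lo <- layout$lower[free_outer]; hi <- layout$upper[free_outer]
          # derivative-free sweep first (box-clamped) to find the right
          # basin, then bounded quasi-Newton to localize the optimum
          if (cycle == 1L && length(free_outer) > 1L) {
            fn_clamped <- function(th) fn_profile(pmin(pmax(th, lo), hi))
            nm <- stats::optim(full[free_outer], fn_clamped,
                               method = "Nelder-Mead",
                               control = list(maxit = 300))
            full[free_outer] <- pmin(pmax(nm$par, lo), hi)
            evals <- evals + unname(nm$counts[1])
          }
          stage_a <- stats::optim(full[free_outer], fn_profile,
                                  method = "L-BFGS-B", lower = lo, upper = hi,
                                  control = utils::modifyList(
                                    ctrl, list(ndeps = ndeps_for(free_outer))))
          full[free_outer] <- stage_a$par
          evals <- evals + unname(stage_a$counts[1])
        }
        full <- with_em_weights(full)
        stage_b <- stats::optim(full[free], fn, method = "L-BFGS-B",
                                lower = layout$lower[free],
                                upper = layout$upper[free],
                                control = utils::modifyList(
                                  ctrl, list(ndeps = ndeps_for(free))))
        evals <- evals + unname(stage_b$counts[1])
        full[free] <- stage_b$par
        if (value - stage_b$value < 1e-4) {
          # objective has stagnated across a full profile/joint cycle:
          # treat as converged even if the last inner run hit its own cap
          stage_b$convergence <- 0L
          value <- stage_b$value
          break
        }
        value <- stage_b$value
      }
      stage_b$counts[1] <- evals
      stage_b
    },
    error = function(e) list(par = s[free], value = Inf, convergence = 99L,
                             counts = c(0, 0), message = conditionMessage(e)))
  }
  runs <- lapply(starts, run_start)
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (!any(is.finite(values)))
    rlang::abort("optimizer failed from every starting point; no fit available.")
  best_i <- which.min(values)
  best <- runs[[best_i]]
  theta <- base_full
  theta[free] <- best$par

  up <- unpack_theta(theta, spec, labels)
  W <- up$W
  cs <- colSums(W)
  P <- sweep(W, 2, ifelse(cs > 0, cs, 1), "/")
  proportions <- tibble::tibble(
    label = rep(labels, each = spec$n_ages),
    age = rep(0:(spec$n_ages - 1), length(labels)),
    p = as.vector(P)
  )
  sig <- up$sigmas
  names(sig) <- paste0("age_", 0:(spec$n_ages - 1))

  structure(list(
    spec = spec, months = months, grid = grid, data = histograms,
    params = up$params, sigmas = sig, proportions = proportions,
    theta = theta, par_names = layout$names, fixed = as.list(fixed),
    free = free, bounds = list(lower = layout$lower, upper = layout$upper),
    neg_log_lik = best$value,
    K_params = count_parameters(spec, length(labels)),
    n_eff = nrow(grid) * length(labels),
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    n_evals = unname(best$counts[1]),
    start_point = starts[[best_i]],
    starts = tibble::tibble(
      start_id = seq_along(runs),
      neg_log_lik = values,
      convergence = vapply(runs, function(r) as.integer(r$convergence), integer(1))
    )
  ), class = "lf_fit")
}

#' @export
print.lf_fit <- function(x, ...) {
  cat(sprintf("<lf_fit> %s growth, %s variance, %s objective\n",
              if (x$spec$seasonal) "seasonal" else "non-seasonal",
              x$spec$variance_at_age, x$spec$objective))
  cat(sprintf("  -ln(L) = %.2f  K = %d params  %s\n", x$neg_log_lik, x$K_params,
              if (x$converged) "converged" else "NOT converged"))
  est <- coef(x)
  cat("  ", paste(sprintf("%s = %.3g", names(est), est), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.lf_fit <- function(object, ...) {
  p <- object$params
  est <- c(K = p$K,
           if (object$spec$seasonal) c(C = p$C, t_s = p$t_s),
           t_b = p$t_b,
           if (object$spec$free_L_inf) c(L_inf = p$L_inf))
  sig <- object$sigmas
  if (object$spec$variance_at_age == "fixed") c(est, sigma = unname(sig[1]))
  else c(est, stats::setNames(sig, paste0("sigma_", 0:(object$spec$n_ages - 1))))
}

#' @export
logLik.lf_fit <- function(object, ...) {
  structure(-object$neg_log_lik, df = object$K_params, class = "logLik")
}

#' Proportions-at-age table
#'
#' Per-month estimated proportions in each age class, in wide form, plus a
#' weighted-mean row computed as `sum(P_{a,m} * n_m) / N` over months.
#'
#' @param fit An [fit_lf()] result.
#' @param digits Optional rounding applied to the proportions first (use 2
#'   to reproduce tables quoted at two decimals).
#' @return A tibble with one row per month plus a `"weighted_mean"` row.
#' @export
proportions_at_age <- function(fit, digits = NULL) {
  stopifnot(inherits(fit, "lf_fit"))
  wide <- fit$proportions |>
    dplyr::mutate(p = if (is.null(digits)) .data$p else round(.data$p, digits)) |>
    tidyr::pivot_wider(names_from = "age", values_from = "p",
                       names_prefix = "age_") |>
    dplyr::left_join(dplyr::select(fit$months, "label", "n"), by = "label") |>
    dplyr::arrange(match(.data$label, fit$months$label))
  wm <- weighted_age_proportions(
    dplyr::left_join(fit$proportions, dplyr::select(fit$months, "label", "n"),
                     by = "label"))
  dplyr::bind_rows(wide, dplyr::mutate(
    tidyr::pivot_wider(wm, names_from = "age", values_from = "p",
                       names_prefix = "age_"),
    label = "weighted_mean", n = sum(fit$months$n)))
}

#' Weighted mean of monthly age proportions
#'
#' Collapses per-month proportions-at-age to a single composition using the
#' monthly sample sizes as weights: `sum_m(P_{a,m} * n_m) / sum_m(n_m)`.
#'
#' @param proportions Long tibble with columns `age`, `p` and `n` (and
#'   optionally `label`).
#' @return A tibble with columns `age`, `p`.
#' @examples
#' tbl <- tidyr::crossing(label = c("a", "b"), age = 0:1) |>
#'   dplyr::mutate(p = c(0.3, 0.7, 0.5, 0.5),
#'                 n = rep(c(10, 30), each = 2))
#' weighted_age_proportions(tbl)
#' @export
weighted_age_proportions <- function(proportions) {
  stopifnot(all(c("age", "p", "n") %in% names(proportions)))
  proportions |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(p = sum(.data$p * .data$n) / sum(.data$n), .groups = "drop")
}

#' Predicted histograms from a fitted model
#'
#' @param object An `lf_fit`.
#' @param months Optional months tibble to predict for (defaults to the
#'   fitted months).
#' @param proportions Optional proportions tibble (defaults to the fitted
#'   proportions).
#' @param ... Unused.
#' @return A long tibble of expected counts, as [predict_lf()].
#' @export
predict.lf_fit <- function(object, months = NULL, proportions = NULL, ...) {
  predict_lf(months %||% object$months, object$params,
             proportions %||% object$proportions, object$sigmas,
             grid = object$grid, seasonal = object$spec$seasonal,
             n_ages = object$spec$n_ages)
}

#' Sensitivity refit with one parameter displaced
#'
#' Clamps a single parameter at a multiple of its unconstrained estimate
#' (default +/-10%) and re-optimizes everything else, quantifying how the
#' remaining estimates and the objective respond. The constrained optimum
#' can never beat the unconstrained one.
#'
#' @param fit A base [fit_lf()] result.
#' @param param Parameter name (e.g. `"K"`, `"C"`, `"t_b"`, `"sigma_0"`).
#' @param delta Signed relative displacement; `0.1` clamps at 110% of the
#'   base estimate.
#' @param n_starts,seed,control As in [fit_lf()] (starts are centred on the
#'   base optimum).
#' @return An `lf_fit` with the parameter held fixed.
#' @export
sensitivity_fit <- function(fit, param, delta = 0.1, n_starts = 5, seed = NULL,
                            control = list()) {
  stopifnot(inherits(fit, "lf_fit"))
  if (!param %in% fit$par_names)
    rlang::abort(sprintf("unknown parameter `%s`.", param))
  value <- fit$theta[[param]] * (1 + delta)
  lo <- fit$bounds$lower[[param]]; hi <- fit$bounds$upper[[param]]
  value <- min(max(value, lo), hi)
  fixed <- fit$fixed
  fixed[[param]] <- value
  fit_lf(fit$data, fit$spec, months = fit$months, n_starts = n_starts,
         seed = seed, start = fit$theta, fixed = fixed, grid = fit$grid,
         control = control)
}

#' Random-start robustness search
#'
#' Refits from starting vectors jittered around a base optimum (default
#' +/-25%) and reports the dispersion of the optima reached. A spread of
#' best objectives above `tol` flags possible multimodality; a
#' well-identified fit converges to the same solution from every start.
#'
#' @param fit A base [fit_lf()] result.
#' @param n_starts Number of jittered starts.
#' @param jitter Relative jitter applied to the base optimum.
#' @param seed Integer seed for reproducible jitter.
#' @param tol Objective spread regarded as "the same optimum".
#' @param control Passed to the optimizer.
#' @return A tibble (class `lf_search`) with one row per start: the
#'   objective reached, convergence code and headline parameter estimates;
#'   attributes `multimodal` (logical) and `best` (the best refit).
#' @export
random_start_search <- function(fit, n_starts = 25, jitter = 0.25, seed = NULL,
                                tol = 1e-3, control = list()) {
  stopifnot(inherits(fit, "lf_fit"))
  run_one <- function(i) {
    s <- fit$theta * stats::runif(length(fit$theta), 1 - jitter, 1 + jitter)
    s <- pmin(pmax(s, fit$bounds$lower), fit$bounds$upper)
    fit_lf(fit$data, fit$spec, months = fit$months, n_starts = 1,
           start = s, fixed = fit$fixed, grid = fit$grid, control = control)
  }
  fits <- if (is.null(seed)) lapply(seq_len(n_starts), run_one)
          else withr::with_seed(seed, lapply(seq_len(n_starts), run_one))
  rows <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    est <- coef(f)
    tibble::tibble(start_id = i, neg_log_lik = f$neg_log_lik,
                   converged = f$converged, !!!as.list(est))
  })
  best <- fits[[which.min(rows$neg_log_lik)]]
  out <- tibble::new_tibble(rows, class = "lf_search")
  attr(out, "multimodal") <- diff(range(rows$neg_log_lik)) > tol
  attr(out, "best") <- best
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
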