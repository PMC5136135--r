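test_that("parameter counting matches the candidate-set convention", {
  expect_equal(count_parameters(lf_model_spec(TRUE, "variable"), 6), 32)
  expect_equal(count_parameters(lf_model_spec(TRUE, "fixed"), 6), 29)
  expect_equal(count_parameters(lf_model_spec(FALSE, "variable"), 6), 30)
  expect_equal(count_parameters(lf_model_spec(FALSE, "fixed"), 6), 27)
  expect_equal(count_parameters(lf_model_spec(TRUE, "variable", free_L_inf = TRUE), 6), 33)
})

test_that("multinomial kernel attains its entropy lower bound", {
  set.seed(2)
  g <- bin_grid(n_bins = 8, width = 50)
  obs <- tidyr::crossing(label = c("2014-04", "2014-08"), bin = g$bin) |>
    dplyr::left_join(g, by = "bin") |>
    dplyr::mutate(count = rpois(16, 20))
  # prediction proportional to the observations: the analytic minimum
  pred_opt <- dplyr::mutate(obs, expected = count * 3.7)
  nll <- histogram_nll(obs, pred_opt, "multinomial")
  entropy <- obs |>
    dplyr::group_by(label) |>
    dplyr::summarise(h = {
      p <- count / sum(count); -sum(count * log(p))
    }) |>
    dplyr::pull(h) |> sum()
  expect_equal(nll, entropy, tolerance = 1e-12)
  # any other prediction does worse
  pred_other <- dplyr::mutate(obs, expected = rev(count) + 1)
  expect_gt(histogram_nll(obs, pred_other, "multinomial"), nll)
  # all-zero observations contribute nothing
  obs0 <- dplyr::mutate(obs, count = 0L)
  expect_equal(histogram_nll(obs0, pred_opt, "multinomial"), 0)
})

test_that("poisson kernel is minimized at predicted = observed", {
  g <- bin_grid(n_bins = 6, width = 50)
  set.seed(3)
  obs <- dplyr::mutate(tidyr::crossing(label = "m", bin = g$bin),
                       count = rpois(6, 15)) |>
    dplyr::left_join(g, by = "bin")
  pred <- dplyr::mutate(obs, expected = count)
  nz <- obs$count[obs$count > 0]
  expect_equal(histogram_nll(obs, pred, "poisson"),
               sum(nz - nz * log(nz)), tolerance = 1e-9)
  pred2 <- dplyr::mutate(obs, expected = count + 2)
  expect_gt(histogram_nll(obs, pred2, "poisson"),
            histogram_nll(obs, pred, "poisson"))
  expect_error(histogram_nll(obs, pred[-1, ], "poisson"), "same months")
})

test_that("near-noiseless synthetic data identify the generating curve", {
  # dispersion well below the bin width localizes the means only if the
  # bins are refined accordingly
  sc <- small_scenario(sigmas = rep(2, 4))
  recs <- simulate_length_records(sc, seed = 7)
  fine <- bin_grid(n_bins = 230, width = 2)
  fit <- fit_lf(quiet_hist(recs, grid = fine),
                lf_model_spec(TRUE, "variable", L_inf = 448),
                n_starts = 2, seed = 1)
  est <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(est["K"] - 0.47) / 0.47, 0.01)
  expect_lt(abs(est["C"] - 0.61) / 0.61, 0.01)
  expect_lt(abs(est["t_b"] - 0.41) / 0.41, 0.01)
})

test_that("fits are reproducible under a seed", {
  h <- get_small_hist()
  spec <- lf_model_spec(TRUE, "variable", L_inf = 448)
  f1 <- fit_lf(h, spec, n_starts = 2, seed = 5)
  f2 <- fit_lf(h, spec, n_starts = 2, seed = 5)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$neg_log_lik, f2$neg_log_lik)
})

test_that("sensitivity refits respect the clamped parameter", {
  base <- get_small_fit()
  up <- sensitivity_fit(base, "K", delta = 0.1, n_starts = 1)
  expect_equal(unname(coef(up)["K"]), unname(coef(base)["K"]) * 1.1,
               tolerance = 1e-12)
  # a binding constraint can never improve the objective
  expect_gte(up$neg_log_lik, base$neg_log_lik - 1e-6)
  dn <- sensitivity_fit(base, "K", delta = -0.1, n_starts = 1)
  expect_gte(dn$neg_log_lik, base$neg_log_lik - 1e-6)
  # delta = 0 reproduces the base fit
  same <- sensitivity_fit(base, "K", delta = 0, n_starts = 1)
  expect_equal(same$neg_log_lik, base$neg_log_lik, tolerance = 1e-4)
  expect_equal(coef(same), coef(base), tolerance = 1e-2)
})

test_that("random starts converge to a common optimum on identified data", {
  base <- get_small_fit()
  search <- random_start_search(base, n_starts = 3, jitter = 0.25, seed = 11,
                                tol = 5e-3)
  # every jittered start reaches the same solution at reporting precision;
  # the residual objective spread is optimizer termination noise
  expect_false(attr(search, "multimodal"))
  expect_lt(diff(range(search$neg_log_lik)), 5e-3)
  expect_lt(max(abs(search$C - search$C[1])), 1e-3)
  expect_lt(max(abs(search$t_b - search$t_b[1])), 1e-3)
  # zero jitter from one start reproduces the base fit
  s0 <- random_start_search(base, n_starts = 1, jitter = 0, seed = 1)
  expect_equal(s0$neg_log_lik[1], base$neg_log_lik, tolerance = 1e-5)
})

test_that("objective is invariant to month relabeling", {
  h <- get_small_hist()
  spec <- lf_model_spec(TRUE, "variable", L_inf = 448)
  f1 <- fit_lf(h, spec, n_starts = 1, seed = 2)
  # permute month block order in the histogram table
  labs <- unique(h$label)
  h_perm <- dplyr::arrange(h, match(label, rev(labs)), bin)
  f2 <- fit_lf(h_perm, spec, n_starts = 1, seed = 2)
  expect_equal(f1$neg_log_lik, f2$neg_log_lik, tolerance = 1e-6)
})
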