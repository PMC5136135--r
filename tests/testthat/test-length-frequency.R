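test_that("default bin grid is 46 contiguous half-open 10-mm bins", {
  g <- bin_grid()
  expect_equal(nrow(g), 46)
  expect_equal(g$bin_lower[1], 0)
  expect_equal(g$bin_upper[46], 460)
  expect_true(all(g$bin_upper - g$bin_lower == 10))
  expect_true(all(g$bin_lower[-1] == g$bin_upper[-46]))
})

test_that("cohort ages wrap at the birthday", {
  expect_equal(cohort_age(0.41, 0.41, 2), 2.0)
  # a cohort's age class increments at its birthday: in mid-January the
  # summer-born young of the year are 0.63 yr old and still age class 0,
  # while age class 1 carries the cohort born the summer before
  expect_equal(cohort_age(0.04, 0.41, 0), 0.63)
  expect_equal(cohort_age(0.04, 0.41, 1), 1.63)
  expect_equal(cohort_age(0.62, 0.41, 0), 0.21)
  expect_equal(cohort_age(0.2849, 0.41, 0), 0.8749, tolerance = 1e-10)
  expect_error(cohort_age(0.5, 0.41, -1), "age_class")
})

test_that("bin masses agree with closed form and quadrature", {
  # bin symmetric about the mean
  expect_equal(bin_mass(235, 10, 230, 240), 2 * pnorm(0.5) - 1, tolerance = 1e-12)
  # quadrature oracle
  quad <- integrate(dnorm, 160, 170, mean = 168, sd = 27.48,
                    rel.tol = 1e-12)$value
  expect_lt(abs(bin_mass(168, 27.48, 160, 170) - quad), 1e-10)
  # a partition of the real line carries total mass 1
  edges <- c(-Inf, seq(-50, 900, by = 10), Inf)
  expect_equal(sum(bin_mass(168, 27.48, edges[-length(edges)], edges[-1])), 1,
               tolerance = 1e-12)
  expect_error(bin_mass(100, 0, 90, 110), "sd")
})

month_fixture <- function(n = 850) {
  tibble::tibble(label = "2014-04", sample_time = year_fraction(4, 15), n = n)
}

test_that("predicted histograms match a brute-force two-loop oracle", {
  gp <- gp_study()
  months <- month_fixture()
  props <- tibble::tibble(label = "2014-04", age = 0:3,
                          p = c(0.37, 0.62, 0.00, 0.02))
  sig <- study_sigmas()
  pred <- predict_lf(months, gp, props, sig)

  # independent summation over ages and bins
  g <- bin_grid()
  p_norm <- props$p / sum(props$p)
  oracle <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    for (a in 0:3) {
      age <- cohort_age(months$sample_time, gp$t_b, a)
      mu <- vbgf_length(gp, age, seasonal = TRUE)
      oracle[i] <- oracle[i] + months$n * p_norm[a + 1] *
        (pnorm(g$bin_upper[i], mu, sig[a + 1]) - pnorm(g$bin_lower[i], mu, sig[a + 1]))
    }
  }
  expect_equal(pred$expected, oracle, tolerance = 1e-12)
  # bimodal with modes near the age-0 and age-1 mean lengths
  mu0 <- vbgf_length(gp, cohort_age(months$sample_time, gp$t_b, 0))
  mu1 <- vbgf_length(gp, cohort_age(months$sample_time, gp$t_b, 1))
  peaks <- pred$bin_lower[order(pred$expected, decreasing = TRUE)][1:8]
  expect_true(any(abs(peaks + 5 - mu0) < 15))
  expect_true(any(abs(peaks + 5 - mu1) < 15))
})

test_that("degenerate mixtures concentrate in a single bin", {
  gp <- gp_study()
  months <- month_fixture(100)
  props <- tibble::tibble(label = "2014-04", age = 0:3, p = c(0, 1, 0, 0))
  pred <- predict_lf(months, gp, props, sigmas = 0.5)
  mu1 <- vbgf_length(gp, cohort_age(months$sample_time, gp$t_b, 1))
  in_bin <- pred$expected[pred$bin_lower <= mu1 & mu1 < pred$bin_upper]
  expect_gt(in_bin, 99)  # essentially all 100 fish
  # zero sample size gives a zero histogram
  pred0 <- predict_lf(month_fixture(0), gp, props, sigmas = 0.5)
  expect_true(all(pred0$expected == 0))
})

test_that("mixtures are additive and conserve mass", {
  gp <- gp_study()
  months <- month_fixture(1000)
  sig <- study_sigmas()
  props <- tibble::tibble(label = "2014-04", age = 0:3,
                          p = c(0.4, 0.3, 0.2, 0.1))
  combined <- predict_lf(months, gp, props, sig)
  single <- lapply(0:3, function(a) {
    pa <- tibble::tibble(label = "2014-04", age = 0:3, p = as.numeric(0:3 == a))
    predict_lf(months, gp, pa, sig)$expected
  })
  weighted <- Reduce(`+`, Map(`*`, single, props$p))
  expect_equal(combined$expected, weighted, tolerance = 1e-12)

  # in-grid mass plus analytic tail mass accounts for every fish
  tail_mass <- sum(vapply(0:3, function(a) {
    mu <- vbgf_length(gp, cohort_age(months$sample_time, gp$t_b, a))
    props$p[a + 1] * (pnorm(0, mu, sig[a + 1]) + pnorm(460, mu, sig[a + 1],
                                                       lower.tail = FALSE))
  }, numeric(1)))
  expect_equal(sum(combined$expected) + 1000 * tail_mass, 1000 * sum(props$p),
               tolerance = 1e-12)
})

test_that("shifting the grid by one bin shifts the prediction by one bin", {
  gp <- gp_study()
  months <- month_fixture(500)
  props <- tibble::tibble(label = "2014-04", age = 0:3,
                          p = c(0.25, 0.25, 0.25, 0.25))
  base <- predict_lf(months, gp, props, 25, grid = bin_grid())
  shifted <- predict_lf(months, gp, props, 25, grid = bin_grid(start = -10))
  expect_equal(shifted$expected[-1], base$expected[-46], tolerance = 1e-12)
})

test_that("records are binned half-open with out-of-range reporting", {
  recs <- tibble::tibble(
    label = "2014-08",
    tl_mm = c(448, 440, 449.9, 41, 39.9, 40, 500))
  expect_warning(h <- records_to_histograms(recs), "outside the bin grid")
  expect_equal(attr(h, "n_outside"), 1L)
  expect_equal(sum(h$count), 6L)
  expect_equal(h$count[h$bin_lower == 440], 3L)  # 448, 440, 449.9
  expect_equal(h$count[h$bin_lower == 40], 2L)   # 41 and the edge value 40
  expect_equal(h$count[h$bin_lower == 30], 1L)   # 39.9
  # empty input gives an empty histogram set
  h0 <- records_to_histograms(tibble::tibble(label = character(), tl_mm = numeric()))
  expect_equal(nrow(h0), 0L)
})
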