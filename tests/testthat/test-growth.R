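test_that("traditional VBGF reproduces the fitted size-at-age values", {
  gp <- gp_study()
  expect_equal(vbgf_length(gp, 1:3, seasonal = FALSE), c(168, 273, 339),
               tolerance = 0.5 / 168)
  expect_lt(max(abs(vbgf_length(gp, 1:3, seasonal = FALSE) - c(168, 273, 339))), 0.5)
  expect_equal(vbgf_length(gp, gp$t0, seasonal = FALSE), 0)
  expect_equal(vbgf_length(gp, gp$t0, seasonal = TRUE), 0)
})

test_that("parameter validation catches bad inputs", {
  expect_error(growth_params(L_inf = -1, K = 0.5), "L_inf")
  expect_error(growth_params(448, K = 0), "K")
  expect_error(growth_params(448, 0.47, C = 1.2), "C")
  gp <- gp_study()
  expect_error(vbgf_length(gp, -0.5), "t0")
  expect_error(vbgf_rate(gp, -0.5), "t0")
  # phase parameters are reduced modulo 1
  expect_equal(growth_params(448, 0.47, t_s = 1.21, t_b = -0.59)$t_s, 0.21)
  expect_equal(growth_params(448, 0.47, t_s = 1.21, t_b = -0.59)$t_b, 0.41)
})

test_that("seasonal growth boosts first-summer length as estimated", {
  gp <- gp_study()
  age80 <- vbgf_inverse(gp, 80)
  expect_equal(age80, 0.4185, tolerance = 1e-3)
  seasonal_len <- vbgf_length(gp, age80, seasonal = TRUE)
  expect_lt(abs(seasonal_len - 111), 1)
})

test_that("seasonal form collapses to traditional at C = 0 and integer ages", {
  gp0 <- growth_params(448, 0.47, C = 0, t_s = 0.21, t_b = 0.41)
  ages <- seq(0, 10, by = 0.13)
  expect_identical(vbgf_length(gp0, ages, seasonal = TRUE),
                   vbgf_length(gp0, ages, seasonal = FALSE))
  # with t0 = 0 the oscillation integrates to zero over whole years
  gp <- gp_study()
  expect_equal(vbgf_length(gp, 0:8, seasonal = TRUE),
               vbgf_length(gp, 0:8, seasonal = FALSE), tolerance = 1e-12)
})

test_that("length-at-age is monotone and asymptotes at L_inf", {
  ages <- seq(0, 30, by = 0.01)
  for (C in c(0, 0.3, 0.61, 0.99)) {
    gp <- growth_params(448, 0.47, C = C, t_s = 0.21)
    expect_true(all(diff(vbgf_length(gp, ages)) > 0))
  }
  gp1 <- growth_params(448, 0.47, C = 1, t_s = 0.21)
  expect_true(all(diff(vbgf_length(gp1, ages)) > -1e-9))
  expect_equal(vbgf_length(gp_study(), 200), 448, tolerance = 1e-12)
})

test_that("growth rate matches its finite-difference oracle", {
  h <- 1e-6
  for (C in c(0, 0.5, 1)) {
    gp <- growth_params(448, 0.47, C = C, t_s = 0.21)
    ages <- seq(0.1, 6, by = 0.37)
    fd <- (vbgf_length(gp, ages + h) - vbgf_length(gp, ages - h)) / (2 * h)
    expect_equal(vbgf_rate(gp, ages), fd, tolerance = 1e-6)
  }
})

test_that("growth stops at the winter point when C = 1", {
  gp <- growth_params(448, 0.47, C = 1, t_s = 0.21)
  expect_equal(vbgf_rate(gp, 0.71), 0, tolerance = 1e-10)
  expect_equal(vbgf_rate(gp, 3.71), 0, tolerance = 1e-10)
  # classic rate K (L_inf - L) when C = 0
  gp0 <- growth_params(448, 0.47)
  expect_equal(vbgf_rate(gp0, 1.7),
               0.47 * (448 - vbgf_length(gp0, 1.7)), tolerance = 1e-12)
  # rate minimum over one year sits at t_s + 0.5 (mod 1); exactly so at
  # C = 1, and within a few days for C < 1 where the declining asymptotic
  # envelope shifts it marginally later
  grid <- seq(2, 3, by = 1e-4)
  expect_equal(grid[which.min(vbgf_rate(gp, grid))] %% 1, 0.71,
               tolerance = 1e-6)
  gp_mid <- gp_study()
  expect_lt(abs(grid[which.min(vbgf_rate(gp_mid, grid))] %% 1 - 0.71), 0.005)
})

test_that("traditional inverse is exact", {
  gp <- gp_study()
  ages <- seq(1e-6, 20, length.out = 50)
  expect_equal(vbgf_inverse(gp, vbgf_length(gp, ages, seasonal = FALSE)),
               ages, tolerance = 1e-9)
  expect_equal(vbgf_inverse(gp, 0), gp$t0)
  expect_equal(vbgf_inverse(gp, 168.1), 1.0, tolerance = 1e-3)
  expect_error(vbgf_inverse(gp, 448), "L_inf")
})

test_that("winter point lands in mid-February on the calendar", {
  wc <- winter_point_calendar(gp_study())
  expect_equal(wc$year_fraction, 0.12, tolerance = 1e-12)
  expect_equal(wc$month, 2L)
  expect_lte(abs(wc$day - 13), 1)
  # wrap-around to January 1
  wc0 <- winter_point_calendar(growth_params(448, 0.47, t_s = 0, t_b = 0.5))
  expect_equal(wc0$year_fraction, 0)
  expect_equal(c(wc0$month, wc0$day), c(1L, 1L))
  # with the tabulated t_b = 0.42
  wc2 <- winter_point_calendar(growth_params(448, 0.47, t_s = 0.21, t_b = 0.42))
  expect_equal(wc2$year_fraction, 0.13, tolerance = 1e-12)
})

test_that("annulus ages follow the winter-point reconciliation", {
  gp <- gp_study()  # t_w = 0.71
  expect_equal(age_at_first_annulus(gp, 1), 1.30)
  expect_equal(age_at_first_annulus(gp, 3), 3.30)
  gp0 <- growth_params(448, 0.47, t_s = 0.5, t_b = 0)  # t_w = 0, t_b = 0
  expect_equal(age_at_first_annulus(gp0, 1), 1.0)
  expect_error(age_at_first_annulus(gp, 0), "annuli")
})

test_that("calendar conversions round-trip every day of the year", {
  for (m in 1:12) {
    days <- seq_len(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m])
    cd <- calendar_date(year_fraction(rep(m, length(days)), days))
    expect_equal(cd$month, rep(m, length(days)))
    expect_equal(cd$day, days)
  }
  expect_error(year_fraction(2, 30), "day")
  expect_equal(year_fraction(6, 2), 152 / 365)
})
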