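test_that("per-window medians match the sort oracle", {
  g <- window_grid(0, 100e3, 3)
  d <- tibble::tibble(
    x = c(1, 5, 9, 2, 4, 6, 8),
    window = c(1L, 1L, 1L, 2L, 2L, 2L, 2L)
  )
  m <- median_by_window(d, g)
  expect_equal(m$centerline_x, c(5, 5, NA))
  expect_equal(m$n, c(3L, 4L, 0L))
  set.seed(91)
  for (i in 1:50) {
    x <- rnorm(sample(1:40, 1))
    s <- sort(x)
    n <- length(s)
    oracle <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    got <- median_by_window(tibble::tibble(x = x, window = 1L), window_grid(0, 1, 1))
    expect_equal(got$centerline_x, oracle)
  }
})

test_that("median comparison: identical data give zero difference, CI covers shifts", {
  g <- window_grid(0, 300e3, 2)
  set.seed(92)
  d <- tibble::tibble(
    x = rnorm(400, 0, 20e3),
    window = sample(1:2, 400, replace = TRUE)
  )
  same <- median_difference_bootstrap(d, d, g, B = 200, min_n = 30, seed = 93)
  expect_equal(same$difference_km, c(0, 0))
  expect_true(all(same$cl_lo <= 0 & same$cl_hi >= 0))
  expect_true(all(same$evaluated))

  shifted <- dplyr::mutate(d, x = x + 10e3)
  diff <- median_difference_bootstrap(shifted, d, g, B = 400, min_n = 30, seed = 94)
  expect_equal(diff$difference_km, c(10, 10), tolerance = 0.35)
  expect_true(all(diff$cl_lo < 10 & diff$cl_hi > 10))

  # sparse opportunistic windows are flagged, not dropped
  sparse <- median_difference_bootstrap(d[1:20, ], d, g, B = 50, min_n = 30, seed = 95)
  expect_true(all(!sparse$evaluated))
  expect_true(all(is.finite(sparse$difference_km[sparse$n_opp > 0 & sparse$n_tel > 0])))
  expect_error(median_difference_bootstrap(d, d, g, B = 1), "B must be")
})

test_that("centerline offsets carry the east-positive sign and tie rule", {
  g <- window_grid(0, 100e3, 1)
  ctr <- tibble::tibble(window = 1L, centerline_x = 100e3)
  d <- tibble::tibble(x = c(100e3, 100e3 + 5e3, 100e3 - 5e3), window = 1L)
  off <- centerline_offsets(d, ctr)
  expect_equal(off$signed_offset, c(0, 5e3, -5e3))
  expect_equal(off$side, c("east", "east", "west"))
  # |offset| invariant under an east-west mirror about the centerline
  mirror <- dplyr::mutate(d, x = 2 * 100e3 - x)
  off_m <- centerline_offsets(mirror, ctr)
  expect_equal(abs(off_m$signed_offset), abs(off$signed_offset))
  # windows without a centerline are skipped with a message
  d2 <- tibble::tibble(x = 1, window = 2L)
  expect_message(out <- centerline_offsets(d2, ctr), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("predictions at reference years follow the posterior-mean line", {
  fake <- structure(
    list(
      draws = cbind(
        alpha_1 = rep(10e3, 200), beta_1 = rep(0, 200),
        alpha_2 = rep(0, 200), beta_2 = rep(1000, 200)
      ),
      sigma2 = rep(1, 200), windows = c(1L, 2L),
      coef_window = c(1L, 1L, 2L, 2L),
      coef_kind = c("alpha", "beta", "alpha", "beta"),
      year0 = 1942, dropped_windows = integer(0),
      prior = NULL, burn = 0, keep = 200, n_obs = 10
    ),
    class = "flyway_gibbs"
  )
  p <- predict_year_positions(fake, years = c(1980, 2014))
  # zero slope: identical predictions; 1 km/year: 34 km over the 34-year span
  expect_equal(p$difference_km, c(0, 34))
  expect_equal(p$pred_1980_km[1], 10)
  expect_warning(predict_year_positions(fake, years = c(1930, 2014)), "extrapolat")
})

test_that("west-flank contraction is recovered by the width trend model", {
  sc <- flyway_scenario(drift = 0, contraction_west = 0.9, contraction_east = 0)
  truth <- scenario_truth(sc)
  expect_equal(truth$west_slope_nodrift, sqrt(2 / pi) * 0.9)
  set.seed(96)
  opp <- simulate_locations(sc, 6000)
  tel <- simulate_locations(sc, 1500, years = sc$years_tel, source = "telemetry")
  all_loc <- dplyr::bind_rows(opp, tel)
  g <- window_grid(sc$y0, 300e3, 13)
  ctr <- median_by_window(all_loc, g)
  off <- centerline_offsets(all_loc, ctr)
  west <- width_trend(off, "west", burn = 300, keep = 1500, seed = 97)
  east <- width_trend(off, "east", burn = 300, keep = 1500, seed = 98)
  sw <- slope_summary(west$stage2)
  se <- slope_summary(east$stage2)
  # average west-flank rate near the analytic truth, east flank near zero
  # (per-window intervals are conditional on the estimated centerline, so the
  # recovery check targets the average rate and the direction of detections)
  expect_equal(mean(sw$slope_mean_km_per_year), truth$west_slope_nodrift, tolerance = 0.25)
  expect_lt(abs(mean(se$slope_mean_km_per_year)), 0.15)
  # the eastward west-flank signal is detected in most windows; the stable
  # east flank yields mostly null windows and no systematic direction
  expect_gt(mean(sw$excludes_zero & sw$slope_mean_km_per_year > 0), 0.7)
  # detections on the stable flank are rarer and directionless on average
  expect_lt(mean(se$excludes_zero), mean(sw$excludes_zero))
})

test_that("positional trend recovers drift plus the asymmetry term", {
  sc <- flyway_scenario() # drift 1.2, west contraction 0.9
  truth <- scenario_truth(sc)
  set.seed(99)
  opp <- simulate_locations(sc, 6000)
  tel <- simulate_locations(sc, 1500, years = sc$years_tel, source = "telemetry")
  fit <- position_trend(dplyr::bind_rows(opp, tel), burn = 300, keep = 1500, seed = 100)
  ss <- slope_summary(fit$stage2)
  expect_equal(mean(ss$slope_mean_km_per_year), truth$position_slope, tolerance = 0.2)
  expect_gt(mean(ss$cl_lo <= truth$position_slope & truth$position_slope <= ss$cl_hi), 0.7)
})

test_that("empty offset subsets are rejected", {
  off <- tibble::tibble(
    source = "opportunistic", window = 1L, year = 2000,
    signed_offset = 5, side = "east"
  )
  expect_error(width_trend(off, "west"), "empty")
})
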