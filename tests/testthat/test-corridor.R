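test_that("core levels map to their symmetric percentile pairs", {
  expect_equal(core_level(50), c(lower = 25, upper = 75))
  expect_equal(core_level(75), c(lower = 12.5, upper = 87.5))
  expect_equal(core_level(95), c(lower = 2.5, upper = 97.5))
  expect_error(core_level(90), "core level")
})

test_that("window percentiles follow linear order-statistic interpolation", {
  expect_equal(window_percentiles(rep(3, 10), 95), c(west = 3, east = 3))
  expect_equal(window_percentiles(1:100, 50), c(west = 25.75, east = 75.25))
  # symmetric data give edges equidistant from the centre
  xs <- c(-5, -2, -1, 0, 1, 2, 5)
  p <- window_percentiles(xs, 75)
  expect_equal(p[["west"]], -p[["east"]])
  expect_equal(window_percentiles(numeric(0), 95), c(west = NA_real_, east = NA_real_))
})

test_that("percentiles match the brute-force sort oracle on random vectors", {
  set.seed(55)
  for (i in 1:200) {
    x <- rnorm(sample(5:200, 1), sd = runif(1, 1, 100))
    lv <- sample(c(50, 75, 95), 1)
    p <- core_level(lv) / 100
    got <- window_percentiles(x, lv)
    expect_equal(got[["west"]], oracle_quantile(x, p[["lower"]]))
    expect_equal(got[["east"]], oracle_quantile(x, p[["upper"]]))
  }
})

test_that("weighted combination averages by sample size and is symmetric", {
  expect_equal(combine_weighted(100, 300, 50, 100), 87.5)
  expect_equal(combine_weighted(100, 300, 50, 0), 100)
  expect_equal(combine_weighted(NA, 0, 50, 10), 50)
  expect_equal(combine_weighted(10, 5, 20, 5), 15)
  expect_true(is.na(combine_weighted(NA, 0, NA, 0)))
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1); na <- sample(100, 1); nb <- sample(100, 1)
    expect_equal(combine_weighted(a, na, b, nb), combine_weighted(b, nb, a, na))
  }
})

test_that("constant edges over a 13x300-km grid give a 39 Mha rectangle", {
  g <- window_grid(0, 300e3, 13)
  edges <- tibble::tibble(
    window = 1:13, y_mid = window_midpoints(g),
    west_x = -50e3, east_x = 50e3
  )
  poly <- build_corridor_polygon(edges, g)
  m <- polygon_metrics(poly)
  expect_equal(m$area_ha, 39e6)
  cr <- structure(
    list(edges = edges, widths_km = rep(100, 13), level = 95),
    class = "flyway_corridor"
  )
  wp <- width_profile(cr)
  expect_equal(wp$sd_width_km, 0)
  expect_equal(wp$mean_width_km, wp$min_width_km)
  expect_equal(wp$mean_width_km, wp$max_width_km)
})

test_that("single-window corridor is a quadrilateral", {
  g <- window_grid(0, 300e3, 1)
  edges <- tibble::tibble(window = 1L, y_mid = 150e3, west_x = -10e3, east_x = 30e3)
  poly <- build_corridor_polygon(edges, g)
  expect_equal(nrow(poly), 4)
  expect_equal(polygon_metrics(poly)$area_ha, 40e3 * 300e3 / 1e4)
})

test_that("linearly widening edges produce the closed-form trapezoid area", {
  g <- window_grid(0, 100e3, 5)
  w <- seq(-10e3, -50e3, length.out = 5)
  e <- seq(10e3, 50e3, length.out = 5)
  edges <- tibble::tibble(window = 1:5, y_mid = window_midpoints(g), west_x = w, east_x = e)
  poly <- build_corridor_polygon(edges, g)
  # widths are linear in y between mid-heights; terminal half-windows squared off
  widths <- e - w
  interior <- sum((widths[-5] + widths[-1]) / 2 * 100e3)
  ends <- widths[1] * 50e3 + widths[5] * 50e3
  expect_equal(polygon_metrics(poly)$area_ha, (interior + ends) / 1e4)
  expect_error(
    build_corridor_polygon(dplyr::mutate(edges, west_x = east_x + 1), g),
    "west edge"
  )
})

test_that("width profile summarises per-window widths", {
  g <- window_grid(0, 300e3, 2)
  edges <- tibble::tibble(
    window = 1:2, y_mid = window_midpoints(g),
    west_x = c(0, 0), east_x = c(25e3, 105e3)
  )
  cr <- structure(
    list(edges = edges, widths_km = c(25, 105), level = 95),
    class = "flyway_corridor"
  )
  wp <- width_profile(cr)
  expect_equal(wp$mean_width_km, 65)
  expect_equal(wp$min_width_km, 25)
  expect_equal(wp$max_width_km, 105)
  expect_equal(wp$max_window, 2L)
})

test_that("interior empty windows are interpolated, terminal ones truncated", {
  g <- window_grid(0, 100e3, 5)
  opp <- tibble::tibble(
    x = c(rnorm(30, 0, 5e3), rnorm(30, 40e3, 5e3), rnorm(30, 80e3, 5e3)),
    y = c(runif(30, 100e3, 200e3), runif(30, 200e3, 300e3), runif(30, 400e3, 500e3))
  )
  ed <- corridor_edges(opp, opp[0, ], g, level = 95)
  expect_equal(ed$window, 2:5) # window 1 truncated
  expect_true(ed$interpolated[ed$window == 4])
  # window 4 edges sit midway between windows 3 and 5
  expect_equal(
    ed$west_x[ed$window == 4],
    (ed$west_x[ed$window == 3] + ed$west_x[ed$window == 5]) / 2
  )
})

test_that("core corridors nest: 50% within 75% within 95%", {
  sc <- stationary_scenario()
  opp <- simulate_locations(sc, 3000, seed = 21)
  tel <- simulate_locations(sc, 1500, years = sc$years_tel, source = "telemetry", seed = 22)
  g <- window_grid(sc$y0, 300e3, 13)
  ed50 <- corridor_edges(opp, tel, g, level = 50)
  ed75 <- corridor_edges(opp, tel, g, level = 75)
  ed95 <- corridor_edges(opp, tel, g, level = 95)
  expect_true(all(ed50$west_x >= ed75$west_x & ed75$west_x >= ed95$west_x))
  expect_true(all(ed50$east_x <= ed75$east_x & ed75$east_x <= ed95$east_x))
})

test_that("degenerate data give zero-width corridors and bands", {
  g <- window_grid(0, 100e3, 3)
  d <- tibble::tibble(x = rep(5e3, 60), y = runif(60, 0, 300e3))
  bb <- bootstrap_bands(d, d[0, ], g, level = 95, B = 50, seed = 1)
  expect_true(all(bb$cl$cl_west_lo == 5e3))
  expect_true(all(bb$cl$cl_east_hi == 5e3))
})

test_that("bootstrap limits bracket the point estimate and tighten with n", {
  sc <- stationary_scenario()
  g <- window_grid(sc$y0, 300e3, 13)
  opp <- simulate_locations(sc, 2000, seed = 41)
  ed <- corridor_edges(opp, opp[0, ], g, level = 95)
  bb <- bootstrap_bands(opp, opp[0, ], g, level = 95, B = 200, seed = 42)
  expect_true(all(bb$cl$cl_west_lo <= ed$west_x & ed$west_x <= bb$cl$cl_west_hi))
  expect_true(all(bb$cl$cl_east_lo <= ed$east_x & ed$east_x <= bb$cl$cl_east_hi))

  big <- simulate_locations(sc, 8000, seed = 43)
  bb_big <- bootstrap_bands(big, big[0, ], g, level = 95, B = 200, seed = 44)
  width_small <- mean(bb$cl$cl_west_hi - bb$cl$cl_west_lo)
  width_big <- mean(bb_big$cl$cl_west_hi - bb_big$cl$cl_west_lo)
  expect_lt(width_big, width_small)
  expect_error(bootstrap_bands(opp, opp[0, ], g, B = 1), "B must be")
})

test_that("window-height selection applies the containment criterion", {
  sc <- stationary_scenario()
  opp <- simulate_locations(sc, 3500, seed = 61)
  tel <- simulate_locations(sc, 1500, years = sc$years_tel, source = "telemetry", seed = 62)
  sel <- select_window_height(opp, tel,
    candidates = c(200e3, 300e3, 450e3, 650e3),
    B = 40, seed = 63
  )
  d <- sel$diagnostics
  expect_equal(nrow(d), 4)
  expect_equal(d$passes, d$containment >= 0.95)
  passers <- d[d$passes, ]
  expect_equal(sel$height, passers$height[which.min(passers$frac_index)])
  # an unreachable criterion errors with per-candidate diagnostics
  expect_error(
    select_window_height(opp, tel, candidates = c(300e3), B = 5, min_containment = 1.01),
    "containment"
  )
})

test_that("corridor estimate object ties together edges, polygon and summaries", {
  sc <- stationary_scenario()
  opp <- simulate_locations(sc, 2500, seed = 71)
  g <- window_grid(sc$y0, 300e3, 13)
  cr <- estimate_corridor(opp, opp[0, ], g, level = 95, B = 100, bands = TRUE, seed = 72)
  expect_s3_class(cr, "flyway_corridor")
  expect_equal(cr$widths_km, (cr$edges$east_x - cr$edges$west_x) / 1000)
  expect_equal(cr$area_ha, polygon_metrics(cr$polygon)$area_ha)
  td <- tidy(cr)
  expect_true(all(c("window", "west_x", "east_x", "cl_west_lo", "width_km") %in% names(td)))
  gl <- glance(cr)
  expect_equal(gl$n_windows, 13L)
  expect_s3_class(autoplot(cr), "ggplot")
})
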