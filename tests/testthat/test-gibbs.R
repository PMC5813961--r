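make_sim_design <- function(n = 300, windows = 1:3, sd = 50, seed = 1,
                            alpha = NULL, beta = NULL) {
  set.seed(seed)
  W <- length(windows)
  if (is.null(alpha)) alpha <- rnorm(W, 0, 100)
  if (is.null(beta)) beta <- rnorm(W, 0, 2)
  d <- tibble::tibble(
    window = sample(windows, n, replace = TRUE),
    year = sample(1942:2016, n, replace = TRUE)
  )
  k <- match(d$window, windows)
  d$x <- alpha[k] + beta[k] * (d$year - 1942) + rnorm(n, 0, sd)
  list(data = d, alpha = alpha, beta = beta)
}

test_that("design construction drops windows without two distinct years", {
  d <- tibble::tibble(
    window = c(1, 1, 1, 2, 2, 3),
    year = c(1950, 1960, 1970, 1980, 1980, 1990),
    x = rnorm(6)
  )
  des <- trend_design(d)
  expect_equal(des$windows, 1L)
  expect_equal(des$dropped_windows, c(2L, 3L))
  expect_equal(colnames(des$X), c("alpha_1", "beta_1"))
  # slope column is the year centered within the window (orthogonal to alpha)
  expect_equal(unname(des$X[, "beta_1"]), d$year[1:3] - 1960)
  expect_equal(unname(des$centers), 1960)
  expect_equal(sum(des$X[, "beta_1"]), 0)
  # a supplied centering is reused verbatim (stage-2 alignment)
  des2 <- trend_design(d, centers = c("1" = 1950))
  expect_equal(unname(des2$X[, "beta_1"]), d$year[1:3] - 1950)
  expect_error(trend_design(d[4:6, ]), "distinct")
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  sim <- make_sim_design(n = 60, windows = 1:2, seed = 3)
  des <- trend_design(sim$data)
  des$X <- cbind(des$X, des$X[, "beta_2"])
  colnames(des$X)[5] <- "beta_2_copy"
  des$coef_window <- c(des$coef_window, 2L)
  des$coef_kind <- c(des$coef_kind, "beta")
  expect_error(
    gibbs_linear_model(des, burn = 10, keep = 100),
    "collinear"
  )
})

test_that("flat-prior posterior means match least squares within Monte-Carlo error", {
  sim <- make_sim_design(n = 400, windows = 1:3, sd = 60, seed = 11)
  des <- trend_design(sim$data)
  fit <- gibbs_linear_model(des, burn = 300, keep = 3000, seed = 12)
  ols <- qr.coef(qr(des$X), des$y)
  z <- abs(colMeans(fit$draws) - ols) /
    apply(fit$draws, 2, mcse_batch)
  expect_true(all(z < 5))
  expect_gt(mean(z < 3), 0.8)
})

test_that("a near-degenerate prior pins the posterior at the prior mean", {
  sim <- make_sim_design(n = 200, windows = 1, seed = 21)
  des <- trend_design(sim$data)
  pr <- normal_prior(des, mean = c(500, 7), var = c(1e-6, 1e-8))
  fit <- gibbs_linear_model(des, pr, burn = 200, keep = 1000, seed = 22)
  expect_equal(unname(colMeans(fit$draws)), c(500, 7), tolerance = 1e-2)
})

test_that("single-coefficient posterior matches the conjugate closed form", {
  set.seed(33)
  n <- 120
  xcov <- rnorm(n)
  s2_true <- 4
  y <- 2.5 * xcov + rnorm(n, 0, sqrt(s2_true))
  des <- structure(
    list(
      X = matrix(xcov, ncol = 1, dimnames = list(NULL, "beta_1")),
      y = y, windows = 1L, coef_window = 1L, coef_kind = "beta",
      year0 = 1942, dropped_windows = integer(0)
    ),
    class = "trend_design"
  )
  m0 <- 0
  v0 <- 0.5
  # pin the error variance via an overwhelming inverse-gamma prior
  pr <- normal_prior(des, mean = m0, var = v0, a0 = 1e8, b0 = 1e8 * s2_true)
  fit <- gibbs_linear_model(des, pr, burn = 500, keep = 5000, seed = 34)
  prec_post <- 1 / v0 + sum(xcov^2) / s2_true
  mean_post <- (m0 / v0 + sum(xcov * y) / s2_true) / prec_post
  expect_lt(abs(mean(fit$draws[, 1]) - mean_post), 4 * mcse_batch(fit$draws[, 1]) + 0.01)
  expect_equal(var(fit$draws[, 1]), 1 / prec_post, tolerance = 0.1)
})

test_that("tidy/glance/slope_summary expose coherent posterior summaries", {
  sim <- make_sim_design(n = 300, windows = c(2, 5), seed = 41)
  des <- trend_design(sim$data)
  fit <- gibbs_linear_model(des, burn = 200, keep = 1000, seed = 42)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(td$credible_lo <= td$estimate & td$estimate <= td$credible_hi))
  expect_equal(td$excludes_zero, td$credible_lo > 0 | td$credible_hi < 0)
  ss <- slope_summary(fit)
  expect_equal(ss$window, c(2L, 5L))
  expect_equal(ss$slope_mean_km_per_year * 1000, td$estimate[td$kind == "beta"])
  expect_equal(glance(fit)$keep, 1000)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("shifting all responses east shifts predictions, not slopes", {
  sim <- make_sim_design(n = 250, windows = 1:2, seed = 51)
  des1 <- trend_design(sim$data)
  shifted <- sim$data
  shifted$x <- shifted$x + 25e3
  des2 <- trend_design(shifted)
  fit1 <- gibbs_linear_model(des1, burn = 100, keep = 500, seed = 52)
  fit2 <- gibbs_linear_model(des2, burn = 100, keep = 500, seed = 52)
  # identical RNG stream: alphas shift by exactly +25 km, betas are identical
  expect_equal(
    colMeans(fit2$draws)[c("beta_1", "beta_2")],
    colMeans(fit1$draws)[c("beta_1", "beta_2")],
    tolerance = 1e-8
  )
  expect_equal(
    unname(colMeans(fit2$draws)[c("alpha_1", "alpha_2")] -
      colMeans(fit1$draws)[c("alpha_1", "alpha_2")]),
    c(25e3, 25e3),
    tolerance = 1e-6
  )
  p1 <- suppressWarnings(predict_year_positions(fit1))
  p2 <- suppressWarnings(predict_year_positions(fit2))
  expect_equal(p2$difference_km, p1$difference_km, tolerance = 1e-8)
  expect_equal(p2$pred_1980_km - p1$pred_1980_km, rep(25, 2), tolerance = 1e-6)
})

test_that("with no stage-2 data the posterior equals the transferred prior", {
  sim <- make_sim_design(n = 300, windows = 1:2, seed = 61)
  des <- trend_design(sim$data)
  empty <- des
  empty$X <- des$X[0, , drop = FALSE]
  empty$y <- numeric(0)
  ts <- two_stage_fit(des, empty, burn = 200, keep = 3000, seed = 62)
  t1 <- tidy(ts$stage1)
  t2 <- tidy(ts$stage2)
  # draw-mean error scaled by the prior spread stays at Monte-Carlo size
  expect_lt(max(abs(t2$estimate - t1$estimate) / t1$std_error), 0.2)
  expect_equal(t2$std_error / t1$std_error, rep(1, 4), tolerance = 0.1)
})

test_that("two-stage posterior matches the pooled closed form in the known-variance limit", {
  set.seed(71)
  n1 <- 150
  n2 <- 100
  s2 <- 9
  x1 <- rnorm(n1)
  x2 <- rnorm(n2)
  y1 <- 3 * x1 + rnorm(n1, 0, sqrt(s2))
  y2 <- 3 * x2 + rnorm(n2, 0, sqrt(s2))
  mk <- function(x, y) {
    structure(
      list(
        X = matrix(x, ncol = 1, dimnames = list(NULL, "beta_1")), y = y,
        windows = 1L, coef_window = 1L, coef_kind = "beta", year0 = 1942,
        dropped_windows = integer(0)
      ),
      class = "trend_design"
    )
  }
  d1 <- mk(x1, y1)
  d2 <- mk(x2, y2)
  pin <- function(des, mean = 0, var = Inf) {
    normal_prior(des, mean = mean, var = var, a0 = 1e8, b0 = 1e8 * s2)
  }
  f1 <- gibbs_linear_model(d1, pin(d1), burn = 300, keep = 4000, seed = 72)
  m1 <- mean(f1$draws[, 1])
  v1 <- var(f1$draws[, 1])
  f2 <- gibbs_linear_model(d2, pin(d2, mean = m1, var = v1), burn = 300, keep = 4000, seed = 73)
  # pooled analytic posterior under known variance and flat initial prior
  prec <- (sum(x1^2) + sum(x2^2)) / s2
  mean_pooled <- (sum(x1 * y1) + sum(x2 * y2)) / s2 / prec
  expect_equal(mean(f2$draws[, 1]), mean_pooled, tolerance = 0.02)
  expect_equal(var(f2$draws[, 1]), 1 / prec, tolerance = 0.15)
  # precision additivity: stage-2 posterior variance below transferred prior variance
  expect_lt(var(f2$draws[, 1]), v1)
})

test_that("flat priors with no data are rejected; keep floor enforced", {
  sim <- make_sim_design(n = 50, windows = 1, seed = 81)
  des <- trend_design(sim$data)
  expect_error(gibbs_linear_model(des, burn = 10, keep = 50), "keep")
  empty <- des
  empty$X <- des$X[0, , drop = FALSE]
  empty$y <- numeric(0)
  expect_error(gibbs_linear_model(empty, flat_prior(empty), burn = 10, keep = 100), "flat prior")
})
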