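#' Cell-means design for the corridor-change linear model
#'
#' Builds the design matrix of the year-trend model: the response (easting in
#' metres, or a centerline offset) is regressed on year with analysis window
#' as a categorical variable, in a cell-means parameterization with one
#' intercept `alpha_w` and one year slope `beta_w` per window. Per-window
#' coefficients keep transferred normal priors window-local.
#'
#' The year covariate is centered per window (at each window's mean
#' observation year) before the slope column is formed. Centering leaves
#' every slope untouched but makes each window's intercept orthogonal to its
#' slope, which matters for the two-stage prior transfer: only per-parameter
#' means and variances move between stages, and with an uncentered intercept
#' (e.g. anchored at calendar year 1942) the discarded intercept-slope
#' posterior correlation (~ -0.9) would make the transferred prior badly
#' overconfident about the slope. Predictions are still reported on the
#' calendar scale via the stored centers; pass `centers` to reuse another
#' design's parameterization (as stage 2 of a two-stage fit must).
#'
#' A window contributes the likelihood only if it has at least two distinct
#' observation years (otherwise its slope is unidentifiable); rows from other
#' windows are dropped and recorded in `dropped_windows`.
#'
#' @param data Tibble with columns `window`, `year`, and the response.
#' @param response Name of the response column (metres).
#' @param year0 Reference origin year (used for reporting and as the fallback
#'   center for windows without their own).
#' @param centers Optional named numeric vector (names = window indices) of
#'   centering years to reuse.
#' @return A `trend_design`: list with `X`, `y`, `windows`, `coef_window`,
#'   `coef_kind`, `year0`, `centers`, `dropped_windows`.
#' @export
trend_design <- function(data, response = "x", year0 = 1942, centers = NULL) {
  stopifnot(all(c("window", "year", response) %in% names(data)))
  d <- data[!is.na(data$window) & is.finite(data[[response]]), , drop = FALSE]
  yrs <- tapply(d$year, d$window, function(v) length(unique(v)))
  good <- as.integer(names(yrs)[yrs >= 2])
  dropped <- sort(setdiff(unique(d$window), good))
  d <- d[d$window %in% good, , drop = FALSE]
  if (nrow(d) == 0) abort("no window has >= 2 distinct observation years")
  wins <- sort(good)
  W <- length(wins)
  n <- nrow(d)
  X <- matrix(0, n, 2 * W)
  ctr <- setNames(numeric(W), as.character(wins))
  for (k in seq_len(W)) {
    idx <- d$window == wins[k]
    cw <- if (!is.null(centers) && as.character(wins[k]) %in% names(centers)) {
      centers[[as.character(wins[k])]]
    } else {
      mean(d$year[idx])
    }
    ctr[k] <- cw
    X[idx, 2 * k - 1] <- 1
    X[idx, 2 * k] <- d$year[idx] - cw
  }
  colnames(X) <- as.vector(rbind(paste0("alpha_", wins), paste0("beta_", wins)))
  structure(
    list(
      X = X, y = d[[response]], windows = wins,
      coef_window = rep(wins, each = 2),
      coef_kind = rep(c("alpha", "beta"), W),
      year0 = year0, centers = ctr, dropped_windows = dropped
    ),
    class = "trend_design"
  )
}

#' Normal priors for the trend model coefficients
#'
#' `flat_prior()` gives every coefficient an (improper) uniform prior —
#' infinite variance, so the coefficient full conditional reduces to the
#' least-squares likelihood. `normal_prior()` sets per-coefficient normal
#' means/variances (as transferred between the two model stages). The error
#' variance always carries a vague inverse-gamma(0.001, 0.001) prior; only
#' coefficient priors ever transfer between stages.
#'
#' @param design A [trend_design()].
#' @param mean,var Per-coefficient prior means and variances (recycled).
#' @param a0,b0 Inverse-gamma shape/rate for the error variance.
#' @return A `trend_prior` list.
#' @export
flat_prior <- function(design, a0 = 0.001, b0 = 0.001) {
  p <- ncol(design$X)
  structure(
    list(
      mean = rep(0, p), var = rep(Inf, p),
      a0 = a0, b0 = b0, names = colnames(design$X)
    ),
    class = "trend_prior"
  )
}

#' @rdname flat_prior
#' @export
normal_prior <- function(design, mean, var, a0 = 0.001, b0 = 0.001) {
  p <- ncol(design$X)
  if (any(var <= 0, na.rm = TRUE)) abort("prior variances must be > 0")
  structure(
    list(
      mean = rep_len(mean, p), var = rep_len(var, p),
      a0 = a0, b0 = b0, names = colnames(design$X)
    ),
    class = "trend_prior"
  )
}

#' Gibbs sampler for the normal linear model with normal coefficient priors
#'
#' Alternates the two conjugate full-conditional updates: coefficients given
#' the error variance are multivariate normal (with a flat prior the mean is
#' exactly the least-squares solution), and the error variance given the
#' coefficients is inverse gamma. The first `burn` draws are discarded; the
#' chain length is fixed, never auto-extended, so runs are reproducible from
#' the seed alone.
#'
#' @param design A [trend_design()].
#' @param prior A [flat_prior()] or [normal_prior()].
#' @param burn,keep Burn-in and retained draw counts.
#' @param seed Optional integer seed.
#' @return A `flyway_gibbs` object: `draws` (keep x p coefficient matrix),
#'   `sigma2` (error-variance draws), plus design metadata.
#' @export
gibbs_linear_model <- function(design, prior = flat_prior(design),
                               burn = 2000, keep = 10000, seed = NULL) {
  stopifnot(inherits(design, "trend_design"))
  if (keep < 100) abort("keep must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  X <- design$X
  y <- design$y
  n <- nrow(X)
  p <- ncol(X)
  if (n > 0) {
    qr_x <- qr(X)
    if (qr_x$rank < p) {
      bad <- colnames(X)[setdiff(seq_len(p), qr_x$pivot[seq_len(qr_x$rank)])]
      abort(sprintf("rank-deficient design; collinear columns: %s", paste(bad, collapse = ", ")))
    }
  } else if (any(!is.finite(prior$var))) {
    abort("cannot sample from a flat prior with no data")
  }
  m0 <- prior$mean
  prior_prec <- ifelse(is.finite(prior$var), 1 / prior$var, 0)
  a0 <- prior$a0
  b0 <- prior$b0
  draws <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(X)))
  s2_draws <- numeric(keep)
  if (n == 0) {
    # no likelihood: the posterior is the prior
    for (j in seq_len(p)) draws[, j] <- rnorm(keep, m0[j], sqrt(prior$var[j]))
    s2_draws <- 1 / rgamma(keep, a0, rate = b0)
    return(new_flyway_gibbs(draws, s2_draws, design, prior, burn, keep))
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y^2)
  beta <- qr.coef(qr_x, y)
  beta[!is.finite(beta)] <- 0
  rss0 <- sum((y - X %*% beta)^2)
  s2 <- max(rss0 / max(1, n - p), 1e-12)
  total <- burn + keep
  for (it in seq_len(total)) {
    prec <- XtX / s2
    diag(prec) <- diag(prec) + prior_prec
    ch <- chol(prec)
    rhs <- Xty / s2 + prior_prec * m0
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    beta <- mu + backsolve(ch, rnorm(p))
    ssr <- yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta))
    s2 <- 1 / rgamma(1, a0 + n / 2, rate = b0 + max(ssr, 0) / 2)
    if (it > burn) {
      draws[it - burn, ] <- beta
      s2_draws[it - burn] <- s2
    }
  }
  new_flyway_gibbs(draws, s2_draws, design, prior, burn, keep)
}

new_flyway_gibbs <- function(draws, s2_draws, design, prior, burn, keep) {
  structure(
    list(
      draws = draws, sigma2 = s2_draws,
      windows = design$windows, coef_window = design$coef_window,
      coef_kind = design$coef_kind, year0 = design$year0,
      centers = design$centers,
      dropped_windows = design$dropped_windows,
      prior = prior, burn = burn, keep = keep,
      n_obs = nrow(design$X)
    ),
    class = "flyway_gibbs"
  )
}

#' @export
print.flyway_gibbs <- function(x, ...) {
  cat(sprintf(
    "<flyway_gibbs> %d coefficients (%d windows), %d retained draws, n = %d\n",
    ncol(x$draws), length(x$windows), x$keep, x$n_obs
  ))
  invisible(x)
}

#' Posterior summaries of a Gibbs fit
#'
#' `tidy()` gives one row per coefficient: posterior mean, SD, 2.5/97.5
#' percentile credible limits, and whether the interval excludes zero. Slopes
#' (`beta`) are also expressed in km/year via `slope_summary()`, which returns
#' one row per analysis window. `glance()` reports chain settings and the
#' posterior error variance.
#'
#' @param x,object A `flyway_gibbs` fit.
#' @param ... Unused.
#' @export
tidy.flyway_gibbs <- function(x, ...) {
  qs <- apply(x$draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble(
    term = colnames(x$draws),
    window = x$coef_window,
    kind = x$coef_kind,
    estimate = unname(colMeans(x$draws)),
    std_error = unname(apply(x$draws, 2, sd)),
    credible_lo = unname(qs[1, ]),
    credible_hi = unname(qs[2, ]),
    excludes_zero = unname(qs[1, ] > 0 | qs[2, ] < 0)
  )
}

#' @rdname tidy.flyway_gibbs
#' @export
glance.flyway_gibbs <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    n_coef = ncol(x$draws),
    n_windows = length(x$windows),
    burn = x$burn,
    keep = x$keep,
    sigma2_mean = mean(x$sigma2)
  )
}

#' @rdname tidy.flyway_gibbs
#' @export
slope_summary <- function(x, ...) {
  td <- tidy(x)
  td <- td[td$kind == "beta", , drop = FALSE]
  tibble(
    window = td$window,
    slope_mean_km_per_year = td$estimate / 1000,
    cl_lo = td$credible_lo / 1000,
    cl_hi = td$credible_hi / 1000,
    excludes_zero = td$excludes_zero
  )
}

#' @rdname tidy.flyway_gibbs
#' @export
autoplot.flyway_gibbs <- function(object, ...) {
  ss <- slope_summary(object)
  ggplot2::ggplot(ss, ggplot2::aes(x = .data$window, y = .data$slope_mean_km_per_year)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$cl_lo, ymax = .data$cl_hi, shape = .data$excludes_zero)
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(
      x = "analysis window (south to north)",
      y = "rate of change (km/year, east positive)"
    )
}

#' Two-stage prior-updating fit
#'
#' Stage 1 fits the opportunistic-sighting design under flat coefficient
#' priors; each stage-1 posterior coefficient mean and variance then defines
#' an independent normal prior for the same coefficient in stage 2, which
#' fits the telemetry design. The stage-2 posterior is the inferential
#' output: decades of sightings inform the priors, and the unbiased (but
#' temporally shallow) telemetry data update them. A window modelled in stage
#' 2 but absent from stage 1 falls back to a flat prior with a warning.
#'
#' @param opp_design,tel_design [trend_design()] objects with the same
#'   coefficient structure.
#' @param burn,keep Chain settings used in both stages.
#' @param seed Optional integer seed.
#' @return A `flyway_two_stage` list: `stage1`, `prior2`, `stage2`.
#' @export
two_stage_fit <- function(opp_design, tel_design, burn = 2000, keep = 10000,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shared <- intersect(opp_design$windows, tel_design$windows)
  if (length(shared)) {
    c1 <- opp_design$centers[as.character(shared)]
    c2 <- tel_design$centers[as.character(shared)]
    if (any(abs(c1 - c2) > 1e-9)) {
      abort(paste(
        "stage designs use different year centerings for shared windows;",
        "build the stage-2 design with `centers = stage1_design$centers`"
      ))
    }
  }
  stage1 <- gibbs_linear_model(opp_design, flat_prior(opp_design),
    burn = burn, keep = keep
  )
  t1 <- tidy(stage1)
  key <- colnames(tel_design$X)
  idx <- match(key, t1$term)
  if (any(is.na(idx))) {
    warn(sprintf(
      "window coefficient(s) absent from stage 1, using flat prior: %s",
      paste(key[is.na(idx)], collapse = ", ")
    ))
  }
  m <- ifelse(is.na(idx), 0, t1$estimate[idx])
  v <- ifelse(is.na(idx), Inf, t1$std_error[idx]^2)
  prior2 <- normal_prior(tel_design, mean = m, var = v)
  prior2$var[is.na(idx)] <- Inf
  stage2 <- gibbs_linear_model(tel_design, prior2, burn = burn, keep = keep)
  structure(
    list(stage1 = stage1, prior2 = prior2, stage2 = stage2),
    class = "flyway_two_stage"
  )
}

#' @export
print.flyway_two_stage <- function(x, ...) {
  cat("<flyway_two_stage> stage 1 (sightings, flat priors) -> stage 2 (telemetry)\n")
  print(x$stage2)
  invisible(x)
}

#' @rdname tidy.flyway_gibbs
#' @export
tidy.flyway_two_stage <- function(x, ...) {
  dplyr::bind_rows(
    mutate(tidy(x$stage1), stage = 1L),
    mutate(tidy(x$stage2), stage = 2L)
  )
}

#' @rdname tidy.flyway_gibbs
#' @export
glance.flyway_two_stage <- function(x, ...) {
  dplyr::bind_rows(
    mutate(glance(x$stage1), stage = 1L),
    mutate(glance(x$stage2), stage = 2L)
  )
}
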