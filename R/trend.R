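#' Per-window median easting (corridor centerline)
#'
#' The centerline is the per-window median easting of the combined datasets
#' over all years (the historic median). Empty windows get a missing
#' centerline value; locations in those windows are excluded downstream.
#'
#' @param locations Tibble with `x` and `window` columns.
#' @param grid A [window_grid()].
#' @return Tibble: `window`, `centerline_x` (metres, `NA` where empty), `n`.
#' @export
median_by_window <- function(locations, grid) {
  win <- factor(locations$window, levels = seq_len(grid$count))
  xs <- split(locations$x, win)
  tibble(
    window = seq_len(grid$count),
    centerline_x = unname(vapply(
      xs, function(v) if (length(v)) median(v) else NA_real_, numeric(1)
    )),
    n = unname(as.integer(lengths(xs)))
  )
}

#' Bootstrap comparison of dataset medians per window
#'
#' Compares per-window median eastings of the opportunistic and telemetry
#' datasets over their overlapping years (the caller restricts both inputs to
#' that span first). The difference is `median(opp) - median(tel)` in km,
#' east positive, with percentile confidence limits from `B` paired
#' resamples. Windows with fewer than `min_n` opportunistic sightings are
#' flagged `evaluated = FALSE`.
#'
#' @param opp_recent,tel_recent Tibbles with `x`, `window` (already
#'   restricted to overlapping years, e.g. 2010-2016).
#' @param grid A [window_grid()].
#' @param B Bootstrap replicates (>= 2).
#' @param min_n Minimum opportunistic sample size per evaluated window.
#' @param seed Optional integer seed.
#' @param conf Confidence level.
#' @return Tibble: `window`, `n_opp`, `n_tel`, `difference_km`, `cl_lo`,
#'   `cl_hi`, `evaluated`.
#' @export
median_difference_bootstrap <- function(opp_recent, tel_recent, grid, B = 1000,
                                        min_n = 30, seed = NULL, conf = 0.95) {
  if (B < 2) abort("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  a <- (1 - conf) / 2
  purrr::map_dfr(seq_len(grid$count), function(w) {
    xo <- opp_recent$x[opp_recent$window %in% w]
    xt <- tel_recent$x[tel_recent$window %in% w]
    no <- length(xo)
    nt <- length(xt)
    if (no == 0 || nt == 0) {
      return(tibble(
        window = w, n_opp = no, n_tel = nt, difference_km = NA_real_,
        cl_lo = NA_real_, cl_hi = NA_real_, evaluated = FALSE
      ))
    }
    diff_km <- (median(xo) - median(xt)) / 1000
    reps <- vapply(seq_len(B), function(b) {
      (median(xo[sample.int(no, no, TRUE)]) - median(xt[sample.int(nt, nt, TRUE)])) / 1000
    }, numeric(1))
    cl <- quantile(reps, c(a, 1 - a), names = FALSE)
    tibble(
      window = w, n_opp = no, n_tel = nt, difference_km = diff_km,
      cl_lo = cl[1], cl_hi = cl[2], evaluated = no >= min_n
    )
  })
}

#' Signed offsets of locations from the corridor centerline
#'
#' Offset is `x - centerline_x` in metres, east positive; the `side` label is
#' `west` for strictly negative offsets and `east` otherwise (an offset of
#' exactly zero counts as east). Locations in windows with no centerline are
#' skipped with a message.
#'
#' @param locations Tibble with `x`, `window` (plus any carried columns).
#' @param centerline Tibble from [median_by_window()].
#' @return `locations` with `centerline_x`, `signed_offset` (metres) and
#'   `side` columns appended; rows without a centerline dropped.
#' @export
centerline_offsets <- function(locations, centerline) {
  out <- left_join(as_tibble(locations), centerline[, c("window", "centerline_x")],
    by = "window"
  )
  missing <- is.na(out$centerline_x)
  if (any(missing)) {
    inform(sprintf("%d location(s) skipped: no centerline for their window", sum(missing)))
    out <- out[!missing, , drop = FALSE]
  }
  out$signed_offset <- out$x - out$centerline_x
  out$side <- ifelse(out$signed_offset < 0, "west", "east")
  out
}

#' Trend in corridor position or width
#'
#' Fits the two-stage year-trend model to a response derived from centerline
#' offsets:
#'
#' * `all_abs` — absolute distance from the centerline, all locations; a
#'   negative slope means the corridor is narrowing.
#' * `west` — signed offset, locations west of the centerline only; a
#'   positive slope means the west flank is moving east (toward the median).
#' * `east` — signed offset, locations east of the centerline only.
#'
#' @param offsets Tibble from [centerline_offsets()]; needs `source`
#'   (`opportunistic`/`telemetry`), `window`, `year`, `signed_offset`, `side`.
#' @param subset One of `"all_abs"`, `"west"`, `"east"`.
#' @param burn,keep,seed Chain settings for [two_stage_fit()].
#' @param year0 Year origin.
#' @return A `flyway_two_stage` fit (see [two_stage_fit()]); its stage-2
#'   [slope_summary()] holds the per-window rates in km/year.
#' @export
width_trend <- function(offsets, subset = c("all_abs", "west", "east"),
                        burn = 2000, keep = 10000, seed = NULL, year0 = 1942) {
  subset <- match.arg(subset)
  d <- as_tibble(offsets)
  if (subset == "all_abs") {
    d$response <- abs(d$signed_offset)
  } else {
    d <- d[d$side == subset, , drop = FALSE]
    d$response <- d$signed_offset
  }
  if (nrow(d) == 0) abort(sprintf("subset '%s' is empty in every window", subset))
  fit_two_stage_sources(d, "response", burn, keep, seed, year0)
}

#' Trend in corridor position (easting)
#'
#' Convenience wrapper fitting the two-stage model with raw easting as the
#' response: per-window year slopes are east-positive shift rates.
#'
#' @param locations Tibble with `source`, `window`, `year`, `x`.
#' @inheritParams width_trend
#' @return A `flyway_two_stage` fit.
#' @export
position_trend <- function(locations, burn = 2000, keep = 10000, seed = NULL,
                           year0 = 1942) {
  fit_two_stage_sources(as_tibble(locations), "x", burn, keep, seed, year0)
}

fit_two_stage_sources <- function(d, response, burn, keep, seed, year0) {
  stopifnot("source" %in% names(d))
  opp <- d[d$source == "opportunistic", , drop = FALSE]
  tel <- d[d$source == "telemetry", , drop = FALSE]
  opp_design <- trend_design(opp, response = response, year0 = year0)
  two_stage_fit(
    opp_design,
    trend_design(tel,
      response = response, year0 = year0,
      centers = opp_design$centers
    ),
    burn = burn, keep = keep, seed = seed
  )
}

#' Model-predicted positions at reference years
#'
#' Point predictions `alpha_w + beta_w (year - center_w)` from posterior
#' coefficient means (each window's intercept refers to its centering year),
#' per analysis window, plus the between-year difference
#' (e.g. 1980 vs 2014, the 10th and 90th percentiles of sightings by
#' observation year). Years outside the observed span trigger an
#' extrapolation warning, not an error.
#'
#' @param fit A `flyway_gibbs` or `flyway_two_stage` (stage 2 is used).
#' @param years Two calendar years to predict at.
#' @param observed_span Years considered interpolation.
#' @return Tibble: `window`, `pred_<year1>_km`, `pred_<year2>_km`,
#'   `difference_km` (second minus first, east positive).
#' @export
predict_year_positions <- function(fit, years = c(1980, 2014),
                                   observed_span = c(1942, 2016)) {
  if (inherits(fit, "flyway_two_stage")) fit <- fit$stage2
  stopifnot(inherits(fit, "flyway_gibbs"), length(years) == 2)
  if (any(years < observed_span[1] | years > observed_span[2])) {
    warn("prediction year(s) outside the observed span: extrapolating")
  }
  td <- tidy(fit)
  al <- td[td$kind == "alpha", , drop = FALSE]
  be <- td[td$kind == "beta", , drop = FALSE]
  stopifnot(identical(al$window, be$window))
  # alphas refer to each window's centering year; map back to calendar years
  ctr <- fit$centers %||% setNames(rep(fit$year0, nrow(al)), as.character(al$window))
  cw <- unname(ctr[as.character(al$window)])
  p1 <- (al$estimate + be$estimate * (years[1] - cw)) / 1000
  p2 <- (al$estimate + be$estimate * (years[2] - cw)) / 1000
  out <- tibble(
    window = al$window,
    p1 = p1,
    p2 = p2,
    difference_km = p2 - p1
  )
  names(out)[2:3] <- paste0("pred_", years, "_km")
  out
}
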