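#' Core corridor levels
#'
#' The three core corridors are bands between symmetric easting percentiles
#' per analysis window: 50% core = 25th-75th, 75% core = 12.5th-87.5th,
#' 95% core = 2.5th-97.5th.
#'
#' @param level One of 50, 75, 95.
#' @return Named numeric vector `c(lower, upper)` of percentile bounds.
#' @export
core_level <- function(level) {
  lv <- as.numeric(level)
  if (!lv %in% c(50, 75, 95)) abort("core level must be one of 50, 75, 95")
  half <- (100 - lv) / 2
  c(lower = half, upper = 100 - half)
}

#' Percentile corridor edges within one window
#'
#' West and east corridor edges are the lower and upper easting percentiles of
#' the window's locations, with linear interpolation between closest order
#' statistics (the `stats::quantile()` type-7 definition, configurable because
#' edges move by O(1/n) between definitions).
#'
#' @param xs Numeric eastings, metres.
#' @param level Core level (50/75/95).
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named vector `c(west, east)` in metres, or `c(NA, NA)` for an
#'   empty window (flagged missing, never coerced to zero).
#' @examples
#' window_percentiles(1:100, 50) # 25.75, 75.25
#' @export
window_percentiles <- function(xs, level = 95, type = 7) {
  xs <- xs[is.finite(xs)]
  if (length(xs) == 0) {
    return(c(west = NA_real_, east = NA_real_))
  }
  p <- core_level(level) / 100
  q <- unname(quantile(xs, probs = p, type = type, names = FALSE))
  c(west = q[1], east = q[2])
}

#' Sample-size-weighted combination of two dataset estimates
#'
#' Percentile edges estimated separately from the opportunistic and telemetry
#' datasets are merged per window by averaging weighted by each dataset's
#' within-window sample size. A dataset that is absent from a window (weight
#' zero or missing estimate) contributes nothing; if both are absent the
#' result is flagged missing.
#'
#' @param a,b Estimates (metres); may be `NA`.
#' @param n_a,n_b Within-window sample sizes.
#' @return Combined estimate, or `NA` if neither dataset is present.
#' @examples
#' combine_weighted(100, 300, 50, 100) # 87.5
#' @export
combine_weighted <- function(a, n_a, b, n_b) {
  wa <- ifelse(is.na(a), 0, n_a)
  wb <- ifelse(is.na(b), 0, n_b)
  tot <- wa + wb
  out <- ifelse(tot > 0,
    (ifelse(is.na(a), 0, a) * wa + ifelse(is.na(b), 0, b) * wb) / tot,
    NA_real_
  )
  out
}

# per-window edges for one dataset: tibble window, west, east, n
edges_one_dataset <- function(data, grid, level, type = 7) {
  w <- assign_windows_quiet(data, grid)
  win <- factor(w$window, levels = seq_len(grid$count))
  xs <- split(w$x, win)
  ed <- t(vapply(xs, window_percentiles,
    FUN.VALUE = c(west = 0, east = 0),
    level = level, type = type
  ))
  tibble(
    window = seq_len(grid$count),
    west = unname(ed[, "west"]),
    east = unname(ed[, "east"]),
    n = unname(as.integer(lengths(xs)))
  )
}

assign_windows_quiet <- function(data, grid) {
  out <- suppressMessages(assign_windows(data, grid))
  out[out$in_grid, , drop = FALSE]
}

#' Combined per-window corridor edges
#'
#' Computes dataset-specific west/east percentile edges per analysis window
#' and merges them by sample-size weighting. Interior windows empty in both
#' datasets get edges linearly interpolated from the nearest estimated
#' neighbours; terminal empty windows truncate the corridor.
#'
#' @param opp,tel Location tibbles with projected `x`, `y` (either may have
#'   zero rows).
#' @param grid A [window_grid()].
#' @param level Core level (50/75/95).
#' @param type Quantile type.
#' @return Tibble: `window`, `y_mid`, `opp_west`, `opp_east`, `tel_west`,
#'   `tel_east`, `n_opp`, `n_tel`, `west_x`, `east_x`, `interpolated`.
#' @export
corridor_edges <- function(opp, tel, grid, level = 95, type = 7) {
  eo <- edges_one_dataset(opp, grid, level, type)
  et <- edges_one_dataset(tel, grid, level, type)
  out <- tibble(
    window = eo$window,
    y_mid = window_midpoints(grid),
    opp_west = eo$west, opp_east = eo$east,
    tel_west = et$west, tel_east = et$east,
    n_opp = eo$n, n_tel = et$n,
    west_x = combine_weighted(eo$west, eo$n, et$west, et$n),
    east_x = combine_weighted(eo$east, eo$n, et$east, et$n)
  )
  fill_interior_gaps(out)
}

# linear interpolation of combined edges across interior empty windows;
# terminal empty windows are dropped (corridor truncation)
fill_interior_gaps <- function(edges) {
  est <- which(!is.na(edges$west_x))
  edges$interpolated <- FALSE
  if (length(est) == 0) abort("no analysis window has any data")
  rng <- seq(min(est), max(est))
  gaps <- setdiff(rng, est)
  if (length(gaps)) {
    edges$west_x[gaps] <- approx(edges$window[est], edges$west_x[est],
      xout = edges$window[gaps]
    )$y
    edges$east_x[gaps] <- approx(edges$window[est], edges$east_x[est],
      xout = edges$window[gaps]
    )$y
    edges$interpolated[gaps] <- TRUE
  }
  edges[rng, , drop = FALSE]
}

#' Build the corridor polygon from per-window edges
#'
#' Vertices sit at window vertical midpoints; the ring runs up the western
#' edge south to north, then down the eastern edge. The first and last
#' windows are squared off to the grid's outer boundaries so the polygon
#' spans the full tiled extent.
#'
#' @param edges Tibble from [corridor_edges()] (needs `window`, `y_mid`,
#'   `west_x`, `east_x`).
#' @param grid The [window_grid()] the edges were computed on.
#' @return A [corridor_polygon()].
#' @export
build_corridor_polygon <- function(edges, grid) {
  ed <- edges[!is.na(edges$west_x) & !is.na(edges$east_x), , drop = FALSE]
  if (nrow(ed) == 0) abort("no windows with estimated edges")
  if (any(ed$west_x > ed$east_x)) {
    abort(sprintf(
      "west edge east of east edge in window(s): %s",
      paste(ed$window[ed$west_x > ed$east_x], collapse = ", ")
    ))
  }
  y_lo <- grid$y0 + (min(ed$window) - 1) * grid$height
  y_hi <- grid$y0 + max(ed$window) * grid$height
  west <- tibble(
    x = c(ed$west_x[1], ed$west_x, ed$west_x[nrow(ed)]),
    y = c(y_lo, ed$y_mid, y_hi)
  )
  east <- tibble(
    x = c(ed$east_x[1], ed$east_x, ed$east_x[nrow(ed)]),
    y = c(y_lo, ed$y_mid, y_hi)
  )
  ring_x <- c(west$x, rev(east$x))
  ring_y <- c(west$y, rev(east$y))
  keep <- drop_collinear(ring_x, ring_y)
  corridor_polygon(ring_x[keep], ring_y[keep])
}

# strictly collinear interior vertices add nothing to the ring shape (and a
# one-window corridor would otherwise carry them on its straight sides)
drop_collinear <- function(x, y) {
  n <- length(x)
  prv <- c(n, seq_len(n - 1))
  nxt <- c(seq_len(n)[-1], 1)
  cross <- (x - x[prv]) * (y[nxt] - y[prv]) - (y - y[prv]) * (x[nxt] - x[prv])
  cross != 0
}

# fast boundary-inclusive containment for corridor-shaped polygons:
# west(y) <= x <= east(y) with edges linear between vertex ordinates
corridor_contains <- function(edges, grid, x, y) {
  ed <- edges[!is.na(edges$west_x) & !is.na(edges$east_x), , drop = FALSE]
  y_lo <- grid$y0 + (min(ed$window) - 1) * grid$height
  y_hi <- grid$y0 + max(ed$window) * grid$height
  yy <- c(y_lo, ed$y_mid, y_hi)
  wx <- c(ed$west_x[1], ed$west_x, ed$west_x[nrow(ed)])
  ex <- c(ed$east_x[1], ed$east_x, ed$east_x[nrow(ed)])
  wv <- approx(yy, wx, xout = y, rule = 1)$y
  ev <- approx(yy, ex, xout = y, rule = 1)$y
  !is.na(wv) & x >= wv & x <= ev
}

#' Bootstrap confidence bands for corridor edges
#'
#' Resamples the opportunistic and telemetry datasets with replacement at
#' their original sizes, recomputes combined per-window west/east edges for
#' each of `B` replicates, and takes the 2.5th/97.5th percentiles of the
#' replicate values as lower/upper confidence limits per edge. Replicates in
#' which a window is empty contribute a missing value for that window and are
#' excluded from its limit percentiles.
#'
#' @inheritParams corridor_edges
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @param conf Confidence level for the limits.
#' @return List: `cl` (tibble with `window`, `cl_west_lo`, `cl_west_hi`,
#'   `cl_east_lo`, `cl_east_hi`, `n_reps`), `replicates` (B x 2W matrix of
#'   west/east draws).
#' @export
bootstrap_bands <- function(opp, tel, grid, level = 95, B = 1000, seed = NULL,
                            type = 7, conf = 0.95) {
  if (B < 2) abort("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  W <- grid$count
  wo <- assign_windows_quiet(opp, grid)
  wt <- assign_windows_quiet(tel, grid)
  reps_w <- matrix(NA_real_, B, W)
  reps_e <- matrix(NA_real_, B, W)
  for (b in seq_len(B)) {
    ed <- resampled_edges(wo, wt, W, level, type)
    reps_w[b, ] <- ed$west
    reps_e[b, ] <- ed$east
  }
  a <- (1 - conf) / 2
  qfun <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_) else quantile(v, c(a, 1 - a), names = FALSE)
  }
  qw <- apply(reps_w, 2, qfun)
  qe <- apply(reps_e, 2, qfun)
  list(
    cl = tibble(
      window = seq_len(W),
      cl_west_lo = qw[1, ], cl_west_hi = qw[2, ],
      cl_east_lo = qe[1, ], cl_east_hi = qe[2, ],
      n_reps = colSums(!is.na(reps_w))
    ),
    replicates = list(west = reps_w, east = reps_e)
  )
}

# one bootstrap replicate of combined per-window edges (vectors length W)
resampled_edges <- function(wo, wt, W, level, type) {
  one <- function(d) {
    n <- nrow(d)
    if (n == 0) {
      return(list(west = rep(NA_real_, W), east = rep(NA_real_, W), n = rep(0L, W)))
    }
    idx <- sample.int(n, n, replace = TRUE)
    win <- factor(d$window[idx], levels = seq_len(W))
    xs <- split(d$x[idx], win)
    ed <- t(vapply(xs, window_percentiles,
      FUN.VALUE = c(west = 0, east = 0),
      level = level, type = type
    ))
    list(
      west = unname(ed[, 1]), east = unname(ed[, 2]),
      n = unname(as.integer(lengths(xs)))
    )
  }
  a <- one(wo)
  b <- one(wt)
  list(
    west = combine_weighted(a$west, a$n, b$west, b$n),
    east = combine_weighted(a$east, a$n, b$east, b$n)
  )
}

#' Estimate a core migration corridor
#'
#' End-to-end corridor estimate at one core level: combined per-window
#' percentile edges, corridor polygon, per-window widths and area, and
#' (optionally) bootstrap confidence limits with inner/outer band polygons.
#'
#' @inheritParams bootstrap_bands
#' @param bands If `TRUE`, compute bootstrap confidence limits.
#' @return A `flyway_corridor` object; see [tidy.flyway_corridor()].
#' @export
estimate_corridor <- function(opp, tel, grid, level = 95, B = 1000,
                              bands = FALSE, seed = NULL, type = 7) {
  edges <- corridor_edges(opp, tel, grid, level = level, type = type)
  poly <- build_corridor_polygon(edges, grid)
  if (bands) {
    bb <- bootstrap_bands(opp, tel, grid, level = level, B = B, seed = seed, type = type)
    edges <- left_join(edges, bb$cl, by = "window")
  }
  metrics <- polygon_metrics(poly)
  structure(
    list(
      level = level,
      grid = grid,
      edges = edges,
      polygon = poly,
      band_polygons = if (bands) band_polygons(edges, grid) else NULL,
      widths_km = (edges$east_x - edges$west_x) / 1000,
      area_ha = metrics$area_ha,
      perimeter_km = metrics$perimeter_km
    ),
    class = "flyway_corridor"
  )
}

band_polygons <- function(edges, grid) {
  ok <- !is.na(edges$cl_west_lo) & !is.na(edges$cl_east_hi)
  if (!any(ok)) return(NULL)
  outer_e <- edges
  outer_e$west_x <- edges$cl_west_lo
  outer_e$east_x <- edges$cl_east_hi
  inner_e <- edges
  inner_e$west_x <- edges$cl_west_hi
  inner_e$east_x <- edges$cl_east_lo
  inner <- tryCatch(build_corridor_polygon(inner_e, grid), error = function(e) NULL)
  if (is.null(inner)) {
    warn("inner confidence band degenerate (upper west limit crosses lower east limit); omitted")
  }
  list(
    outer = build_corridor_polygon(outer_e, grid),
    inner = inner
  )
}

#' @export
print.flyway_corridor <- function(x, ...) {
  cat(sprintf(
    "<flyway_corridor> %g%% core: %d windows, mean width %.0f km, area %.1f Mha\n",
    x$level, nrow(x$edges), mean(x$widths_km), x$area_ha / 1e6
  ))
  invisible(x)
}

#' Tidy and summarise corridor estimates
#'
#' `tidy()` returns the per-window edge table (one row per analysis window);
#' `glance()` a one-row corridor summary (mean/SD/min/max width, area,
#' perimeter, fractal index).
#'
#' @param x A `flyway_corridor`.
#' @param ... Unused.
#' @export
tidy.flyway_corridor <- function(x, ...) {
  out <- x$edges
  out$width_km <- x$widths_km
  out
}

#' @rdname tidy.flyway_corridor
#' @export
glance.flyway_corridor <- function(x, ...) {
  wp <- width_profile(x)
  wp$level <- x$level
  wp$area_ha <- x$area_ha
  wp$perimeter_km <- x$perimeter_km
  wp$frac_index <- fractal_dimension(x$polygon)
  wp
}

#' Per-window width profile of a corridor
#'
#' Widths in kilometres per analysis window plus their mean, sample SD,
#' minimum and maximum (with the windows where the extremes occur), using the
#' analysis windows as sample points.
#'
#' @param estimate A `flyway_corridor`.
#' @return One-row tibble: `mean_width_km`, `sd_width_km`, `min_width_km`,
#'   `min_window`, `max_width_km`, `max_window`, `n_windows`.
#' @export
width_profile <- function(estimate) {
  stopifnot(inherits(estimate, "flyway_corridor"))
  w <- estimate$widths_km
  win <- estimate$edges$window
  tibble(
    mean_width_km = mean(w),
    sd_width_km = if (length(w) > 1) sd(w) else 0,
    min_width_km = min(w),
    min_window = win[which.min(w)],
    max_width_km = max(w),
    max_window = win[which.max(w)],
    n_windows = length(w)
  )
}

#' Select the analysis-window height
#'
#' Tests candidate window heights (default 50-700 km by 50 km). For each
#' candidate the 95% corridor is estimated; the data-fit criterion is the
#' mean, over `B` bootstrap corridor replicates, of the fraction of all
#' original locations contained, which must reach `min_containment`. Among
#' candidates meeting the criterion the one with the smallest fractal
#' dimension index (least complex shape) wins; ties go to the smaller height.
#'
#' @inheritParams bootstrap_bands
#' @param candidates Window heights to test, metres.
#' @param min_containment Containment criterion (default 0.95).
#' @return List: `height` (chosen, metres), `diagnostics` (tibble with
#'   `height`, `containment`, `frac_index`, `passes`).
#' @export
select_window_height <- function(opp, tel, candidates = seq(50e3, 700e3, by = 50e3),
                                 B = 1000, level = 95, min_containment = 0.95,
                                 seed = NULL, type = 7) {
  if (length(candidates) == 0) abort("no candidate window heights")
  if (!is.null(seed)) set.seed(seed)
  all_pts <- dplyr::bind_rows(
    opp[, c("x", "y"), drop = FALSE],
    tel[, c("x", "y"), drop = FALSE]
  )
  diag <- purrr::map_dfr(candidates, function(h) {
    grid <- window_grid_from_data(all_pts, h)
    edges <- corridor_edges(opp, tel, grid, level = level, type = type)
    frac <- fractal_dimension(build_corridor_polygon(edges, grid))
    wo <- assign_windows_quiet(opp, grid)
    wt <- assign_windows_quiet(tel, grid)
    cont <- mean(vapply(seq_len(B), function(b) {
      ed <- resampled_edges(wo, wt, grid$count, level, type)
      edt <- tibble(
        window = seq_len(grid$count), y_mid = window_midpoints(grid),
        west_x = ed$west, east_x = ed$east
      )
      edt <- tryCatch(fill_interior_gaps(edt), error = function(e) edt)
      mean(corridor_contains(edt, grid, all_pts$x, all_pts$y))
    }, numeric(1)))
    tibble(height = h, containment = cont, frac_index = frac)
  })
  diag$passes <- diag$containment >= min_containment
  if (!any(diag$passes)) {
    abort(paste(
      "no candidate window height meets the containment criterion;",
      paste(sprintf(
        "%.0f km: containment %.3f, FRAC %.3f",
        diag$height / 1000, diag$containment, diag$frac_index
      ), collapse = "; ")
    ))
  }
  ok <- diag[diag$passes, , drop = FALSE]
  ok <- ok[order(ok$frac_index, ok$height), , drop = FALSE]
  list(height = ok$height[1], diagnostics = diag)
}

#' @rdname tidy.flyway_corridor
#' @param object A `flyway_corridor` (for `autoplot`).
#' @export
autoplot.flyway_corridor <- function(object, ...) {
  ed <- tidy(object)
  p <- ggplot2::ggplot(ed, ggplot2::aes(y = .data$y_mid / 1000)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(xmin = .data$west_x / 1000, xmax = .data$east_x / 1000),
      fill = "steelblue", alpha = 0.4
    ) +
    ggplot2::geom_path(ggplot2::aes(x = .data$west_x / 1000)) +
    ggplot2::geom_path(ggplot2::aes(x = .data$east_x / 1000)) +
    ggplot2::labs(
      x = "easting (km)", y = "northing (km)",
      title = sprintf("%g%% core corridor", object$level)
    )
  if (all(c("cl_west_lo", "cl_east_hi") %in% names(ed))) {
    p <- p +
      ggplot2::geom_path(ggplot2::aes(x = .data$cl_west_lo / 1000), linetype = 2) +
      ggplot2::geom_path(ggplot2::aes(x = .data$cl_east_hi / 1000), linetype = 2)
  }
  p
}
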