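#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults at the analysis'
#' canonical values: bootstrap B = 1000; Gibbs burn-in 2000 / 10000 retained
#' draws; >= 30 sightings per window for the median comparison; QC thresholds
#' 2.6 m/s (flight), 100 km/h (displacement), 5 degrees / 50 km (spike),
#' 15 km (stopover break). `window_height = "auto"` triggers height selection
#' over 50-700 km candidates in 50-km steps. Every run writes its resolved
#' configuration beside its outputs so results are reproducible from the
#' emitted config + seed.
#'
#' @param sightings,telemetry Input CSV paths (as written by [run_simulate()]).
#' @param out_dir Output directory.
#' @param window_height Metres, or `"auto"`.
#' @param levels Core levels to estimate.
#' @param B Bootstrap replicates.
#' @param B_height Bootstrap replicates during window-height selection.
#' @param burn,keep MCMC chain settings.
#' @param min_n Minimum per-window opportunistic n for the median comparison.
#' @param overlap_years Year span shared by both datasets.
#' @param flight_threshold_ms,max_speed_kmh,min_angle_deg,angle_leg_km,break_km
#'   QC thresholds.
#' @param seed Integer seed governing all randomness in a run.
#' @param scenario A [flyway_scenario()] used by [run_simulate()].
#' @return A `flyway_config` list.
#' @export
flyway_config <- function(sightings = NULL, telemetry = NULL, out_dir = tempdir(),
                          window_height = "auto", levels = c(50, 75, 95),
                          B = 1000, B_height = 200, burn = 2000, keep = 10000,
                          min_n = 30, overlap_years = c(2010, 2016),
                          flight_threshold_ms = 2.6, max_speed_kmh = 100,
                          min_angle_deg = 5, angle_leg_km = 50, break_km = 15,
                          seed = 1, scenario = flyway_scenario()) {
  cfg <- list(
    config_version = 1L,
    sightings = sightings, telemetry = telemetry, out_dir = out_dir,
    window_height = window_height, levels = levels,
    B = B, B_height = B_height, burn = burn, keep = keep, min_n = min_n,
    overlap_years = overlap_years,
    flight_threshold_ms = flight_threshold_ms, max_speed_kmh = max_speed_kmh,
    min_angle_deg = min_angle_deg, angle_leg_km = angle_leg_km,
    break_km = break_km, seed = seed, scenario = scenario
  )
  stopifnot(
    cfg$B >= 2, cfg$flight_threshold_ms > 0, cfg$max_speed_kmh > 0,
    cfg$min_angle_deg > 0, cfg$angle_leg_km > 0, cfg$break_km > 0
  )
  structure(cfg, class = "flyway_config")
}

write_resolved_config <- function(config, dir) {
  cfg <- unclass(config)
  cfg$scenario <- unclass(cfg$scenario)[setdiff(
    names(unclass(cfg$scenario)), c("prj", "anchor_x", "anchor_y")
  )]
  jsonlite::write_json(cfg, file.path(dir, "resolved_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

#' Simulate fixture inputs for a pipeline run
#'
#' Writes `sightings.csv` and `telemetry.csv` in the raw input dialects plus
#' a `truth.json` sidecar of generative parameters. Deterministic given the
#' scenario and seed.
#'
#' @param config A [flyway_config()] (its `scenario` and `seed` are used).
#' @return Invisibly, a list of the written paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "flyway_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  sg <- simulate_sightings(config$scenario)
  tl <- simulate_telemetry(config$scenario)
  paths <- list(
    sightings = file.path(config$out_dir, "sightings.csv"),
    telemetry = file.path(config$out_dir, "telemetry.csv"),
    truth = file.path(config$out_dir, "truth.json")
  )
  readr::write_csv(sg$records, paths$sightings, progress = FALSE)
  tel_out <- tl$fixes
  tel_out$timestamp <- format(tel_out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  readr::write_csv(tel_out, paths$telemetry, progress = FALSE)
  jsonlite::write_json(
    list(
      truth = scenario_truth(config$scenario),
      n_sightings = nrow(sg$records),
      n_fixes = nrow(tl$fixes),
      n_planted_stopovers = nrow(tl$stopovers),
      n_artifacts = nrow(tl$artifacts),
      seed = config$seed
    ),
    paths$truth,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  write_resolved_config(config, config$out_dir)
  invisible(paths)
}

# shared ingest: screen + project sightings, QC + reduce telemetry
ingest_inputs <- function(config) {
  if (is.null(config$sightings) || !file.exists(config$sightings)) {
    abort(sprintf("sightings file not found: %s", config$sightings %||% "<unset>"))
  }
  if (is.null(config$telemetry) || !file.exists(config$telemetry)) {
    abort(sprintf("telemetry file not found: %s", config$telemetry %||% "<unset>"))
  }
  prj <- config$scenario$prj %||% eqdc_nad83()
  scr <- screen_sightings(read_sightings(config$sightings))
  opp <- project_locations(scr$retained, prj, id_col = "id")
  opp$source <- "opportunistic"
  tel_raw <- project_locations(read_telemetry(config$telemetry), prj, id_col = "fix_id")
  red <- suppressWarnings(reduce_telemetry(
    tel_raw,
    flight_threshold_ms = config$flight_threshold_ms,
    max_speed_kmh = config$max_speed_kmh,
    min_angle_deg = config$min_angle_deg,
    angle_leg_km = config$angle_leg_km,
    break_km = config$break_km
  ))
  list(
    opp = opp, tel = red$locations, screened = scr, reduction = red,
    prj = prj,
    attrition = tibble(
      stage = c(
        "sightings_raw", "sightings_retained", "telemetry_fixes_raw",
        "telemetry_fixes_retained", "telemetry_locations"
      ),
      n = c(
        nrow(scr$retained) + nrow(scr$rejected), nrow(scr$retained),
        nrow(tel_raw), nrow(red$retained), nrow(red$locations)
      )
    )
  )
}

#' Delineate the core migration corridors
#'
#' Runs ingest, window-height selection (when `window_height = "auto"`),
#' corridor estimation at each configured core level with bootstrap
#' confidence bands, and writes: corridor + band polygons as GeoJSON
#' (WGS84), per-window edge tables and width summaries as CSV, selection
#' diagnostics when height was selected, and a JSON run report with
#' filter-by-filter attrition counts.
#'
#' @param config A [flyway_config()].
#' @return Invisibly, a list with `corridors`, `grid`, `diagnostics`,
#'   `report`.
#' @export
run_delineate <- function(config) {
  stopifnot(inherits(config, "flyway_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  inp <- ingest_inputs(config)
  if (nrow(inp$opp) + nrow(inp$tel) == 0) {
    abort(paste(
      "no locations survive filtering; attrition:",
      paste(sprintf("%s=%d", inp$attrition$stage, inp$attrition$n), collapse = ", ")
    ))
  }
  diagnostics <- NULL
  if (identical(config$window_height, "auto")) {
    sel <- select_window_height(inp$opp, inp$tel, B = config$B_height)
    height <- sel$height
    diagnostics <- sel$diagnostics
    readr::write_csv(diagnostics, file.path(config$out_dir, "window_selection.csv"),
      progress = FALSE
    )
  } else {
    height <- config$window_height
  }
  all_pts <- dplyr::bind_rows(inp$opp[, c("x", "y")], inp$tel[, c("x", "y")])
  grid <- window_grid_from_data(all_pts, height)
  corridors <- lapply(config$levels, function(lv) {
    estimate_corridor(inp$opp, inp$tel, grid,
      level = lv, B = config$B, bands = TRUE
    )
  })
  names(corridors) <- paste0("core_", config$levels)
  for (cr in corridors) {
    readr::write_csv(
      edge_table(cr),
      file.path(config$out_dir, sprintf("edges_%g.csv", cr$level)),
      progress = FALSE
    )
  }
  write_corridor_geojson(
    corridors,
    file.path(config$out_dir, "corridors.geojson"), inp$prj
  )
  widths <- dplyr::bind_rows(lapply(corridors, glance))
  readr::write_csv(widths, file.path(config$out_dir, "width_summary.csv"), progress = FALSE)
  report <- list(
    seed = config$seed,
    window_height_m = height,
    n_windows = grid$count,
    attrition = inp$attrition,
    levels = config$levels,
    B = config$B
  )
  jsonlite::write_json(report, file.path(config$out_dir, "delineate_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  write_resolved_config(config, config$out_dir)
  invisible(list(
    corridors = corridors, grid = grid, diagnostics = diagnostics,
    report = report, inputs = inp
  ))
}

edge_table <- function(cr) {
  ed <- cr$edges
  out <- tibble(
    window = ed$window, y_mid_m = ed$y_mid,
    west_x_m = ed$west_x, east_x_m = ed$east_x,
    n_opp = ed$n_opp, n_tel = ed$n_tel
  )
  for (cl in c("cl_west_lo", "cl_west_hi", "cl_east_lo", "cl_east_hi")) {
    out[[cl]] <- if (cl %in% names(ed)) ed[[cl]] else NA_real_
  }
  out
}

#' Trend analysis over the corridor
#'
#' Runs ingest, per-window median comparison over the overlapping years,
#' two-stage positional and width trend fits (overall absolute offset plus
#' west/east subsets), and reference-year predictions; writes each table as
#' CSV plus a JSON run report.
#'
#' @param config A [flyway_config()].
#' @param grid Optional [window_grid()] (e.g. from [run_delineate()]); by
#'   default a 300-km grid anchored on the data.
#' @return Invisibly, a list with the fitted objects and tables.
#' @export
run_trend <- function(config, grid = NULL) {
  stopifnot(inherits(config, "flyway_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  inp <- ingest_inputs(config)
  all_loc <- dplyr::bind_rows(
    inp$opp[, c("source", "x", "y", "year")],
    inp$tel[, c("source", "x", "y", "year")]
  )
  if (is.null(grid)) {
    h <- if (identical(config$window_height, "auto")) 300e3 else config$window_height
    grid <- window_grid_from_data(all_loc, h)
  }
  all_loc <- suppressMessages(assign_windows(all_loc, grid))
  recent <- all_loc[all_loc$year >= config$overlap_years[1] &
    all_loc$year <= config$overlap_years[2], , drop = FALSE]
  med_diff <- median_difference_bootstrap(
    recent[recent$source == "opportunistic", ],
    recent[recent$source == "telemetry", ],
    grid,
    B = config$B, min_n = config$min_n
  )
  centerline <- median_by_window(all_loc, grid)
  offsets <- centerline_offsets(all_loc, centerline)
  pos_fit <- position_trend(all_loc, burn = config$burn, keep = config$keep)
  fits <- list(position = pos_fit)
  for (sub in c("all_abs", "west", "east")) {
    fits[[sub]] <- width_trend(offsets, sub, burn = config$burn, keep = config$keep)
  }
  slope_tables <- purrr::imap_dfr(fits, function(f, nm) {
    mutate(slope_summary(f$stage2), model = nm)
  })
  preds <- predict_year_positions(pos_fit)
  readr::write_csv(med_diff, file.path(config$out_dir, "median_differences.csv"),
    progress = FALSE
  )
  readr::write_csv(slope_tables, file.path(config$out_dir, "slope_summaries.csv"),
    progress = FALSE
  )
  readr::write_csv(preds, file.path(config$out_dir, "predictions_1980_2014.csv"),
    progress = FALSE
  )
  report <- list(
    seed = config$seed, burn = config$burn, keep = config$keep,
    n_windows = grid$count, attrition = inp$attrition
  )
  jsonlite::write_json(report, file.path(config$out_dir, "trend_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  write_resolved_config(config, config$out_dir)
  invisible(list(
    median_differences = med_diff, fits = fits, slopes = slope_tables,
    predictions = preds, centerline = centerline, grid = grid
  ))
}

#' @rdname run_trend
#' @export
run_all <- function(config) {
  paths <- run_simulate(config)
  config$sightings <- paths$sightings
  config$telemetry <- paths$telemetry
  del <- run_delineate(config)
  tr <- run_trend(config, grid = del$grid)
  invisible(list(simulate = paths, delineate = del, trend = tr))
}

#' Write corridor polygons as GeoJSON
#'
#' Polygons are inverse-projected to geographic coordinates (WGS84-equivalent
#' lon/lat) and written as a FeatureCollection; each feature carries `level`
#' and `band` (`point`, `inner`, `outer`) properties. Rings are closed on
#' output. `read_corridor_geojson()` reads them back, reprojected, for
#' round-trip checks.
#'
#' @param corridors A `flyway_corridor` or list of them.
#' @param path Output file.
#' @param prj Projection used for the inverse mapping.
#' @export
write_corridor_geojson <- function(corridors, path, prj = eqdc_nad83()) {
  if (inherits(corridors, "flyway_corridor")) corridors <- list(corridors)
  feats <- list()
  for (cr in corridors) {
    feats[[length(feats) + 1]] <- geojson_feature(cr$polygon, cr$level, "point", prj)
    if (!is.null(cr$band_polygons)) {
      if (!is.null(cr$band_polygons$outer)) {
        feats[[length(feats) + 1]] <- geojson_feature(cr$band_polygons$outer, cr$level, "outer", prj)
      }
      if (!is.null(cr$band_polygons$inner)) {
        feats[[length(feats) + 1]] <- geojson_feature(cr$band_polygons$inner, cr$level, "inner", prj)
      }
    }
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

geojson_feature <- function(poly, level, band, prj) {
  ll <- eqdc_inverse(prj, poly$x, poly$y)
  ring <- cbind(ll$lon, ll$lat)
  ring <- rbind(ring, ring[1, ])
  list(
    type = "Feature",
    properties = list(level = level, band = band),
    geometry = list(type = "Polygon", coordinates = list(ring))
  )
}

#' @rdname write_corridor_geojson
#' @return `read_corridor_geojson()`: tibble of features with reprojected
#'   vertex tibbles in a `polygon` list-column plus `level`, `band`.
#' @export
read_corridor_geojson <- function(path, prj = eqdc_nad83()) {
  gj <- jsonlite::read_json(path)
  purrr::map_dfr(gj$features, function(ft) {
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist))
    xy <- eqdc_forward(prj, lat = ring[, 2], lon = ring[, 1])
    tibble(
      level = ft$properties$level,
      band = ft$properties$band,
      polygon = list(corridor_polygon(xy$x, xy$y))
    )
  })
}
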