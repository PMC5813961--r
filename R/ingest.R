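#' Read raw sighting and telemetry tables
#'
#' Thin readr wrappers enforcing the expected column types. Sightings: `id`,
#' `lat`, `lon`, `date` (ISO-8601), `country` (`CA`/`US`), `classification`
#' (`confirmed`/`probable`/`unconfirmed`), optional `group_size`. Telemetry:
#' `bird_id`, `timestamp` (ISO-8601 UTC), `lat`, `lon`, `velocity_ms`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_sightings <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      lat = readr::col_double(),
      lon = readr::col_double(),
      date = readr::col_character(),
      country = readr::col_character(),
      classification = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
}

#' @rdname read_sightings
#' @export
read_telemetry <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      bird_id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      lat = readr::col_double(),
      lon = readr::col_double(),
      velocity_ms = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
}

#' Screen opportunistic sightings
#'
#' Retains only verified (`confirmed`) sightings, and additionally excludes
#' Canadian records dated in the sedentary summering period, 25 May to
#' 20 August inclusive, when birds are not actively migrating. United States
#' records are never subject to the summer exclusion. Unparseable dates are
#' rejected with a reason rather than raising an error.
#'
#' @param sightings Tibble as from [read_sightings()].
#' @return A list with `retained` (tibble, with parsed `date`, `year`) and
#'   `rejected` (tibble with a `reason` column: `not_confirmed`,
#'   `canada_summer`, `bad_date`).
#' @examples
#' s <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   lat = 50, lon = -105,
#'   date = c("2000-06-01", "2000-06-01", "2000-10-01"),
#'   country = c("US", "CA", "CA"),
#'   classification = c("confirmed", "confirmed", "probable")
#' )
#' screen_sightings(s)$rejected$reason # "canada_summer" "not_confirmed"
#' @export
screen_sightings <- function(sightings) {
  stopifnot(all(c("date", "country", "classification") %in% names(sightings)))
  s <- as_tibble(sightings)
  d <- suppressWarnings(as.Date(s$date))
  reason <- rep(NA_character_, nrow(s))
  reason[is.na(d)] <- "bad_date"
  reason[is.na(reason) & s$classification != "confirmed"] <- "not_confirmed"
  summer <- !is.na(d) & in_summer_window(d)
  reason[is.na(reason) & s$country == "CA" & summer] <- "canada_summer"
  keep <- is.na(reason)
  retained <- s[keep, , drop = FALSE]
  retained$date <- d[keep]
  retained$year <- as.integer(format(retained$date, "%Y"))
  list(
    retained = retained,
    rejected = dplyr::bind_cols(s[!keep, , drop = FALSE], reason = reason[!keep])
  )
}

# 25 May - 20 Aug, endpoints inclusive, in any year
in_summer_window <- function(d) {
  md <- as.integer(format(d, "%m")) * 100 + as.integer(format(d, "%d"))
  md >= 525 & md <= 820
}

#' Classify a telemetry fix as in-flight or on the ground
#'
#' A fix is in flight when its instantaneous velocity exceeds 2.6 m/s
#' (strictly); a reading of exactly 2.6 m/s, or a missing velocity, is
#' classified ground. The missing-velocity default is conservative: most fixes
#' are on the ground, and a misclassified flight fix joins a stopover cluster
#' instead of being discarded.
#'
#' @param velocity_ms Numeric vector of instantaneous velocities, m/s.
#' @param threshold Flight threshold, m/s.
#' @return Character vector, `"flight"` or `"ground"`.
#' @export
classify_flight <- function(velocity_ms, threshold = 2.6) {
  if (any(velocity_ms < 0, na.rm = TRUE)) abort("negative velocity is not a valid reading")
  if (any(is.na(velocity_ms))) {
    warn(sprintf(
      "%d fix(es) with missing velocity classified as ground",
      sum(is.na(velocity_ms))
    ))
  }
  ifelse(!is.na(velocity_ms) & velocity_ms > threshold, "flight", "ground")
}

#' Plausibility filtering of GPS telemetry tracks
#'
#' Per-bird sequential QC over time-ordered fixes, mirroring standard
#' satellite-telemetry screening:
#'
#' 1. *Time sequence*: a fix whose timestamp is not strictly later than the
#'    previous retained fix is dropped (`rejected_time`).
#' 2. *Displacement rate*: a fix implying > 100 km/h from the previous
#'    retained fix is dropped (`rejected_speed`); the later fix of the pair is
#'    removed and screening resumes from the last retained fix.
#' 3. *Spike angle*: the apex of any retained triple forming a turn angle
#'    < 5 degrees with both legs > 50 km is dropped (`rejected_angle`).
#'
#' Coordinates must already be projected (`x`, `y` metres). The pass is
#' idempotent: running it on its own output retains everything.
#'
#' @param fixes Tibble with `bird_id`, `timestamp` (POSIXct), `x`, `y`.
#' @param max_speed_kmh Displacement-rate limit, km/h (strict).
#' @param min_angle_deg Spike-angle limit, degrees (strict).
#' @param angle_leg_km Both legs must exceed this distance, km (strict).
#' @return A list with `retained` and `rejected` tibbles; `rejected` carries a
#'   `reason` column (`rejected_time`, `rejected_speed`, `rejected_angle`).
#' @export
qc_telemetry <- function(fixes, max_speed_kmh = 100, min_angle_deg = 5,
                         angle_leg_km = 50) {
  stopifnot(all(c("bird_id", "timestamp", "x", "y") %in% names(fixes)))
  f <- as_tibble(fixes)
  if (nrow(f) == 0) {
    return(list(retained = f, rejected = dplyr::bind_cols(f, reason = character(0))))
  }
  f$.row <- seq_len(nrow(f))
  parts <- split(f, f$bird_id)
  res <- lapply(parts, qc_one_bird,
    max_speed_kmh = max_speed_kmh,
    min_angle_deg = min_angle_deg, angle_leg_km = angle_leg_km
  )
  retained <- dplyr::bind_rows(lapply(res, `[[`, "retained"))
  rejected <- dplyr::bind_rows(lapply(res, `[[`, "rejected"))
  retained <- dplyr::arrange(retained, .data$.row)
  if (nrow(rejected)) rejected <- dplyr::arrange(rejected, .data$.row)
  retained$.row <- NULL
  rejected$.row <- NULL
  list(retained = retained, rejected = rejected)
}

qc_one_bird <- function(f, max_speed_kmh, min_angle_deg, angle_leg_km) {
  n <- nrow(f)
  reason <- rep(NA_character_, n)
  # passes 1+2: sequential time / displacement-rate screen against the last
  # retained fix
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(last)) {
      last <- i
      next
    }
    dt <- as.numeric(difftime(f$timestamp[i], f$timestamp[last], units = "hours"))
    if (dt <= 0) {
      reason[i] <- "rejected_time"
      next
    }
    dist_km <- sqrt((f$x[i] - f$x[last])^2 + (f$y[i] - f$y[last])^2) / 1000
    if (dist_km / dt > max_speed_kmh) {
      reason[i] <- "rejected_speed"
      next
    }
    last <- i
  }
  # pass 3: spike angles over the retained sequence
  keep <- which(is.na(reason))
  repeat {
    if (length(keep) < 3) break
    dropped <- FALSE
    for (k in 2:(length(keep) - 1)) {
      a <- keep[k - 1]; b <- keep[k]; c <- keep[k + 1]
      leg1 <- sqrt((f$x[b] - f$x[a])^2 + (f$y[b] - f$y[a])^2) / 1000
      leg2 <- sqrt((f$x[c] - f$x[b])^2 + (f$y[c] - f$y[b])^2) / 1000
      if (leg1 > angle_leg_km && leg2 > angle_leg_km) {
        ang <- turn_angle_deg(
          f$x[a], f$y[a], f$x[b], f$y[b], f$x[c], f$y[c]
        )
        if (!is.na(ang) && ang < min_angle_deg) {
          reason[b] <- "rejected_angle"
          keep <- keep[-k]
          dropped <- TRUE
          break
        }
      }
    }
    if (!dropped) break
  }
  ok <- is.na(reason)
  list(
    retained = f[ok, , drop = FALSE],
    rejected = dplyr::bind_cols(f[!ok, , drop = FALSE], reason = reason[!ok])
  )
}

# interior angle at B of the path A -> B -> C, degrees (0 = doubling back)
turn_angle_deg <- function(ax, ay, bx, by, cx, cy) {
  v1 <- c(ax - bx, ay - by)
  v2 <- c(cx - bx, cy - by)
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Cluster ground fixes into stopover sites
#'
#' Sequential chaining over each bird's time-ordered ground fixes: a new
#' stopover site starts whenever the move from the previous ground fix exceeds
#' 15 km. Each site is summarised by the arithmetic-mean centroid of its
#' member fixes.
#'
#' @param ground_fixes Tibble of QC-retained ground fixes with `bird_id`,
#'   `timestamp`, `x`, `y`.
#' @param break_km Move distance that starts a new site, km (strict).
#' @return Tibble of sites: `bird_id`, `site`, `n_fixes`, `centroid_x`,
#'   `centroid_y`, `first_time`, `last_time`.
#' @export
cluster_stopovers <- function(ground_fixes, break_km = 15) {
  stopifnot(all(c("bird_id", "timestamp", "x", "y") %in% names(ground_fixes)))
  g <- dplyr::arrange(as_tibble(ground_fixes), .data$bird_id, .data$timestamp)
  if (nrow(g) == 0) {
    return(tibble(
      bird_id = character(0), site = integer(0), n_fixes = integer(0),
      centroid_x = numeric(0), centroid_y = numeric(0),
      first_time = g$timestamp[0], last_time = g$timestamp[0]
    ))
  }
  g <- g |>
    group_by(.data$bird_id) |>
    mutate(
      step_km = c(0, sqrt(diff(.data$x)^2 + diff(.data$y)^2) / 1000),
      site = cumsum(.data$step_km > break_km) + 1L
    ) |>
    ungroup()
  g |>
    group_by(.data$bird_id, .data$site) |>
    summarise(
      n_fixes = dplyr::n(),
      centroid_x = mean(.data$x),
      centroid_y = mean(.data$y),
      first_time = min(.data$timestamp),
      last_time = max(.data$timestamp),
      .groups = "drop"
    )
}

#' Assemble analysis-ready telemetry migration locations
#'
#' One location per stopover centroid plus one per retained in-flight fix,
#' all tagged `source = "telemetry"`. The `year` of a centroid comes from its
#' first member fix.
#'
#' @param sites Tibble from [cluster_stopovers()].
#' @param flight_fixes Tibble of QC-retained flight fixes (`bird_id`,
#'   `timestamp`, `x`, `y`).
#' @return Tibble with `source`, `bird_id`, `x`, `y`, `year`, `kind`
#'   (`stopover_centroid` / `flight_fix`).
#' @export
assemble_migration_locations <- function(sites, flight_fixes) {
  cent <- tibble(
    source = "telemetry",
    bird_id = sites$bird_id,
    x = sites$centroid_x,
    y = sites$centroid_y,
    year = as.integer(format(sites$first_time, "%Y")),
    kind = "stopover_centroid"
  )
  fl <- tibble(
    source = "telemetry",
    bird_id = flight_fixes$bird_id,
    x = flight_fixes$x,
    y = flight_fixes$y,
    year = as.integer(format(flight_fixes$timestamp, "%Y")),
    kind = "flight_fix"
  )
  dplyr::bind_rows(cent, fl)
}

#' Full telemetry reduction: QC, flight split, stopovers, locations
#'
#' Convenience wrapper running [qc_telemetry()], [classify_flight()],
#' [cluster_stopovers()] and [assemble_migration_locations()] in order.
#'
#' @param fixes Projected telemetry fixes with `bird_id`, `timestamp`, `x`,
#'   `y`, `velocity_ms`.
#' @inheritParams qc_telemetry
#' @inheritParams cluster_stopovers
#' @param flight_threshold_ms Flight-classification threshold, m/s.
#' @return List: `locations` (analysis-ready tibble), `sites`, `retained`,
#'   `rejected`.
#' @export
reduce_telemetry <- function(fixes, flight_threshold_ms = 2.6,
                             max_speed_kmh = 100, min_angle_deg = 5,
                             angle_leg_km = 50, break_km = 15) {
  qc <- qc_telemetry(fixes,
    max_speed_kmh = max_speed_kmh,
    min_angle_deg = min_angle_deg, angle_leg_km = angle_leg_km
  )
  ret <- qc$retained
  ret$flight <- classify_flight(ret$velocity_ms, flight_threshold_ms) == "flight"
  sites <- cluster_stopovers(ret[!ret$flight, , drop = FALSE], break_km = break_km)
  locs <- assemble_migration_locations(sites, ret[ret$flight, , drop = FALSE])
  list(locations = locs, sites = sites, retained = ret, rejected = qc$rejected)
}
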