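# shared fixtures and small oracles used across test files

# reduced flyway: same 13-window geometry, cheaper datasets
small_scenario <- function(...) {
  flyway_scenario(n_sightings = 1500, n_birds = 8, ...)
}

stationary_scenario <- function(...) {
  flyway_scenario(drift = 0, contraction_west = 0, contraction_east = 0, ...)
}

# independent quantile oracle: explicit order-statistic interpolation,
# h = (n - 1) p + 1 on the sorted sample
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# batch-means Monte-Carlo standard error of a chain's mean
mcse_batch <- function(draws, n_batch = 30) {
  n <- length(draws)
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch), function(b) {
    mean(draws[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  sd(bm) / sqrt(n_batch)
}

# square corridor polygon of side `s` metres at origin
square_poly <- function(s = 1000) {
  corridor_polygon(c(0, s, s, 0), c(0, 0, s, s))
}

# telemetry fix tibble from planar km coordinates and hour offsets
fixes_km <- function(x_km, y_km, hours, bird = "b1", velocity = 1) {
  tibble::tibble(
    bird_id = bird,
    timestamp = as.POSIXct("2014-04-01 00:00:00", tz = "UTC") + hours * 3600,
    x = x_km * 1000,
    y = y_km * 1000,
    velocity_ms = velocity
  )
}
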