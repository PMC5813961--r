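#' Equidistant conic projection definition
#'
#' Builds the projection used to put sightings and telemetry locations on a
#' common planar coordinate system before any corridor computation. The
#' default is the North America Equidistant Conic parameterization on the
#' GRS80 ellipsoid (NAD83): standard parallels 20 and 60 degrees north,
#' central meridian 96 degrees west, latitude of origin 40 degrees north.
#' The defining property of the projection is that distances along every
#' meridian are true, so north-south window heights in metres correspond to
#' real ground distance.
#'
#' @param lat1,lat2 Standard parallels, decimal degrees.
#' @param lon0 Central meridian, decimal degrees (east positive).
#' @param lat0 Latitude of origin, decimal degrees.
#' @param false_easting,false_northing Offsets added to x and y, metres.
#' @param a Semi-major axis of the ellipsoid, metres (GRS80 default).
#' @param f Flattening (GRS80 default). Use `f = 0` for a sphere.
#'
#' @return An object of class `eqdc_projection`.
#' @examples
#' prj <- eqdc_nad83()
#' eqdc_forward(prj, lat = 40, lon = -96) # origin maps to (0, 0)
#' @export
eqdc_nad83 <- function(lat1 = 20, lat2 = 60, lon0 = -96, lat0 = 40,
                       false_easting = 0, false_northing = 0,
                       a = 6378137, f = 1 / 298.257222101) {
  stopifnot(is.numeric(lat1), is.numeric(lat2), lat1 != -lat2)
  e2 <- f * (2 - f)
  prj <- list(
    lat1 = lat1, lat2 = lat2, lon0 = lon0, lat0 = lat0,
    fe = false_easting, fn = false_northing, a = a, f = f, e2 = e2
  )
  # meridional-arc series coefficients (ellipsoidal equidistant conic)
  e4 <- e2^2
  e6 <- e2^3
  prj$c0 <- 1 - e2 / 4 - 3 * e4 / 64 - 5 * e6 / 256
  prj$c1 <- 3 * e2 / 8 + 3 * e4 / 32 + 45 * e6 / 1024
  prj$c2 <- 15 * e4 / 256 + 45 * e6 / 1024
  prj$c3 <- 35 * e6 / 3072
  m <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  phi1 <- lat1 * pi / 180
  phi2 <- lat2 * pi / 180
  m1 <- m(phi1)
  m2 <- m(phi2)
  M1 <- meridian_arc(prj, phi1)
  M2 <- meridian_arc(prj, phi2)
  prj$n <- if (abs(lat1 - lat2) < 1e-12) sin(phi1) else a * (m1 - m2) / (M2 - M1)
  prj$G <- m1 / prj$n + M1 / a
  prj$rho0 <- a * prj$G - meridian_arc(prj, lat0 * pi / 180)
  sqrt1me2 <- sqrt(1 - e2)
  prj$e1 <- (1 - sqrt1me2) / (1 + sqrt1me2)
  class(prj) <- "eqdc_projection"
  prj
}

#' @export
print.eqdc_projection <- function(x, ...) {
  cat(sprintf(
    "<eqdc_projection> std parallels %g/%g, central meridian %g, origin %g (a = %g, f = 1/%g)\n",
    x$lat1, x$lat2, x$lon0, x$lat0, x$a, if (x$f > 0) 1 / x$f else Inf
  ))
  invisible(x)
}

# meridian arc length from equator to latitude phi (radians), metres
meridian_arc <- function(prj, phi) {
  prj$a * (prj$c0 * phi - prj$c1 * sin(2 * phi) +
             prj$c2 * sin(4 * phi) - prj$c3 * sin(6 * phi))
}

#' Forward and inverse equidistant conic mapping
#'
#' `eqdc_forward()` maps geographic coordinates to planar easting/northing in
#' metres; `eqdc_inverse()` maps back. Both are vectorised.
#'
#' @param prj An [eqdc_nad83()] projection object.
#' @param lat,lon Decimal degrees; `lat` in \[-90, 90\], `lon` in \[-180, 180\].
#' @param x,y Easting and northing, metres.
#' @return A tibble with columns `x`, `y` (forward) or `lat`, `lon` (inverse).
#' @export
eqdc_forward <- function(prj, lat, lon) {
  stopifnot(inherits(prj, "eqdc_projection"))
  bad <- !is.finite(lat) | !is.finite(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    abort(sprintf(
      "out-of-range coordinates at positions: %s",
      paste(which(bad), collapse = ", ")
    ))
  }
  phi <- lat * pi / 180
  rho <- prj$a * prj$G - meridian_arc(prj, phi)
  dlon <- ((lon - prj$lon0 + 180) %% 360 - 180) # wrap to (-180, 180]
  theta <- prj$n * dlon * pi / 180
  tibble(
    x = prj$fe + rho * sin(theta),
    y = prj$fn + prj$rho0 - rho * cos(theta)
  )
}

#' @rdname eqdc_forward
#' @export
eqdc_inverse <- function(prj, x, y) {
  stopifnot(inherits(prj, "eqdc_projection"))
  xp <- x - prj$fe
  yp <- prj$rho0 - (y - prj$fn)
  rho <- sign(prj$n) * sqrt(xp^2 + yp^2)
  theta <- atan2(sign(prj$n) * xp, sign(prj$n) * yp)
  M <- prj$a * prj$G - rho
  mu <- M / (prj$a * prj$c0)
  e1 <- prj$e1
  phi <- mu +
    (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  tibble(
    lat = phi * 180 / pi,
    lon = prj$lon0 + (theta / prj$n) * 180 / pi
  )
}

#' Project locations onto the flyway analysis plane
#'
#' Takes any data frame with `lat`/`lon` columns and appends planar `x`
#' (easting) and `y` (northing) in metres under the supplied equidistant-conic
#' projection. Rows with out-of-range coordinates raise an error naming the
#' offending records, so bad positions never silently enter the corridor
#' analysis.
#'
#' @param data Data frame with numeric `lat` and `lon` columns (decimal
#'   degrees); other columns pass through untouched.
#' @param prj Projection from [eqdc_nad83()].
#' @param id_col Optional column name used to identify rejected records in the
#'   error message.
#' @return The input as a tibble with `x` and `y` columns appended.
#' @examples
#' project_locations(data.frame(lat = c(30, 50), lon = c(-97, -105)))
#' @export
project_locations <- function(data, prj = eqdc_nad83(), id_col = NULL) {
  stopifnot(is.data.frame(data), all(c("lat", "lon") %in% names(data)))
  bad <- !is.finite(data$lat) | !is.finite(data$lon) |
    abs(data$lat) > 90 | abs(data$lon) > 180
  if (any(bad)) {
    ids <- if (!is.null(id_col) && id_col %in% names(data)) {
      data[[id_col]][bad]
    } else {
      which(bad)
    }
    abort(sprintf(
      "%d record(s) with out-of-range coordinates: %s",
      sum(bad), paste(utils::head(ids, 10), collapse = ", ")
    ))
  }
  xy <- eqdc_forward(prj, data$lat, data$lon)
  out <- as_tibble(data)
  out$x <- xy$x
  out$y <- xy$y
  out
}
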