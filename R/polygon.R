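#' Corridor polygon constructor
#'
#' A corridor polygon is a simple (non-self-intersecting) closed ring of
#' planar vertices in metres. The constructor validates simplicity and drops a
#' duplicated closing vertex if present; orientation is immaterial.
#'
#' @param x,y Vertex coordinates in metres (or a two-column matrix/data frame
#'   passed as `x`).
#' @return A `corridor_polygon`: tibble of vertices with columns `x`, `y`.
#' @examples
#' corridor_polygon(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' @export
corridor_polygon <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.data.frame(x)
    stopifnot(ncol(m) >= 2)
    y <- m[[2]]
    x <- m[[1]]
  }
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1
  }
  if (n < 3) abort("a polygon needs at least 3 distinct vertices")
  poly <- structure(tibble(x = x, y = y), class = c("corridor_polygon", class(tibble())))
  cross <- first_self_intersection(poly)
  if (!is.null(cross)) {
    abort(sprintf(
      "self-intersecting ring: segment %d-%d crosses segment %d-%d",
      cross[1], cross[1] %% n + 1, cross[2], cross[2] %% n + 1
    ))
  }
  poly
}

# first pair of non-adjacent edges that properly cross, or NULL
first_self_intersection <- function(poly) {
  x <- poly$x
  y <- poly$y
  n <- length(x)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2)) {
    for (j in seq((i + 2), n)) {
      if (i == 1 && j == n) next # adjacent through the closure
      if (segments_cross(
        x[i], y[i], x[nxt[i]], y[nxt[i]],
        x[j], y[j], x[nxt[j]], y[nxt[j]]
      )) {
        return(c(i, j))
      }
    }
  }
  NULL
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Polygon area and perimeter
#'
#' Shoelace area (reported in hectares, the unit corridor areas are quoted in)
#' and ring perimeter (kilometres), from vertices in metres.
#'
#' @param poly A [corridor_polygon()].
#' @return A tibble with one row: `area_ha`, `perimeter_km`.
#' @examples
#' sq <- corridor_polygon(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' polygon_metrics(sq) # 100 ha, 4 km
#' @export
polygon_metrics <- function(poly) {
  stopifnot(inherits(poly, "corridor_polygon"))
  tibble(
    area_ha = polygon_area_m2(poly) / 1e4,
    perimeter_km = polygon_perimeter_m(poly) / 1e3
  )
}

polygon_area_m2 <- function(poly) {
  x <- poly$x
  y <- poly$y
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_perimeter_m <- function(poly) {
  x <- poly$x
  y <- poly$y
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  sum(sqrt((xs - x)^2 + (ys - y)^2))
}

#' Fractal dimension index of a corridor polygon
#'
#' Patch-level shape-complexity index from landscape metrics:
#' `2 * ln(0.25 * P) / ln(A)` with perimeter P and area A both in metres.
#' It equals exactly 1 for a square at any scale and grows toward 2 as the
#' boundary becomes more convoluted at fixed area. The raw value is returned
#' untouched; values outside \[1, 2\] (possible for thin shapes at the index's
#' known area dependence) are reported, never clamped silently.
#'
#' @param poly A [corridor_polygon()].
#' @return A single numeric index.
#' @examples
#' fractal_dimension(corridor_polygon(c(0, 5, 5, 0) * 1e3, c(0, 0, 5, 5) * 1e3)) # 1
#' @export
fractal_dimension <- function(poly) {
  stopifnot(inherits(poly, "corridor_polygon"))
  A <- polygon_area_m2(poly)
  P <- polygon_perimeter_m(poly)
  if (A <= 1) abort("fractal dimension undefined for area <= 1 m^2 (log degeneracy)")
  2 * log(0.25 * P) / log(A)
}

#' Fraction of locations contained in a polygon
#'
#' Boundary-inclusive point-in-polygon test (ray casting plus an explicit
#' on-edge check), so a location exactly on a corridor edge counts as inside.
#'
#' @param poly A [corridor_polygon()].
#' @param data Data frame with projected `x`, `y` columns in metres.
#' @return Fraction in \[0, 1\].
#' @export
containment_fraction <- function(poly, data) {
  stopifnot(inherits(poly, "corridor_polygon"), is.data.frame(data))
  if (nrow(data) == 0) abort("containment_fraction needs a nonempty point set")
  mean(points_in_polygon(poly, data$x, data$y))
}

# vectorised over points; loops over edges (corridor rings are short)
points_in_polygon <- function(poly, px, py) {
  vx <- poly$x
  vy <- poly$y
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary check: collinear and within the segment's bounding box
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    tol <- 1e-9 * max(1, seglen2)
    onseg <- abs(cr) <= tol &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    onedge <- onedge | onseg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | onedge
}
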