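#' Latitudinal analysis windows
#'
#' The corridor is estimated inside equal-height slabs ("analysis windows")
#' stacked along the projected y-axis. Windows are half-open
#' `[y0 + (w-1)h, y0 + w h)`, lower-inclusive, numbered from the south
#' (window 1) northward; they tile the grid span contiguously with no gaps.
#'
#' `window_grid()` builds a grid explicitly; `window_grid_from_data()` anchors
#' the grid flush at the minimum northing of the data and takes
#' `count = ceiling(span / height)` so every point falls in a window.
#'
#' @param y0 Northing of the southern grid boundary, metres.
#' @param height Window height, metres (> 0).
#' @param count Number of windows W (>= 1).
#' @return A `window_grid` object with fields `y0`, `height`, `count`.
#' @examples
#' g <- window_grid(0, 300e3, 13)
#' window_midpoints(g)[1:3]
#' @export
window_grid <- function(y0, height, count) {
  stopifnot(is.numeric(y0), length(y0) == 1, is.finite(y0))
  if (!is.numeric(height) || height <= 0) abort("window height must be > 0")
  if (!is.numeric(count) || count < 1) abort("window count must be >= 1")
  structure(
    list(y0 = as.numeric(y0), height = as.numeric(height), count = as.integer(count)),
    class = "window_grid"
  )
}

#' @rdname window_grid
#' @param data Data frame with a projected `y` column, metres.
#' @export
window_grid_from_data <- function(data, height) {
  stopifnot("y" %in% names(data), nrow(data) > 0)
  y0 <- min(data$y)
  span <- max(data$y) - y0
  window_grid(y0, height, max(1L, ceiling(span / height)))
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "<window_grid> %d windows of %.0f km starting at y = %.0f km\n",
    x$count, x$height / 1000, x$y0 / 1000
  ))
  invisible(x)
}

#' @rdname window_grid
#' @export
window_midpoints <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  grid$y0 + (seq_len(grid$count) - 0.5) * grid$height
}

#' Assign locations to analysis windows
#'
#' Appends an integer `window` column: `floor((y - y0) / height) + 1` for
#' points inside the grid, `NA` (with `in_grid = FALSE`) for points outside.
#' Out-of-grid points are flagged rather than dropped so callers can decide.
#'
#' @param data Data frame with a projected `y` column, metres.
#' @param grid A [window_grid()].
#' @return `data` as a tibble with `window` (integer or NA) and `in_grid`
#'   (logical) columns.
#' @export
assign_windows <- function(data, grid) {
  stopifnot(is.data.frame(data), "y" %in% names(data), inherits(grid, "window_grid"))
  w <- floor((data$y - grid$y0) / grid$height) + 1
  inside <- is.finite(w) & w >= 1 & w <= grid$count
  out <- as_tibble(data)
  out$window <- ifelse(inside, as.integer(w), NA_integer_)
  out$in_grid <- inside
  if (any(!inside)) {
    inform(sprintf("%d location(s) fall outside the window grid", sum(!inside)))
  }
  out
}
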