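#' Barn geometry with functional zones
#'
#' Describes the axis-aligned barn rectangle and its two functional zones:
#' the feeding zone (feed passage plus nearest passageway) and the
#' non-feeding zone (cubicles and passageways). Default coordinates follow
#' the study barn: feeding zone 10.5 <= y <= 17.2 m, non-feeding zone
#' 1.62 <= y <= 10.5 m with -1.6 <= x <= 58.6 m. Positions are filtered into
#' zones with a dilation buffer (default 3 m) so minor positional error at a
#' zone boundary does not drop genuine records.
#'
#' @param x_range numeric length-2, barn x extent in metres.
#' @param y_range numeric length-2, barn y extent in metres.
#' @param feeding_y numeric length-2, y interval of the feeding zone.
#' @param non_feeding_y numeric length-2, y interval of the non-feeding zone.
#' @param non_feeding_x numeric length-2, x interval of the non-feeding zone.
#' @param zone_buffer metres of dilation applied when filtering into a zone.
#'
#' @return An object of class `barn_geometry`: a list with elements
#'   `barn` (list with `x`, `y` ranges), `feeding`, `non_feeding`
#'   (rectangles as `x`/`y` ranges) and `zone_buffer`.
#' @examples
#' geom <- barn_geometry()
#' geom$feeding$y
#' @export
barn_geometry <- function(x_range = c(-1.6, 58.6),
                          y_range = c(1.62, 17.2),
                          feeding_y = c(10.5, 17.2),
                          non_feeding_y = c(1.62, 10.5),
                          non_feeding_x = c(-1.6, 58.6),
                          zone_buffer = 3) {
  stopifnot(length(x_range) == 2, length(y_range) == 2,
            x_range[1] < x_range[2], y_range[1] < y_range[2],
            feeding_y[1] < feeding_y[2], non_feeding_y[1] < non_feeding_y[2],
            zone_buffer >= 0)
  in_y <- function(z, r) z[1] >= r[1] - 1e-9 && z[2] <= r[2] + 1e-9
  if (!in_y(feeding_y, y_range) || !in_y(non_feeding_y, y_range))
    stop("zone y-intervals must lie inside the barn rectangle")
  geom <- list(
    barn = list(x = as.numeric(x_range), y = as.numeric(y_range)),
    feeding = list(x = as.numeric(x_range), y = as.numeric(feeding_y)),
    non_feeding = list(x = as.numeric(non_feeding_x), y = as.numeric(non_feeding_y)),
    zone_buffer = zone_buffer
  )
  class(geom) <- "barn_geometry"
  geom
}

#' @export
print.barn_geometry <- function(x, ...) {
  cat("Barn geometry\n")
  cat(sprintf("  barn:        x [%.2f, %.2f] m, y [%.2f, %.2f] m\n",
              x$barn$x[1], x$barn$x[2], x$barn$y[1], x$barn$y[2]))
  cat(sprintf("  feeding:     y [%.2f, %.2f] m\n", x$feeding$y[1], x$feeding$y[2]))
  cat(sprintf("  non-feeding: x [%.2f, %.2f] m, y [%.2f, %.2f] m\n",
              x$non_feeding$x[1], x$non_feeding$x[2],
              x$non_feeding$y[1], x$non_feeding$y[2]))
  cat(sprintf("  zone buffer: %.2f m\n", x$zone_buffer))
  invisible(x)
}

# rectangle for a zone label ("full_barn", "feeding", "non_feeding"),
# dilated by buffer metres
zone_rect <- function(geometry, zone, buffer_m = 0) {
  stopifnot(inherits(geometry, "barn_geometry"), buffer_m >= 0)
  r <- switch(zone,
    full_barn = geometry$barn,
    feeding = geometry$feeding,
    non_feeding = geometry$non_feeding,
    stop("unknown zone label: ", zone)
  )
  list(x = r$x + c(-buffer_m, buffer_m), y = r$y + c(-buffer_m, buffer_m))
}

# logical: points inside an axis-aligned rectangle (inclusive bounds)
points_in_rect <- function(x, y, rect) {
  x >= rect$x[1] & x <= rect$x[2] & y >= rect$y[1] & y <= rect$y[2]
}
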