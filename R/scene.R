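#' Standardised home-stretch track scene
#'
#' The world frame puts the lane (running) direction along `x`, lateral
#' across the lanes along `y` and up along `z`. Lane demarcation line `k`
#' (0-based) is the ground line `y = k * lane_width`. Track lanes are a
#' standardised 1.22 m wide; the default of nine lines bounds eight lanes.
#'
#' @param lane_width Lane spacing in metres (default 1.22).
#' @param n_lanes Number of painted lane lines (default 9, i.e. 8 lanes).
#' @param lane_extent Length-2 range of `x`, metres, over which lines are
#'   rendered/considered.
#' @return An object of class `track_scene`.
#' @export
track_scene <- function(lane_width = 1.22, n_lanes = 9,
                        lane_extent = c(-100, 200)) {
  if (!is_number(lane_width) || lane_width <= 0)
    abort_trackcal("`lane_width` must be a positive number.", "invalid_parameter")
  if (!is_number(n_lanes) || n_lanes < 2)
    abort_trackcal("`n_lanes` must be at least 2.", "invalid_parameter")
  stopifnot(length(lane_extent) == 2L, lane_extent[1] < lane_extent[2])
  structure(list(lane_width = lane_width, n_lanes = as.integer(n_lanes),
                 lane_extent = as.numeric(lane_extent)),
            class = "track_scene")
}

#' @export
print.track_scene <- function(x, ...) {
  cat(sprintf("<track_scene> %d lane lines, %.2f m apart, x in [%g, %g] m\n",
              x$n_lanes, x$lane_width, x$lane_extent[1], x$lane_extent[2]))
  invisible(x)
}

#' Lane demarcation lines as 3D segments
#'
#' @param scene A [track_scene()].
#' @return A tibble with one row per lane line: `lane` (0-based index) and
#'   segment endpoints `x1, y1, z1, x2, y2, z2` in metres. All segments are
#'   parallel to `(1, 0, 0)` on the ground plane, spaced `lane_width` apart.
#' @export
lane_lines_3d <- function(scene) {
  stopifnot(inherits(scene, "track_scene"))
  k <- seq_len(scene$n_lanes) - 1L
  tibble::tibble(
    lane = k,
    x1 = scene$lane_extent[1], y1 = k * scene$lane_width, z1 = 0,
    x2 = scene$lane_extent[2], y2 = k * scene$lane_width, z2 = 0)
}
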