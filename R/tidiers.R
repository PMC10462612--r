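# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.candidate_set <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.candidate_set <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    sweep_step = attr(x, "sweep_step"),
    azimuth_min = min(x$azimuth), azimuth_max = max(x$azimuth),
    v0_x = attr(x, "v0")[1], v0_y = attr(x, "v0")[2],
    n_failures = nrow(attr(x, "failures")))
}

#' @export
tidy.pose_eval <- function(x, ...) x$per_frame

#' @export
glance.pose_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(strategy = x$strategy,
                                  n_frames = nrow(x$per_frame),
                                  n_skipped = length(x$skipped)),
                   x$summary)
}

#' Plot the candidate camera family
#'
#' The one-parameter family of camera positions consistent with a single
#' lane vanishing point traces a curve in space; plotted here in plan view
#' (`x` along the lanes, `y` lateral) coloured by azimuth, with the lane
#' grid for reference.
#'
#' @param object A `candidate_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.candidate_set <- function(object, ...) {
  scene <- attr(object, "scene")
  lanes <- lane_lines_3d(scene)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = lanes,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2),
      inherit.aes = FALSE, colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$azimuth), linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$azimuth), size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "azimuth (deg)") +
    ggplot2::coord_equal(xlim = c(-60, 60)) +
    ggplot2::labs(x = "x along lanes (m)", y = "y across lanes (m)",
                  title = "Candidate camera positions for one vanishing point")
}

#' Plot per-frame audit metrics
#'
#' @param object A `pose_eval`.
#' @param ... Unused.
#' @return A ggplot of the four error metrics over frames.
#' @export
autoplot.pose_eval <- function(object, ...) {
  df <- object$per_frame
  long <- tibble::tibble(
    frame = rep(df$frame, 4),
    metric = rep(c("reprojection (px)", "reprojection (mm)",
                   "knee 2D (deg)", "knee approx 3D (deg)"),
                 each = nrow(df)),
    value = c(df$reproj_px, df$reproj_mm, df$knee2d_deg, df$knee3d_deg))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL,
                  title = paste0("Pose audit (strategy: ", object$strategy, ")"))
}

#' Plot a synthetic frame with detected overlays
#'
#' @param object A `synthetic_frame`.
#' @param lanes Optional `lane_set` to overlay.
#' @param ... Unused.
#' @return A ggplot raster of the frame.
#' @export
autoplot.synthetic_frame <- function(object, lanes = NULL, ...) {
  img <- object$image
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$v <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal()
  if (!is.null(lanes)) {
    p <- p + ggplot2::geom_segment(
      data = tibble::as_tibble(lanes),
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2),
      colour = "red", linewidth = 0.4)
  }
  p
}

#' @importFrom rlang .data
NULL
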