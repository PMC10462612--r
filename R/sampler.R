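#' Sample random broadcast-like ground-truth cameras
#'
#' Draws pan/tilt/zoom cameras positioned like a broadcast camera in the
#' stands viewing the home stretch: azimuth, elevation and field of view
#' uniform over the given ranges, with the principal axis aimed at a point
#' on the lane grid and the viewing distance coupled to the field of view
#' so that a realistic stretch of track (roughly 8-16 m across) fills the
#' frame. Camera `x` (along the lanes) is 0: the world origin sits at the
#' camera's station along the track, which is the component parallel lane
#' lines cannot identify.
#'
#' @param n Number of cameras.
#' @param seed Integer seed.
#' @param az_range,el_range,fov_range Parameter ranges, degrees.
#' @param scene A [track_scene()] (for the lane grid aim point).
#' @param image_size Length-2 `(width, height)`.
#' @return A list of [camera_params()].
#' @export
sample_broadcast_cameras <- function(n, seed = 1,
                                     az_range = c(15, 75),
                                     el_range = c(3, 30),
                                     fov_range = c(5, 40),
                                     scene = track_scene(),
                                     image_size = c(1280, 720)) {
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      az <- stats::runif(1, az_range[1], az_range[2])
      el <- stats::runif(1, el_range[1], el_range[2])
      fov <- stats::runif(1, fov_range[1], fov_range[2])
      # couple viewing distance to zoom: ground footprint of 8-16 m
      footprint <- stats::runif(1, 8, 16)
      D <- footprint / (2 * tan(deg2rad(fov) / 2))
      z <- clamp(D * sin(deg2rad(el)), 3, 45)
      # aim the principal axis near the first lanes so lane 0 is in frame
      aim_y <- stats::runif(1, 1.2, 3.2) * scene$lane_width
      y <- aim_y - z * cos(deg2rad(el)) * sin(deg2rad(az)) / sin(deg2rad(el))
      camera_params(az, el, 0, fov, c(0, y, z), image_size)
    })
  })
}
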