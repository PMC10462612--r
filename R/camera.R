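#' Camera parameters for a pan/tilt/zoom pinhole broadcast camera
#'
#' A camera is described by three angles, a horizontal field of view and a 3D
#' position in the world frame. The world frame is right-handed with `x` the
#' lane (running) direction toward the finish line, `y` lateral across the
#' lanes, and `z` up; lane line `k` is the ground line `y = k * lane_width`.
#'
#' Angle conventions (degrees at every interface, radians internally):
#' * `azimuth` — pan about the world vertical. At azimuth 0 the optical axis
#'   is parallel to the lane direction `(1, 0, 0)`; positive azimuth pans
#'   toward `+y` (from the stands toward the track).
#' * `elevation` — tilt below the horizontal, in `[0, 90)`.
#' * `roll` — rotation about the optical axis; 0 gives a horizontal horizon.
#' * `fov` — horizontal field of view in `(0, 180)`. The focal length in
#'   pixels is `(width / 2) / tan(fov / 2)`: square pixels, zero skew, and the
#'   principal point at the exact image centre.
#'
#' Image coordinates have their origin at the top-left corner, `x` right and
#' `y` down, in pixels.
#'
#' @param azimuth,elevation,roll Camera angles in degrees.
#' @param fov Horizontal field of view in degrees, in (0, 180).
#' @param position Numeric length-3 camera centre, metres, world frame.
#' @param image_size Numeric length-2 `(width, height)` in pixels.
#' @return An object of class `camera_params`.
#' @examples
#' cam <- camera_params(azimuth = 30, elevation = 10, fov = 20,
#'                      position = c(0, -12, 6), image_size = c(1280, 720))
#' cam
#' @export
camera_params <- function(azimuth, elevation, roll = 0, fov,
                          position, image_size = c(1280, 720)) {
  if (!is_number(fov) || fov <= 0 || fov >= 180)
    abort_trackcal("`fov` must lie strictly between 0 and 180 degrees.",
                   "invalid_parameter")
  if (!is_number(elevation) || elevation < 0 || elevation >= 90)
    abort_trackcal("`elevation` must lie in [0, 90) degrees.", "invalid_parameter")
  if (!is_number(azimuth) || !is_number(roll))
    abort_trackcal("`azimuth` and `roll` must be finite numbers.", "invalid_parameter")
  if (!is.numeric(position) || length(position) != 3L || !all(is.finite(position)))
    abort_trackcal("`position` must be a finite length-3 numeric vector.",
                   "invalid_parameter")
  if (!is.numeric(image_size) || length(image_size) != 2L || any(image_size <= 0))
    abort_trackcal("`image_size` must be two positive numbers (width, height).",
                   "invalid_parameter")
  structure(
    list(azimuth = azimuth, elevation = elevation, roll = roll, fov = fov,
         position = as.numeric(position), image_size = as.numeric(image_size)),
    class = "camera_params"
  )
}

#' @export
print.camera_params <- function(x, ...) {
  cat(sprintf(
    "<camera_params> az %.3f deg | el %.3f deg | roll %.3f deg | fov %.3f deg\n",
    x$azimuth, x$elevation, x$roll, x$fov))
  cat(sprintf("  position (%.3f, %.3f, %.3f) m | image %d x %d px\n",
              x$position[1], x$position[2], x$position[3],
              round(x$image_size[1]), round(x$image_size[2])))
  invisible(x)
}

#' @export
tidy.camera_params <- function(x, ...) {
  tibble::tibble(
    azimuth = x$azimuth, elevation = x$elevation, roll = x$roll, fov = x$fov,
    x = x$position[1], y = x$position[2], z = x$position[3],
    width = x$image_size[1], height = x$image_size[2])
}

# World -> camera rotation. Composition (applied world -> camera):
#   R = R_roll(optical axis) . R_elevation(camera x) . R0 . R_azimuth(world z)
# where R0 aligns the frames: camera z (optical axis) = world x, camera x
# (image right) = world -y, camera y (image down) = world -z.
camera_rotation <- function(azimuth, elevation, roll = 0) {
  r0 <- matrix(c(0, -1, 0,
                 0, 0, -1,
                 1, 0, 0), 3, 3, byrow = TRUE)
  rot_z(deg2rad(roll)) %*% rot_x(deg2rad(elevation)) %*% r0 %*% rot_z(-deg2rad(azimuth))
}

camera_intrinsics <- function(fov, image_size) {
  f <- (image_size[1] / 2) / tan(deg2rad(fov) / 2)
  matrix(c(f, 0, image_size[1] / 2,
           0, f, image_size[2] / 2,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Build the projection matrix of a camera
#'
#' Composes the intrinsic matrix `K`, world-to-camera rotation `R` and
#' translation `t = -R %*% position` into the 3x4 projection matrix
#' `P = K [R | t]`, so that a world point `X` maps to the homogeneous pixel
#' `P %*% c(X, 1)`.
#'
#' @param params A [camera_params()] object.
#' @return An object of class `projection_matrix` with elements `K`, `R`,
#'   `t`, `P`, and the originating `params`.
#' @examples
#' proj <- build_projection(camera_params(30, 10, 0, 20, c(0, -12, 6)))
#' round(proj$P, 3)
#' @export
build_projection <- function(params) {
  stopifnot(inherits(params, "camera_params"))
  K <- camera_intrinsics(params$fov, params$image_size)
  R <- camera_rotation(params$azimuth, params$elevation, params$roll)
  t <- as.numeric(-R %*% params$position)
  structure(list(K = K, R = R, t = t, P = K %*% cbind(R, t), params = params),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("<projection_matrix> P = K [R | t]\n")
  print(signif(x$P, 6))
  invisible(x)
}

as_point_matrix <- function(points, d) {
  if (is.data.frame(points)) {
    cols <- c("x", "y", "z")[seq_len(d)]
    points <- as.matrix(points[, cols])
  } else if (is.numeric(points) && is.null(dim(points))) {
    points <- matrix(points, ncol = d, byrow = TRUE)
  }
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == d)
  points
}

#' Project world points into the image
#'
#' Applies the pinhole projection `(u, v, w) = P %*% (X, Y, Z, 1)` and
#' dehomogenises to pixels `(u/w, v/w)`. Points behind the camera (`w < 0`)
#' are flagged in the `behind` column; points on the principal plane
#' (`w = 0`) raise a projection-at-infinity error.
#'
#' @param points An `n x 3` matrix, a data frame with columns `x`, `y`, `z`,
#'   or a bare length-3 vector. Metres, world frame.
#' @param proj A [build_projection()] result.
#' @return A tibble with columns `x`, `y` (pixels), `w` (homogeneous depth
#'   scale) and `behind`.
#' @export
project_points <- function(points, proj) {
  stopifnot(inherits(proj, "projection_matrix"))
  pts <- as_point_matrix(points, 3)
  h <- proj$P %*% rbind(t(pts), 1)
  w <- h[3, ]
  if (any(abs(w) < 1e-12))
    abort_trackcal("Point on the camera's principal plane projects to infinity.",
                   "projection_at_infinity")
  tibble::tibble(x = unname(h[1, ] / w), y = unname(h[2, ] / w),
                 w = unname(w), behind = unname(w < 0))
}

#' Image of a 3D direction (vanishing point)
#'
#' The projections of all 3D lines sharing a direction meet in the image of
#' that direction's point at infinity: `K %*% R %*% d` dehomogenised. The
#' result is independent of the camera position.
#'
#' @param direction Nonzero length-3 direction vector, world frame.
#' @param proj A [build_projection()] result.
#' @return A length-2 pixel coordinate. If the direction is parallel to the
#'   image plane the vanishing point is at infinity: the result is
#'   `c(NA, NA)` with attributes `at_infinity = TRUE` and `direction`, the
#'   unit image direction toward it.
#' @export
vanishing_point_of_direction <- function(direction, proj) {
  stopifnot(inherits(proj, "projection_matrix"))
  d <- as.numeric(direction)
  nd <- sqrt(sum(d^2))
  if (length(d) != 3L || nd == 0)
    abort_trackcal("`direction` must be a nonzero 3-vector.", "invalid_parameter")
  h <- as.numeric(proj$K %*% proj$R %*% (d / nd))
  if (abs(h[3]) < 1e-9 * sqrt(sum(h^2))) {
    u <- h[1:2] / sqrt(sum(h[1:2]^2))
    return(structure(c(NA_real_, NA_real_), at_infinity = TRUE, direction = u))
  }
  c(h[1] / h[3], h[2] / h[3])
}

# Analytic lane vanishing point (image of the running direction (1,0,0)).
lane_vanishing_point <- function(proj) vanishing_point_of_direction(c(1, 0, 0), proj)

# Image y of the ground-plane horizon for a roll-free camera.
horizon_y <- function(proj) {
  p <- proj$params
  f <- proj$K[1, 1]
  p$image_size[2] / 2 - f * tan(deg2rad(p$elevation))
}

#' Ray-trace an image point onto the ground plane
#'
#' Back-projects a pixel through the camera centre and intersects the ray
#' with the ground plane `z = 0`. The round trip
#' `project_points(ray_trace_to_ground(p), proj)` recovers `p`.
#'
#' @param pixel Length-2 pixel coordinate.
#' @param proj A [build_projection()] result.
#' @return Length-2 ground coordinate `(x, y)` in metres (a point on `z = 0`).
#' @export
ray_trace_to_ground <- function(pixel, proj) {
  stopifnot(inherits(proj, "projection_matrix"), length(pixel) == 2L)
  d_cam <- solve(proj$K, c(pixel, 1))
  d_world <- as.numeric(t(proj$R) %*% d_cam)
  C <- proj$params$position
  if (d_world[3] >= -1e-12)
    abort_trackcal("Ray is parallel to or points above the ground plane.",
                   "no_intersection")
  s <- -C[3] / d_world[3]
  if (s <= 0)
    abort_trackcal("Ground intersection lies behind the camera.", "no_intersection")
  (C + s * d_world)[1:2]
}

# Back-project a pixel onto the horizontal plane z = h (internal; h = 0 is
# the exported ray_trace_to_ground).
ray_trace_to_height <- function(pixel, proj, h) {
  d_cam <- solve(proj$K, c(pixel, 1))
  d_world <- as.numeric(t(proj$R) %*% d_cam)
  C <- proj$params$position
  if (d_world[3] >= -1e-12)
    abort_trackcal("Ray is parallel to or points above the ground plane.",
                   "no_intersection")
  s <- (h - C[3]) / d_world[3]
  if (s <= 0)
    abort_trackcal("Plane intersection lies behind the camera.", "no_intersection")
  (C + s * d_world)[1:2]
}

#' Read or write camera parameters as YAML
#'
#' The schema uses keys `azimuth_deg`, `elevation_deg`, `roll_deg`,
#' `fov_deg`, `position_m` (list of 3) and `image_size` (list of 2).
#'
#' @param path File path.
#' @return `read_camera()` returns a [camera_params()]; `write_camera()`
#'   returns `path` invisibly.
#' @export
read_camera <- function(path) {
  y <- yaml::read_yaml(path)
  camera_params(azimuth = y$azimuth_deg, elevation = y$elevation_deg,
                roll = y$roll_deg %||% 0, fov = y$fov_deg,
                position = as.numeric(y$position_m),
                image_size = as.numeric(y$image_size))
}

#' @param params A [camera_params()] object.
#' @rdname read_camera
#' @export
write_camera <- function(params, path) {
  stopifnot(inherits(params, "camera_params"))
  yaml::write_yaml(
    list(azimuth_deg = params$azimuth, elevation_deg = params$elevation,
         roll_deg = params$roll, fov_deg = params$fov,
         position_m = as.numeric(params$position),
         image_size = as.numeric(params$image_size)),
    path)
  invisible(path)
}
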