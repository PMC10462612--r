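# Shared fixtures: reference cameras and small helpers used across tests.

# A typical home-stretch broadcast camera (stands, mid pan, moderate zoom).
test_camera <- function(azimuth = 35, elevation = 8, fov = 12, z = 7,
                        aim_y = 4, image_size = c(1280, 720)) {
  y <- aim_y - z * cos(elevation * pi / 180) * sin(azimuth * pi / 180) /
    sin(elevation * pi / 180)
  camera_params(azimuth, elevation, 0, fov, c(0, y, z), image_size)
}

# Independent oracle: compose K [R | t] by hand from first principles
# (explicit elementary matrices, written out separately from the package).
oracle_projection <- function(az, el, roll, fov, pos, size = c(1280, 720)) {
  d2r <- pi / 180
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)),
                           3, 3, byrow = TRUE)
  align <- matrix(c(0, -1, 0, 0, 0, -1, 1, 0, 0), 3, 3, byrow = TRUE)
  R <- Rz(roll * d2r) %*% Rx(el * d2r) %*% align %*% Rz(-az * d2r)
  f <- (size[1] / 2) / tan(fov * d2r / 2)
  K <- matrix(c(f, 0, size[1] / 2, 0, f, size[2] / 2, 0, 0, 1), 3, 3,
              byrow = TRUE)
  list(K = K, R = R, t = -R %*% pos, P = K %*% cbind(R, -R %*% pos))
}

oracle_project <- function(P, X) {
  h <- P %*% c(X, 1)
  c(h[1] / h[3], h[2] / h[3])
}

# Analytic image lines of the visible lane demarcations for a camera, as a
# lane_set (bypasses the renderer; used to test the search in isolation).
analytic_lane_set <- function(camera, scene = track_scene()) {
  fr <- render_track(camera, scene,
                     style = render_style(bg_noise_sd = 0, bg_gradient = 0,
                                          bg_base = 0))
  lt <- fr$lanes_true
  lane_set(px = (lt$x1 + lt$x2) / 2, py = (lt$y1 + lt$y2) / 2,
           angle = lt$angle, support = sqrt((lt$x2 - lt$x1)^2 + (lt$y2 - lt$y1)^2),
           x1 = lt$x1, y1 = lt$y1, x2 = lt$x2, y2 = lt$y2,
           image_size = camera$image_size)
}

# A plain standing 3D skeleton at the origin (for geometric metric tests).
standing_skeleton <- function() {
  generate_runner(gait_config(speed = 0), n_frames = 1, seed = 1)$skeletons[[1]]
}

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
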