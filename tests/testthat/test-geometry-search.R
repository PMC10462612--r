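# Candidate enumeration: elevation/fov/translation solvers and selection.

# closed-form elevation oracle: sin(el) = -tan(az) * dy / dx for the
# direction (dx, dy) from the principal point to the vanishing point
oracle_elevation <- function(az, d) {
  asin(-tan(az * pi / 180) * d[2] / d[1]) * 180 / pi
}

vp_direction <- function(cam) {
  v0 <- vanishing_point_of_direction(c(1, 0, 0), build_projection(cam))
  d <- v0 - cam$image_size / 2
  d / sqrt(sum(d^2))
}

test_that("solve_elevation inverts the forward-rendered direction", {
  for (az in c(10, 33.5, 61, 80)) for (el in c(2, 9.5, 25)) {
    cam <- camera_params(az, el, 0, 17, c(0, -20, 8))
    got <- solve_elevation(az, vp_direction(cam))
    expect_equal(got, el, tolerance = 1e-4)
    expect_equal(got, oracle_elevation(az, vp_direction(cam)), tolerance = 1e-5)
  }
})

test_that("solve_elevation limit and no-solution cases", {
  # direction along the horizontal through the centre: elevation -> 0
  expect_equal(solve_elevation(30, c(1, 0)), 0)
  # flipped 180 degrees: no solution
  expect_true(is.na(solve_elevation(30, c(-1, 0.2))))
  # upward-pointing (v0 below centre): no solution
  expect_true(is.na(solve_elevation(30, c(1, 0.3))))
  # mirrored pan: negative azimuth with v0 left of centre
  cam <- camera_params(-40, 12, 0, 20, c(0, -20, 8))
  expect_equal(solve_elevation(-40, vp_direction(cam)), 12, tolerance = 1e-4)
})

test_that("fit_fov recovers the rendered field of view in closed form", {
  for (az in c(20, 45, 70)) for (fov in c(6, 18, 35)) {
    cam <- camera_params(az, 11, 0, fov, c(0, -25, 9))
    v0 <- vanishing_point_of_direction(c(1, 0, 0), build_projection(cam))
    expect_equal(fit_fov(az, 11, v0, cam$image_size), fov, tolerance = 1e-4)
  }
  # halving the vanishing-point distance doubles the fov's tangent
  cam <- camera_params(30, 10, 0, 20, c(0, -20, 8))
  v0 <- vanishing_point_of_direction(c(1, 0, 0), build_projection(cam))
  c0 <- cam$image_size / 2
  vhalf <- c0 + (v0 - c0) / 2
  f1 <- tan(fit_fov(30, 10, v0, cam$image_size) * pi / 360)
  f2 <- tan(fit_fov(30, 10, vhalf, cam$image_size) * pi / 360)
  expect_equal(f2 / f1, 2, tolerance = 1e-9)
  # v0 at the centre is degenerate
  expect_true(is.na(fit_fov(30, 10, c0, cam$image_size)))
})

test_that("solve_translation recovers position from analytic lanes", {
  cam <- test_camera(azimuth = 40, elevation = 10, fov = 15, z = 9)
  lanes <- analytic_lane_set(cam)
  pos <- solve_translation(cam$azimuth, cam$elevation, cam$fov, lanes,
                           track_scene(), cam$image_size)
  expect_equal_tol(pos, cam$position, 1e-3)
})

test_that("translation scales linearly with lane spacing (similar triangles)", {
  cam <- test_camera(azimuth = 40, elevation = 10, fov = 15, z = 9)
  lanes <- analytic_lane_set(cam)
  # claiming lanes are twice as wide must move the camera twice as far
  pos1 <- solve_translation(cam$azimuth, cam$elevation, cam$fov, lanes,
                            track_scene(), cam$image_size)
  pos2 <- solve_translation(cam$azimuth, cam$elevation, cam$fov, lanes,
                            track_scene(lane_width = 2 * 1.22), cam$image_size)
  expect_equal_tol(pos2, 2 * pos1, 1e-6)
})

test_that("translation degrades smoothly under 1 px lane jitter", {
  cam <- camera_params(35, 9, 0, 14, c(0, -40, 7.5))
  lanes <- analytic_lane_set(cam)
  dist <- sqrt(sum((cam$position - c(45, 4, 0))^2))
  set.seed(99)
  errs <- vapply(1:100, function(i) {
    jit <- tibble::as_tibble(lanes)
    th <- jit$angle * pi / 180
    off <- rnorm(nrow(jit), 0, 1)
    jit$y1 <- jit$y1 + off * cos(th); jit$x1 <- jit$x1 - off * sin(th)
    jit$y2 <- jit$y2 + off * cos(th); jit$x2 <- jit$x2 - off * sin(th)
    jit$py <- jit$py + off * cos(th); jit$px <- jit$px - off * sin(th)
    jit <- structure(jit, image_size = cam$image_size, class = class(lanes))
    pos <- solve_translation(cam$azimuth, cam$elevation, cam$fov, jit,
                             track_scene(), cam$image_size)
    sqrt(sum((pos - cam$position)^2))
  }, numeric(1))
  expect_lt(mean(errs), 0.02 * dist)
  expect_lt(max(errs), 0.1 * dist)
})

test_that("enumeration sweeps the azimuth grid and satisfies the constraint", {
  cam <- test_camera(azimuth = 33.5, elevation = 9, fov = 16, z = 8)
  proj <- build_projection(cam)
  lanes <- analytic_lane_set(cam)
  v0 <- vanishing_point_of_direction(c(1, 0, 0), proj)
  cands <- enumerate_candidates(v0, lanes)

  # on-grid azimuth: that candidate matches truth within per-stage tolerances
  i <- which(abs(cands$azimuth - 33.5) < 1e-9)
  expect_length(i, 1)
  expect_equal(cands$elevation[i], 9, tolerance = 1e-4)
  expect_equal(cands$fov[i], 16, tolerance = 1e-3)
  expect_equal_tol(c(cands$x[i], cands$y[i], cands$z[i]), cam$position, 1e-3)

  # constraint satisfaction en masse: every candidate reprojects the lane
  # vanishing point onto v0
  vperr <- vapply(seq_len(nrow(cands)), function(k) {
    pk <- build_projection(candidate_camera(cands, k))
    sqrt(sum((vanishing_point_of_direction(c(1, 0, 0), pk) - v0)^2))
  }, numeric(1))
  expect_lt(max(vperr), 0.5)

  # candidate positions trace a connected curve (no jumps)
  gaps <- sqrt(diff(cands$x)^2 + diff(cands$y)^2 + diff(cands$z)^2)
  expect_lt(max(gaps) / stats::median(gaps), 100)
  expect_lt(max(gaps), 5)

  # azimuths strictly increasing on the sweep grid
  expect_true(all(diff(cands$azimuth) > 0))
})

test_that("selection by the true second vanishing point recovers the camera", {
  cam <- test_camera(azimuth = 38.2, elevation = 11, fov = 13, z = 10)
  proj <- build_projection(cam)
  lanes <- analytic_lane_set(cam)
  v0 <- vanishing_point_of_direction(c(1, 0, 0), proj)
  cands <- enumerate_candidates(v0, lanes)
  v1 <- vanishing_point_of_direction(c(0, 1, 0), proj)
  sel <- select_candidate(cands, constraint_v1(v1))
  expect_lt(abs(sel$azimuth - cam$azimuth), 0.25)
  expect_lt(abs(sel$elevation - cam$elevation), 0.1)
  expect_lt(abs(sel$fov - cam$fov) / cam$fov, 0.01)
})

test_that("selection by height returns an on-grid candidate exactly", {
  cam <- test_camera(azimuth = 30, elevation = 9, fov = 16, z = 8)
  lanes <- analytic_lane_set(cam)
  v0 <- vanishing_point_of_direction(c(1, 0, 0), build_projection(cam))
  cands <- enumerate_candidates(v0, lanes)
  k <- which.min(abs(cands$azimuth - 25))
  # the height curve need not be unimodal along the sweep; the selector may
  # legitimately warn while still returning the exact on-grid candidate
  sel <- suppressWarnings(select_candidate(cands, constraint_height(cands$z[k])))
  expect_equal(sel$azimuth, cands$azimuth[k], tolerance = 1e-6)
  expect_equal(sel$position[3], cands$z[k], tolerance = 1e-9)
})

test_that("ties resolve to the lower azimuth", {
  cands <- structure(
    tibble::tibble(azimuth = c(20, 40), elevation = c(10, 12), roll = 0,
                   fov = c(15, 14), x = 0, y = c(-20, -25), z = c(6, 6),
                   v1_x = c(-500, -700), v1_y = -100),
    v0 = c(3000, -200), image_size = c(1280, 720), scene = track_scene(),
    sweep_step = 0.5, failures = tibble::tibble(),
    class = c("candidate_set", class(tibble::tibble())))
  sel <- select_candidate(cands, constraint_height(8)) # both residuals -2
  expect_equal(sel$azimuth, 20)
})

test_that("the ambiguity of a single vanishing point is real", {
  # two widely separated candidates both overlay the detected lanes
  cam <- test_camera(azimuth = 45, elevation = 10, fov = 14, z = 9)
  lanes <- analytic_lane_set(cam)
  v0 <- vanishing_point_of_direction(c(1, 0, 0), build_projection(cam))
  cands <- enumerate_candidates(v0, lanes)
  picks <- c(which.min(abs(cands$azimuth - 25)), which.min(abs(cands$azimuth - 65)))
  expect_gt(abs(diff(cands$azimuth[picks])), 30)
  w <- attr(cands, "scene")$lane_width
  for (k in picks) {
    pk <- build_projection(candidate_camera(cands, k))
    # each detected lane endpoint, ray-traced through the candidate, lands
    # on a lane grid line; its image distance to that line stays under 1 px
    for (i in seq_len(nrow(lanes))) {
      for (pt in list(c(lanes$x1[i], lanes$y1[i]), c(lanes$x2[i], lanes$y2[i]))) {
        g <- ray_trace_to_ground(pt, pk)
        gy <- round(g[2] / w) * w
        a <- project_points(c(g[1] - 3, gy, 0), pk)
        b <- project_points(c(g[1] + 3, gy, 0), pk)
        u <- c(b$x - a$x, b$y - a$y); u <- u / sqrt(sum(u^2))
        dpx <- abs((pt[1] - a$x) * (-u[2]) + (pt[2] - a$y) * u[1])
        expect_lt(dpx, 1)
      }
    }
  }
})
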