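# Alignment, reprojection, knee angles, touch-downs and strategies.

sagittal_camera <- function(target, az = 90, dist = 40, el = 5, fov = 25) {
  pos <- target + dist * c(-cos(az * pi / 180), -sin(az * pi / 180), 0) + c(0, 0, 2)
  camera_params(az, el, 0, fov, pos)
}

test_that("align_2d closed form handles exact similarity transforms", {
  proj <- build_projection(test_camera())
  s <- project_skeleton(place_skeleton(standing_skeleton(), c(25, 3)), proj)

  ref <- s; ref$x <- 2 * s$x + 3; ref$y <- 2 * s$y + 4
  tr <- align_2d(s, ref)
  expect_equal(tr$scale, 2, tolerance = 1e-12)
  expect_equal(tr$translation, c(3, 4), tolerance = 1e-9)
  al <- trackcal:::apply_alignment(s, tr)
  expect_equal_tol(cbind(al$x, al$y), cbind(ref$x, ref$y), 1e-9)

  # identity when reference equals projection
  tr0 <- align_2d(s, s)
  expect_equal(tr0$scale, 1, tolerance = 1e-12)
  expect_equal_tol(tr0$translation, c(0, 0), 1e-9)
})

test_that("align_2d closed form beats random probes", {
  set.seed(31)
  proj <- build_projection(test_camera())
  base <- project_skeleton(place_skeleton(standing_skeleton(), c(25, 3)), proj)
  for (rep in 1:3) {
    ref <- base
    ref$x <- 1.3 * base$x + 10 + rnorm(17, 0, 6)
    ref$y <- 1.3 * base$y - 7 + rnorm(17, 0, 6)
    tr <- align_2d(base, ref)
    al <- trackcal:::apply_alignment(base, tr)
    best <- sum((al$x - ref$x)^2 + (al$y - ref$y)^2)
    # 10,000 random (scale, translation) probes around the optimum
    sc <- runif(10000, 0.5, 2.5)
    tx <- runif(10000, -50, 70); ty <- runif(10000, -60, 50)
    probes <- vapply(1:10000, function(i) {
      sum((sc[i] * base$x + tx[i] - ref$x)^2 + (sc[i] * base$y + ty[i] - ref$y)^2)
    }, numeric(1))
    expect_gte(min(probes), best)
  }
  # degenerate: all projected joints coincident
  degen <- base; degen$x[] <- 5; degen$y[] <- 5
  expect_error(align_2d(degen, base), class = "trackcal_error_degenerate")
})

test_that("reprojection error is zero on self-projection and exact on offsets", {
  proj <- build_projection(test_camera())
  s3 <- place_skeleton(standing_skeleton(), c(25, 3))
  ref <- project_skeleton(s3, proj)
  re <- reprojection_error(s3, proj, ref)
  expect_lt(re$px, 1e-9)
  expect_lt(re$mm, 1e-9)

  # uniform (3, 4) px offset without alignment: mean error exactly 5 px,
  # and the mm scaling follows the reference pixel height
  off <- ref; off$x <- ref$x + 3; off$y <- ref$y + 4
  re2 <- reprojection_error(s3, proj, off, athlete_height_mm = 1800,
                            align = FALSE)
  expect_equal(re2$px, 5, tolerance = 1e-9)
  expect_equal(re2$mm, 5 * 1800 / skeleton_height(off), tolerance = 1e-9)
})

test_that("reprojection error under 2 px jitter matches the Rayleigh mean", {
  proj <- build_projection(test_camera())
  s3 <- place_skeleton(standing_skeleton(), c(25, 3))
  ref0 <- project_skeleton(s3, proj)
  set.seed(123)
  sigma <- 2
  errs <- vapply(1:1000, function(i) {
    ref <- ref0
    ref$x <- ref0$x + rnorm(17, 0, sigma)
    ref$y <- ref0$y + rnorm(17, 0, sigma)
    reprojection_error(s3, proj, ref)$px
  }, numeric(1))
  expect_lt(abs(mean(errs) / (sigma * sqrt(pi / 2)) - 1), 0.05)
})

test_that("knee angles match the independent dot-product oracle", {
  mk <- function(hip, knee, ankle) {
    m <- matrix(0, 17, 2)
    m[, 1] <- seq_len(17); m[, 2] <- seq_len(17) # non-degenerate filler
    m[12, ] <- hip; m[14, ] <- knee; m[16, ] <- ankle
    skeleton_2d(m)
  }
  expect_equal(knee_angle_2d(mk(c(0, 0), c(0, 1), c(0, 2)), "left"), 180)
  expect_equal(knee_angle_2d(mk(c(0, 0), c(0, 1), c(1, 1)), "left"), 90)

  hip <- c(0, 0); knee <- c(1, 0); ankle <- c(2, tan(30 * pi / 180))
  oracle <- acos(sum((hip - knee) * (ankle - knee)) /
                   (sqrt(sum((hip - knee)^2)) * sqrt(sum((ankle - knee)^2)))) * 180 / pi
  expect_equal(knee_angle_2d(mk(hip, knee, ankle), "left"), oracle,
               tolerance = 1e-9)
  expect_equal(oracle, 150, tolerance = 1e-9)

  expect_error(knee_angle_2d(mk(c(1, 1), c(1, 1), c(2, 2)), "left"),
               class = "trackcal_error_undefined_angle")
})

test_that("approx 3D knee error: sagittal sensitivity near 1, frontal amplifies", {
  s <- standing_skeleton()
  tgt <- trackcal:::joint_xyz(s, "pelvis")
  p_sag <- build_projection(sagittal_camera(tgt))
  e <- approx_3d_knee_error(s, p_sag, 10, "left")
  expect_gte(attr(e, "sensitivity"), 0.9)
  expect_lte(attr(e, "sensitivity"), 1.1)

  # monotone decrease of sensitivity toward the frontal view
  svals <- vapply(seq(80, 10, by = -10), function(az) {
    attr(approx_3d_knee_error(s, build_projection(sagittal_camera(tgt, az)),
                              10, "left"), "sensitivity")
  }, numeric(1))
  expect_true(all(diff(svals) < 0))
})

test_that("approx 3D knee error recovers a known 3D perturbation", {
  s <- standing_skeleton()
  tgt <- trackcal:::joint_xyz(s, "pelvis")
  proj <- build_projection(sagittal_camera(tgt, az = 40))
  s5 <- trackcal:::rotate_lower_leg(s, "left", 5)
  k2 <- abs(knee_angle_2d(project_skeleton(s5, proj), "left") -
              knee_angle_2d(project_skeleton(s, proj), "left"))
  est <- approx_3d_knee_error(s, proj, k2, "left")
  expect_lt(abs(as.numeric(est) - 5) / 5, 0.2)
})

test_that("touch-down detection matches the scripted gait", {
  cam <- camera_params(85, 5, 0, 25, c(30, -30, 3))
  case <- make_case(cam, n_frames = 40, seed = 2)
  td <- detect_touchdown_frames(case$skeletons2d)
  expect_gte(length(td), 2)
  for (f in case$touchdowns$frame)
    expect_lte(min(abs(td - f)), 1)

  expect_error(detect_touchdown_frames(case$skeletons2d[1:3]),
               class = "trackcal_error_too_short")
})

test_that("stationary sequences collapse to midpoints; airborne gives none", {
  proj <- build_projection(test_camera())
  s2 <- project_skeleton(place_skeleton(standing_skeleton(), c(25, 3)), proj)
  static <- rep(list(s2), 9)
  td <- detect_touchdown_frames(static)
  # frames 2..9 qualify (frame 1 has no velocity estimate); one run,
  # collapsed to its midpoint
  expect_equal(td, 6L)

  # airborne: ankles steadily rising relative to the pelvis, so no frame
  # combines a lowest-point ankle with low relative velocity
  lift <- lapply(1:9, function(i) {
    s <- s2
    sel <- s$joint %in% c("ankle_l", "ankle_r")
    s$y[sel] <- s$y[sel] - 6 * i
    s
  })
  expect_length(detect_touchdown_frames(lift), 0)
})

test_that("straighten_path projects anchors onto the fitted line rigidly", {
  r <- generate_runner(n_frames = 20, seed = 4)
  # exactly collinear anchors: unchanged
  line_anchors <- tibble::tibble(x = seq(0, 19) * 0.8 + 1, y = 0.5 * (seq(0, 19) * 0.8 + 1) + 2)
  line_skels <- lapply(seq_len(20), function(i)
    place_skeleton(r$skeletons[[i]], c(line_anchors$x[i], line_anchors$y[i])))
  st <- straighten_path(line_skels, line_anchors)
  expect_equal_tol(st$anchors$x, line_anchors$x, 1e-9)
  expect_equal_tol(st$skeletons[[3]]$x, line_skels[[3]]$x, 1e-9)

  # anchors on a known arc: output collinear, moved by the analytic chord
  radius <- 60
  theta <- seq(-0.3, 0.3, length.out = 20)
  arc <- tibble::tibble(x = radius * sin(theta),
                        y = radius * (1 - cos(theta)))
  skels <- lapply(seq_len(20), function(i)
    place_skeleton(r$skeletons[[i]], c(arc$x[i], arc$y[i])))
  st2 <- straighten_path(skels, arc)
  fitted <- cbind(st2$anchors$x, st2$anchors$y)
  ctr <- colMeans(fitted)
  u <- prcomp(fitted)$rotation[, 1]
  resid <- sweep(fitted, 2, ctr) %*% c(-u[2], u[1])
  expect_lt(max(abs(resid)), 1e-9)

  # rigid: internal joint geometry preserved exactly
  d0 <- dist(trackcal:::skeleton_matrix(skels[[7]]))
  d1 <- dist(trackcal:::skeleton_matrix(st2$skeletons[[7]]))
  expect_equal_tol(as.numeric(d0), as.numeric(d1), 1e-12)

  # coincident anchors: identity with a warning
  same <- tibble::tibble(x = rep(1, 20), y = rep(2, 20))
  expect_warning(st3 <- straighten_path(skels, same))
  expect_equal(st3$anchors, same)
})

test_that("rotate_to_facing yields the requested facing for random yaws", {
  set.seed(61)
  s0 <- standing_skeleton()
  worst <- 0
  for (i in 1:1000) {
    yaw <- runif(1, -180, 180)
    s <- trackcal:::rotate_skeleton_z(s0, yaw, c(0, 0))
    ang <- runif(1, 0, 2 * pi)
    f <- c(cos(ang), sin(ang))
    got <- trackcal:::facing_of(rotate_to_facing(s, f))
    worst <- max(worst, max(abs(got - f)))
  }
  expect_lt(worst, 1e-9)

  # already facing (1, 0): unchanged
  s <- rotate_to_facing(s0, c(1, 0))
  expect_equal_tol(s$x, s0$x, 1e-9)

  # facing (0,1) to (1,0): -90 degree rotation, distances preserved
  sy <- rotate_to_facing(s0, c(0, 1))
  back <- rotate_to_facing(sy, c(1, 0))
  expect_equal_tol(back$x, s0$x, 1e-9)
  expect_equal_tol(as.numeric(dist(trackcal:::skeleton_matrix(sy))),
                   as.numeric(dist(trackcal:::skeleton_matrix(s0))), 1e-9)
})

test_that("evaluate: zero metrics on perfect cases, bias recovered, rotation helps", {
  cam <- camera_params(85, 5, 0, 25, c(30, -30, 3))
  perfect <- make_case(cam, n_frames = 30, seed = 2)
  ev0 <- evaluate_case(perfect)
  # at anchored (touch-down) frames the placement is exact: all metrics zero
  td <- tidy(ev0)[tidy(ev0)$frame %in% perfect$touchdowns$frame, ]
  expect_gte(nrow(td), 1)
  expect_lt(max(td$reproj_px, td$knee2d_deg, td$knee3d_deg), 1e-6)
  # between touch-downs the monocular ankle-height convention leaves only a
  # second-order perspective residual
  g0 <- glance(ev0)
  expect_lt(g0$reproj_px_mean, 0.02)
  expect_lt(g0$knee2d_deg_mean, 0.02)
  expect_lt(g0$knee3d_deg_mean, 0.02)

  # injected knee bias, near-sagittal camera: recovered within 10%
  b <- 10
  biased <- make_case(cam, n_frames = 30,
                      noise = noise_config(knee_bias_deg = b), seed = 2)
  gb <- glance(evaluate_case(biased))
  expect_lt(abs(gb$knee2d_deg_mean - b) / b, 0.10)

  # yaw drift: rotation knowledge reduces all knee errors vs base
  cam2 <- camera_params(45, 8, 0, 20, c(0, -30, 6))
  drift <- make_case(cam2, n_frames = 30,
                     noise = noise_config(yaw_drift_deg = 0.6), seed = 5)
  gbase <- glance(evaluate_case(drift, strategy = "base"))
  grot <- glance(evaluate_case(drift, strategy = "rotation"))
  gmov <- glance(evaluate_case(drift, strategy = "movement"))
  expect_lt(grot$knee3d_deg_mean, gbase$knee3d_deg_mean)
  expect_lt(grot$reproj_px_mean, gbase$reproj_px_mean)
  # movement (path straightening) never hurts
  expect_lte(gmov$reproj_px_mean, gbase$reproj_px_mean * 1.01)
})

test_that("metrics are invariant under similarity transforms of the reference", {
  proj <- build_projection(test_camera())
  s3 <- place_skeleton(standing_skeleton(), c(25, 3))
  ref <- project_skeleton(s3, proj)
  set.seed(77)
  ref$x <- ref$x + rnorm(17, 0, 3); ref$y <- ref$y + rnorm(17, 0, 3)
  e1 <- reprojection_error(s3, proj, ref)$px
  ref2 <- ref; ref2$x <- 1.7 * ref$x + 31; ref2$y <- 1.7 * ref$y - 12
  e2 <- reprojection_error(s3, proj, ref2)$px
  expect_equal(e2, 1.7 * e1, tolerance = 1e-9) # px errors scale with the frame
  expect_equal(knee_angle_2d(ref2, "left"), knee_angle_2d(ref, "left"),
               tolerance = 1e-9)
})
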