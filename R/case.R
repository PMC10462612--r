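# Full paired fixtures: ground-truth camera + runner with exact 2D/3D
# correspondence, plus parametric corruptions that emulate the error modes of
# monocular 3D pose lifting (2D joint jitter, knee-angle bias, yaw drift
# producing a curved trajectory).

#' Noise / corruption configuration for synthetic cases
#'
#' @param jitter2d_sd Gaussian jitter applied to the reference 2D joints,
#'   pixels per coordinate.
#' @param knee_bias_deg Systematic knee-angle bias injected into the
#'   "predicted" 3D skeletons, degrees (lower leg rotated about the knee
#'   flexion axis).
#' @param yaw_drift_deg Per-frame heading drift, degrees: the predicted
#'   skeletons follow a curved path and yaw with it, emulating the curved
#'   trajectories produced by 2D-to-3D lifting under camera pan.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(jitter2d_sd = 0, knee_bias_deg = 0, yaw_drift_deg = 0) {
  structure(list(jitter2d_sd = jitter2d_sd, knee_bias_deg = knee_bias_deg,
                 yaw_drift_deg = yaw_drift_deg), class = "noise_config")
}

rotate_skeleton_z <- function(skel, angle_deg, centre_xy) {
  th <- deg2rad(angle_deg)
  c0 <- cos(th); s0 <- sin(th)
  dx <- skel$x - centre_xy[1]; dy <- skel$y - centre_xy[2]
  out <- skel
  out$x <- centre_xy[1] + c0 * dx - s0 * dy
  out$y <- centre_xy[2] + s0 * dx + c0 * dy
  out
}

# Rotate the lower leg (ankle about the knee) by delta degrees about the
# knee flexion axis (normal of the hip-knee-ankle plane). Positive delta
# opens the knee angle toward the straight leg.
rotate_lower_leg <- function(skel3d, side = c("left", "right"), delta_deg) {
  side <- match.arg(side)
  sfx <- if (side == "left") "_l" else "_r"
  hip <- joint_xyz(skel3d, paste0("hip", sfx))
  knee <- joint_xyz(skel3d, paste0("knee", sfx))
  ankle <- joint_xyz(skel3d, paste0("ankle", sfx))
  u <- hip - knee; v <- ankle - knee
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9)
    abort_trackcal("Degenerate leg: coincident joints.", "undefined_angle")
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  na <- sqrt(sum(ax^2))
  if (na < 1e-8) {
    # straight leg: flexion plane undefined; use a horizontal axis
    # perpendicular to the leg as the documented fallback
    ld <- v / sqrt(sum(v^2))
    ax <- c(-ld[2], ld[1], 0)
    na <- sqrt(sum(ax^2))
    if (na < 1e-9) ax <- c(0, 1, 0) else ax <- ax / na
  } else ax <- ax / na
  th <- deg2rad(delta_deg)
  # Rodrigues rotation of v about ax
  vr <- v * cos(th) + c(ax[2] * v[3] - ax[3] * v[2],
                        ax[3] * v[1] - ax[1] * v[3],
                        ax[1] * v[2] - ax[2] * v[1]) * sin(th) +
    ax * sum(ax * v) * (1 - cos(th))
  out <- skel3d
  i <- which(out$joint == paste0("ankle", sfx))
  newa <- knee + vr
  out$x[i] <- newa[1]; out$y[i] <- newa[2]; out$z[i] <- newa[3]
  out
}

#' Build a full synthetic evaluation case
#'
#' Combines a ground-truth camera, track scene and runner into a paired
#' fixture: true 3D skeletons, their exact 2D projections (optionally
#' jittered) as the reference, and corrupted "predicted" 3D skeletons
#' emulating pose-estimator error modes.
#'
#' @param camera A [camera_params()] (ground truth).
#' @param scene A [track_scene()].
#' @param gait A [gait_config()].
#' @param n_frames Number of frames.
#' @param noise A [noise_config()].
#' @param seed Integer seed for the gait phase and all noise draws.
#' @param render_image If `TRUE`, also render the lane image for the first
#'   frame (via [render_track()]).
#' @return An object of class `synthetic_case` with elements `camera`,
#'   `scene`, `skeletons3d` (true), `skeletons3d_pred` (corrupted),
#'   `skeletons2d` (reference projections), `anchors`, `touchdowns`,
#'   `v0_true`, `frame` (optional `synthetic_frame`), `noise` and `seed`.
#' @export
make_case <- function(camera, scene = track_scene(), gait = gait_config(),
                      n_frames = 50, noise = noise_config(), seed = 1,
                      render_image = FALSE) {
  runner <- generate_runner(gait, n_frames, seed)
  proj <- build_projection(camera)

  skels2d <- lapply(runner$skeletons, project_skeleton, proj = proj)
  if (noise$jitter2d_sd > 0) {
    skels2d <- with_local_seed(seed + 1L, lapply(skels2d, function(s) {
      s$x <- s$x + stats::rnorm(17, 0, noise$jitter2d_sd)
      s$y <- s$y + stats::rnorm(17, 0, noise$jitter2d_sd)
      s
    }))
  }

  pred <- runner$skeletons
  if (noise$knee_bias_deg != 0) {
    pred <- lapply(pred, function(s) {
      s <- rotate_lower_leg(s, "left", noise$knee_bias_deg)
      rotate_lower_leg(s, "right", noise$knee_bias_deg)
    })
  }
  anchors <- runner$anchors
  if (noise$yaw_drift_deg != 0) {
    a <- as.matrix(anchors[, c("x", "y")])
    heading <- noise$yaw_drift_deg * (seq_len(n_frames) - 1)
    newa <- a
    if (n_frames >= 2) {
      for (i in 2:n_frames) {
        th <- deg2rad(heading[i])
        step <- a[i, ] - a[i - 1, ]
        newa[i, ] <- newa[i - 1, ] + c(cos(th) * step[1] - sin(th) * step[2],
                                       sin(th) * step[1] + cos(th) * step[2])
      }
    }
    pred <- lapply(seq_len(n_frames), function(i) {
      s <- rotate_skeleton_z(pred[[i]], heading[i], a[i, ])
      s$x <- s$x + (newa[i, 1] - a[i, 1])
      s$y <- s$y + (newa[i, 2] - a[i, 2])
      s
    })
  }

  structure(list(camera = camera, scene = scene,
                 skeletons3d = runner$skeletons, skeletons3d_pred = pred,
                 skeletons2d = skels2d, anchors = anchors,
                 touchdowns = runner$touchdowns,
                 v0_true = lane_vanishing_point(proj),
                 frame = if (render_image) render_track(camera, scene, seed = seed),
                 noise = noise, seed = seed, gait = gait),
            class = "synthetic_case")
}
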