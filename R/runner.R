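# Parametric 17-joint runner. This is deliberately a simple kinematic gait
# (sinusoidal limb cycling with two-link leg inverse kinematics), not a
# biomechanical model: it exists to provide paired 2D/3D ground truth with
# scripted touch-downs and well-defined knee angles.

#' Gait configuration for the synthetic runner
#'
#' @param speed Forward speed, m/s (elite middle-distance pace by default).
#' @param cadence Steps per second (both legs counted).
#' @param fps Frames per second of the emitted sequence.
#' @param lane 0-based lane index the athlete runs in (centred in the lane).
#' @param pelvis_height Standing pelvis height, metres.
#' @param thigh,shank Leg segment lengths, metres.
#' @param foot_lift Peak ankle lift during swing, metres.
#' @param reach Fore-aft ankle amplitude relative to the pelvis, metres.
#' @return A list of class `gait_config`. The step length is
#'   `speed / cadence`; touch-downs of alternating feet are spaced exactly
#'   one step length apart by construction.
#' @export
gait_config <- function(speed = 8.5, cadence = 10 / 3, fps = 50, lane = 3,
                        pelvis_height = 0.95, thigh = 0.48, shank = 0.48,
                        foot_lift = 0.45, reach = 0.47) {
  structure(list(speed = speed, cadence = cadence, fps = fps, lane = lane,
                 pelvis_height = pelvis_height, thigh = thigh, shank = shank,
                 foot_lift = foot_lift, reach = reach),
            class = "gait_config")
}

# Two-link inverse kinematics: knee position given hip, ankle and segment
# lengths; the knee vertex points toward `fwd` (the facing direction).
knee_ik <- function(hip, ankle, l1, l2, fwd) {
  v <- ankle - hip
  D <- sqrt(sum(v^2))
  Dmax <- (l1 + l2) * 0.999
  if (D > Dmax) { # clamp: pull the ankle toward the hip along v
    ankle <- hip + v * Dmax / D
    v <- ankle - hip
    D <- Dmax
  }
  a <- (l1^2 - l2^2 + D^2) / (2 * D)
  h <- sqrt(max(l1^2 - a^2, 0))
  u <- v / D
  n <- fwd - sum(fwd * u) * u
  nn <- sqrt(sum(n^2))
  n <- if (nn < 1e-9) c(0, 0, 0) else n / nn
  list(knee = hip + a * u + h * n, ankle = ankle)
}

#' Generate a synthetic runner sequence
#'
#' Emits a deterministic 17-joint skeleton sequence advancing along `+x`
#' (facing the finish line), with sinusoidal limb cycling, two-link leg
#' inverse kinematics, and scripted touch-down events. At touch-down the
#' ankle is at its lowest point and momentarily stationary relative to the
#' pelvis. Output is a pure function of `(gait, n_frames, seed)`; the seed
#' only draws the initial gait phase.
#'
#' @param gait A [gait_config()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed (initial phase).
#' @return A list of class `runner_sequence`: `skeletons` (list of
#'   `skeleton3d`), `anchors` (tibble `frame`, `x`, `y` of the contact
#'   ankle's ground position), `touchdowns` (tibble `frame`, `side`, `x`,
#'   `y`), and the `gait`.
#' @export
generate_runner <- function(gait = gait_config(), n_frames = 50, seed = 1) {
  stopifnot(inherits(gait, "gait_config"), n_frames >= 1)
  phi0 <- with_local_seed(seed, stats::runif(1, 0, 2 * pi))
  g <- gait
  # snap the phase so touch-down events land exactly on frame times (the
  # default cadence makes the step interval an integer frame count); the
  # contact ankle then sits at its exact lowest point on those frames
  omega0 <- 2 * pi * g$cadence / 2
  t1 <- ((-phi0) %% pi) / omega0
  phi0 <- phi0 + omega0 * (t1 - round(t1 * g$fps) / g$fps)
  lane_y <- (g$lane + 0.5) * 1.22 # centred in the lane; scene width standard
  leg_hz <- g$cadence / 2
  tt <- (seq_len(n_frames) - 1) / g$fps
  omega <- 2 * pi * leg_hz

  hip_half <- 0.10
  shoulder_half <- 0.19
  leg_len <- g$thigh + g$shank

  skels <- vector("list", n_frames)
  anchors_x <- numeric(n_frames)
  anchors_y <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    t <- tt[i]
    px <- g$speed * t
    pz <- g$pelvis_height + 0.03 * sin(2 * omega * t + phi0)
    phiL <- omega * t + phi0
    phiR <- phiL + pi

    mk_leg <- function(phi, side_y) {
      hip <- c(px, lane_y + side_y, pz - 0.05)
      ax <- px - g$reach * cos(phi)
      az <- 0.08 + g$foot_lift * (1 - cos(phi)) / 2 *
        (0.25 + 0.75 * (1 + sin(phi - pi / 2)) / 2)
      ankle <- c(ax, lane_y + side_y, az)
      ik <- knee_ik(hip, ankle, g$thigh, g$shank, c(1, 0, 0))
      list(hip = hip, knee = ik$knee, ankle = ik$ankle)
    }
    legL <- mk_leg(phiL, +hip_half)
    legR <- mk_leg(phiR, -hip_half)

    mk_arm <- function(phi, side_y) {
      sh <- c(px, lane_y + side_y, pz + 0.55)
      th <- 0.7 * sin(phi) # arms counter-swing the same-side leg's opposite
      el <- sh + 0.28 * c(sin(th), 0, -cos(th))
      wr <- el + 0.25 * c(sin(th + 1.0), 0, -cos(th + 1.0))
      list(sh = sh, el = el, wr = wr)
    }
    armL <- mk_arm(phiR, +shoulder_half)
    armR <- mk_arm(phiL, -shoulder_half)

    m <- rbind(
      head = c(px + 0.02, lane_y, pz + 0.72),
      neck = c(px + 0.01, lane_y, pz + 0.58),
      chest = c(px, lane_y, pz + 0.40),
      navel = c(px, lane_y, pz + 0.18),
      pelvis = c(px, lane_y, pz),
      shoulder_l = armL$sh, shoulder_r = armR$sh,
      elbow_l = armL$el, elbow_r = armR$el,
      wrist_l = armL$wr, wrist_r = armR$wr,
      hip_l = legL$hip, hip_r = legR$hip,
      knee_l = legL$knee, knee_r = legR$knee,
      ankle_l = legL$ankle, ankle_r = legR$ankle)
    skels[[i]] <- skeleton_3d(unname(m))
    cj <- contact_joint(skels[[i]])
    cpos <- joint_xyz(skels[[i]], cj)
    anchors_x[i] <- cpos[1]
    anchors_y[i] <- cpos[2]
  }

  # Scripted touch-downs: leg phase crosses 0 (mod 2pi), where the ankle is
  # lowest and stationary relative to the pelvis. Successive touch-downs of
  # alternating feet are exactly one step length (speed / cadence) apart.
  td <- list()
  for (side in c("l", "r")) {
    off <- if (side == "l") phi0 else phi0 + pi
    kk <- seq(ceiling(off / (2 * pi) - 1e-9),
              floor((omega * max(tt) + off) / (2 * pi) + 1e-9))
    t_ev <- (2 * pi * kk - off) / omega
    t_ev <- t_ev[t_ev >= -1e-9 & t_ev <= max(tt) + 1e-9]
    if (length(t_ev)) {
      fr <- pmin(pmax(round(t_ev * g$fps) + 1, 1), n_frames)
      td[[side]] <- tibble::tibble(
        frame = as.integer(fr), side = side,
        x = g$speed * t_ev - g$reach, y = lane_y +
          ifelse(side == "l", hip_half, -hip_half))
    }
  }
  touchdowns <- dplyr::bind_rows(td)
  if (nrow(touchdowns) == 0)
    touchdowns <- tibble::tibble(frame = integer(), side = character(),
                                 x = double(), y = double())
  touchdowns <- dplyr::arrange(touchdowns, .data$frame)

  # per-frame anchor: the athlete's ground position, i.e. the most recent
  # touch-down (the first one before it happens); falls back to the contact
  # ankle's ground track if no touch-down occurs in range
  if (nrow(touchdowns) > 0) {
    idx <- findInterval(seq_len(n_frames), touchdowns$frame)
    idx[idx == 0] <- 1L
    anchors_x <- touchdowns$x[idx]
    anchors_y <- touchdowns$y[idx]
  }

  structure(list(
    skeletons = skels,
    anchors = tibble::tibble(frame = seq_len(n_frames), x = anchors_x,
                             y = anchors_y),
    touchdowns = touchdowns, gait = g, n_frames = n_frames, seed = seed),
    class = "runner_sequence")
}
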