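# Pose auditing: alignment, reprojection error, knee-angle metrics,
# touch-down detection, and the two domain-knowledge correction strategies.

#' Least-squares 2D alignment (scale + translation)
#'
#' Finds the closed-form scale `s > 0` and translation `t` minimising
#' `sum_j || s * p_j + t - q_j ||^2` over all 17 joints, with `p` the
#' projected and `q` the reference skeleton. No rotation component.
#'
#' @param projected,reference `skeleton2d` objects.
#' @return A list of class `alignment_transform` with elements `scale` and
#'   `translation` (length-2, px).
#' @export
align_2d <- function(projected, reference) {
  p <- skeleton_matrix(projected)
  q <- skeleton_matrix(reference)
  pbar <- colMeans(p); qbar <- colMeans(q)
  pc <- sweep(p, 2, pbar); qc <- sweep(q, 2, qbar)
  denom <- sum(pc^2)
  if (denom < 1e-12)
    abort_trackcal("Degenerate skeleton: all joints coincident.", "degenerate")
  s <- sum(pc * qc) / denom
  if (s <= 0)
    abort_trackcal("Alignment collapsed to non-positive scale.", "degenerate")
  structure(list(scale = s, translation = unname(qbar - s * pbar)),
            class = "alignment_transform")
}

apply_alignment <- function(skel2d, tr) {
  out <- skel2d
  out$x <- tr$scale * skel2d$x + tr$translation[1]
  out$y <- tr$scale * skel2d$y + tr$translation[2]
  out
}

#' Reprojection error of a placed 3D skeleton
#'
#' Projects the 3D skeleton into the image, aligns it to the reference 2D
#' skeleton (closed-form scale + translation), and reports the mean
#' per-joint Euclidean offset in pixels. The millimetre value scales the
#' pixel error by the athlete's real-world height over the reference
#' skeleton's pixel height; it is an image-scale approximation, not a true
#' 3D distance.
#'
#' @param skel3d A `skeleton3d` (already placed in the scene).
#' @param proj A [build_projection()] result.
#' @param reference The reference `skeleton2d`.
#' @param athlete_height_mm Real-world athlete height, millimetres.
#' @param align If `TRUE` (default) apply [align_2d()] before measuring.
#' @return A named list `px`, `mm`.
#' @export
reprojection_error <- function(skel3d, proj, reference,
                               athlete_height_mm = 1800, align = TRUE) {
  p2 <- project_skeleton(skel3d, proj)
  if (align) p2 <- apply_alignment(p2, align_2d(p2, reference))
  d <- sqrt((p2$x - reference$x)^2 + (p2$y - reference$y)^2)
  ref_h <- skeleton_height(reference)
  if (ref_h <= 1e-9)
    abort_trackcal("Reference skeleton has zero pixel height.", "degenerate")
  px <- mean(d)
  list(px = px, mm = px * athlete_height_mm / ref_h)
}

#' Interior knee angle of a skeleton
#'
#' The angle at the knee between the knee-to-hip and knee-to-ankle
#' vectors, in `[0, 180]` degrees (180 = straight leg). Works for both 2D
#' and 3D skeletons.
#'
#' @param skel A skeleton.
#' @param side `"left"` or `"right"`.
#' @return Angle in degrees.
#' @export
knee_angle_2d <- function(skel, side = c("left", "right")) {
  side <- match.arg(side)
  sfx <- if (side == "left") "_l" else "_r"
  hip <- joint_xyz(skel, paste0("hip", sfx))
  knee <- joint_xyz(skel, paste0("knee", sfx))
  ankle <- joint_xyz(skel, paste0("ankle", sfx))
  u <- hip - knee; v <- ankle - knee
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9)
    abort_trackcal("Coincident leg joints: knee angle undefined.",
                   "undefined_angle")
  rad2deg(acos(clamp(sum(u * v) / (nu * nv), -1, 1)))
}

#' Approximate 3D knee-angle error from a 2D error
#'
#' A 2D knee-angle error only reflects the true 3D error when the camera
#' views the knee roughly side-on (in the athlete's sagittal plane). This
#' estimates the local sensitivity `s` of the observed 2D knee angle to 3D
#' knee movement by rotating the lower leg about the knee's flexion axis by
#' +/- `delta` degrees, projecting, and recording the induced 2D angle
#' change: `s = mean(|d angle2d|) / delta`. The measured 2D error is then
#' rescaled as `knee2d_error / s`; steep (frontal) viewing angles give
#' small `s` and amplify the implied 3D error.
#'
#' @param skel3d The placed `skeleton3d`.
#' @param proj A [build_projection()] result.
#' @param knee2d_error Measured 2D knee-angle error, degrees.
#' @param side `"left"` or `"right"`.
#' @param delta Perturbation magnitude, degrees (central differencing).
#' @param s_floor Sensitivity floor: below it the result is capped at
#'   `knee2d_error / s_floor` with a warning attribute.
#' @return Approximate 3D error in degrees, with attributes `sensitivity`
#'   and `capped`.
#' @export
approx_3d_knee_error <- function(skel3d, proj, knee2d_error,
                                 side = c("left", "right"), delta = 1,
                                 s_floor = 0.05) {
  side <- match.arg(side)
  stopifnot(delta > 0)
  base <- knee_angle_2d(project_skeleton(skel3d, proj), side)
  dplus <- knee_angle_2d(
    project_skeleton(rotate_lower_leg(skel3d, side, delta), proj), side)
  dminus <- knee_angle_2d(
    project_skeleton(rotate_lower_leg(skel3d, side, -delta), proj), side)
  s <- (abs(dplus - base) + abs(dminus - base)) / (2 * delta)
  capped <- s < s_floor
  if (capped) {
    rlang::warn("2D knee angle nearly insensitive to 3D knee movement; capping the approximate 3D error.")
    s <- s_floor
  }
  structure(knee2d_error / s, sensitivity = s, capped = capped)
}

#' Touch-down configuration
#'
#' @param rel_velocity Maximum pelvis-relative ankle displacement per
#'   frame, as a fraction of the skeleton's 2D height.
#' @param window Local-maximum half-window (frames) for the lowest-ankle
#'   test.
#' @return A list of class `touchdown_config`.
#' @export
touchdown_config <- function(rel_velocity = 0.03, window = 2) {
  structure(list(rel_velocity = rel_velocity, window = window),
            class = "touchdown_config")
}

#' Detect touch-down frames from a 2D skeleton sequence
#'
#' A frame is a touch-down candidate when an ankle is at a local maximum
#' of image `y` (its lowest point) and its frame-to-frame displacement
#' relative to the pelvis is below the configured threshold. Runs of
#' consecutive qualifying frames collapse to their midpoints.
#'
#' @param seq2d A list of `skeleton2d` (>= 5 frames).
#' @param config A [touchdown_config()].
#' @return Sorted integer frame indices (possibly empty).
#' @export
detect_touchdown_frames <- function(seq2d, config = touchdown_config()) {
  n <- length(seq2d)
  if (n < 5)
    abort_trackcal("Need at least 5 frames to detect touch-downs.",
                   "too_short")
  get <- function(j, c) vapply(seq2d, function(s) s[[c]][s$joint == j], numeric(1))
  px <- get("pelvis", "x"); py <- get("pelvis", "y")
  heights <- vapply(seq2d, skeleton_height, numeric(1))
  w <- config$window

  hits <- logical(n)
  for (sfx in c("ankle_l", "ankle_r")) {
    ax <- get(sfx, "x"); ay <- get(sfx, "y")
    relx <- ax - px; rely <- ay - py
    disp <- c(Inf, sqrt(diff(relx)^2 + diff(rely)^2))
    for (i in seq_len(n)) {
      lo <- max(1, i - w); hi <- min(n, i + w)
      if (ay[i] >= max(ay[lo:hi]) - 1e-9 &&
          disp[i] <= config$rel_velocity * heights[i])
        hits[i] <- TRUE
    }
  }
  if (!any(hits)) return(integer(0))
  # collapse consecutive runs to midpoints
  idx <- which(hits)
  runs <- split(idx, cumsum(c(1, diff(idx) > 1)))
  sort(unique(vapply(runs, function(r) as.integer(round(mean(r))), integer(1))))
}

#' Straighten a skeleton sequence's ground path
#'
#' Fits a total-least-squares line to the ground anchors and rigidly
#' translates each skeleton so its anchor lands on its orthogonal
#' projection onto that line (the home-stretch path is straight; curved
#' trajectories are a pose-lifting artefact).
#'
#' @param skeletons A list of `skeleton3d`.
#' @param anchors A tibble with columns `x`, `y` (one row per skeleton).
#' @return A list with elements `skeletons` and `anchors` (both
#'   straightened).
#' @export
straighten_path <- function(skeletons, anchors) {
  stopifnot(length(skeletons) == nrow(anchors), length(skeletons) >= 2)
  a <- as.matrix(anchors[, c("x", "y")])
  ctr <- colMeans(a)
  ac <- sweep(a, 2, ctr)
  if (sum(ac^2) < 1e-18) {
    rlang::warn("All anchors coincident; path left unchanged.")
    return(list(skeletons = skeletons, anchors = anchors))
  }
  u <- svd(ac, nu = 0, nv = 1)$v[, 1]
  tproj <- ac %*% u
  newa <- sweep(tproj %*% t(u), 2, ctr, `+`)
  out <- lapply(seq_along(skeletons), function(i) {
    s <- skeletons[[i]]
    s$x <- s$x + (newa[i, 1] - a[i, 1])
    s$y <- s$y + (newa[i, 2] - a[i, 2])
    s
  })
  na <- anchors
  na$x <- newa[, 1]; na$y <- newa[, 2]
  list(skeletons = out, anchors = na)
}

# Horizontal facing direction: perpendicular of the left-to-right hip line,
# signed toward the chest-forward side.
facing_of <- function(skel3d) {
  d <- joint_xyz(skel3d, "hip_r") - joint_xyz(skel3d, "hip_l")
  f <- c(-d[2], d[1])
  nf <- sqrt(sum(f^2))
  if (nf < 1e-9)
    abort_trackcal("Degenerate hips: facing undefined.", "degenerate")
  f / nf
}

#' Rotate a skeleton to face a given direction
#'
#' Rotates the skeleton about the vertical axis through its ground-contact
#' anchor so its facing direction (the horizontal perpendicular of the
#' hip line) equals `facing` — e.g. `c(1, 0)` to face the finish line.
#'
#' @param skel3d A `skeleton3d`.
#' @param facing Length-2 unit(ish) direction in the ground plane.
#' @return The rotated `skeleton3d`.
#' @export
rotate_to_facing <- function(skel3d, facing = c(1, 0)) {
  f0 <- facing_of(skel3d)
  f1 <- as.numeric(facing)
  f1 <- f1 / sqrt(sum(f1^2))
  ang <- rad2deg(atan2(f1[2], f1[1]) - atan2(f0[2], f0[1]))
  anchor <- joint_xyz(skel3d, contact_joint(skel3d))[1:2]
  rotate_skeleton_z(skel3d, ang, anchor)
}
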