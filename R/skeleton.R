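#' The 17-joint skeleton convention
#'
#' Joints follow the common 17-joint benchmark set, in this fixed order:
#' head, neck, chest, navel, pelvis, then left/right pairs of shoulder,
#' elbow, wrist, hip, knee, ankle. The order is also the JSON serialisation
#' order.
#'
#' @return Character vector of the 17 joint names.
#' @export
joint_names <- function() {
  c("head", "neck", "chest", "navel", "pelvis",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r", "wrist_l", "wrist_r",
    "hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r")
}

new_skeleton <- function(df, space) {
  cls <- if (space == "metric") "skeleton3d" else "skeleton2d"
  structure(df, class = c(cls, class(tibble::tibble())), space = space)
}

validate_joints <- function(df, cols) {
  if (!identical(sort(df$joint), sort(joint_names())))
    abort_trackcal("Skeleton must contain exactly the 17 standard joints.",
                   "invalid_skeleton")
  if (!all(vapply(df[cols], function(v) all(is.finite(v)), logical(1))))
    abort_trackcal("Skeleton coordinates must be finite.", "invalid_skeleton")
  df[match(joint_names(), df$joint), , drop = FALSE]
}

#' Construct a 3D (metric) or 2D (pixel) skeleton
#'
#' A skeleton is a tibble with a `joint` column and coordinate columns
#' (`x`, `y`, `z` in metres for 3D; `x`, `y` in pixels for 2D), one row per
#' joint in the fixed [joint_names()] order.
#'
#' @param joints A data frame with columns `joint`, `x`, `y` (and `z` for
#'   3D), or a numeric matrix with 17 rows in [joint_names()] order.
#' @return A `skeleton3d` / `skeleton2d` tibble.
#' @export
skeleton_3d <- function(joints) {
  if (is.matrix(joints)) {
    stopifnot(nrow(joints) == 17L, ncol(joints) == 3L)
    joints <- tibble::tibble(joint = joint_names(), x = joints[, 1],
                             y = joints[, 2], z = joints[, 3])
  }
  df <- tibble::as_tibble(joints)[, c("joint", "x", "y", "z")]
  new_skeleton(validate_joints(df, c("x", "y", "z")), "metric")
}

#' @rdname skeleton_3d
#' @export
skeleton_2d <- function(joints) {
  if (is.matrix(joints)) {
    stopifnot(nrow(joints) == 17L, ncol(joints) == 2L)
    joints <- tibble::tibble(joint = joint_names(), x = joints[, 1], y = joints[, 2])
  }
  df <- tibble::as_tibble(joints)[, c("joint", "x", "y")]
  new_skeleton(validate_joints(df, c("x", "y")), "pixel")
}

skeleton_matrix <- function(skel) {
  cols <- if (inherits(skel, "skeleton3d")) c("x", "y", "z") else c("x", "y")
  m <- as.matrix(as.data.frame(skel)[, cols])
  rownames(m) <- skel$joint
  m
}

joint_xyz <- function(skel, joint) {
  as.numeric(skeleton_matrix(skel)[joint, ])
}

#' Vertical extent ("height") of a skeleton
#'
#' For 3D skeletons the extent along `z` (metres); for 2D skeletons the
#' extent along image `y` (pixels).
#'
#' @param skel A skeleton.
#' @return A nonnegative number.
#' @export
skeleton_height <- function(skel) {
  if (inherits(skel, "skeleton3d")) diff(range(skel$z)) else diff(range(skel$y))
}

# Ground-contact joint: the lowest ankle (ties go to the left).
contact_joint <- function(skel3d) {
  if (skel3d$z[skel3d$joint == "ankle_l"] <= skel3d$z[skel3d$joint == "ankle_r"])
    "ankle_l" else "ankle_r"
}

#' Project a 3D skeleton into the image
#'
#' @param skel3d A `skeleton3d`.
#' @param proj A [build_projection()] result.
#' @return A `skeleton2d`. Errors if any joint lies on or behind the
#'   camera's principal plane.
#' @export
project_skeleton <- function(skel3d, proj) {
  stopifnot(inherits(skel3d, "skeleton3d"))
  p <- project_points(skeleton_matrix(skel3d), proj)
  if (any(p$behind))
    abort_trackcal("Skeleton joint behind the camera.", "projection_at_infinity")
  skeleton_2d(tibble::tibble(joint = skel3d$joint, x = p$x, y = p$y))
}

#' Place a skeleton at a ground anchor
#'
#' Rigidly translates the skeleton so that its ground-contact joint (the
#' lowest ankle) sits at `(anchor[1], anchor[2], 0)`.
#'
#' @param skel A `skeleton3d`.
#' @param anchor Length-2 ground point `(x, y)` in metres.
#' @return The translated `skeleton3d`.
#' @export
place_skeleton <- function(skel, anchor) {
  stopifnot(inherits(skel, "skeleton3d"), length(anchor) == 2L)
  cj <- contact_joint(skel)
  ref <- joint_xyz(skel, cj)
  shift <- c(anchor[1], anchor[2], 0) - ref
  out <- skel
  out$x <- skel$x + shift[1]; out$y <- skel$y + shift[2]; out$z <- skel$z + shift[3]
  out
}

#' Scale a skeleton to a target projected height
#'
#' Scales the skeleton about its ground-contact joint until its projected
#' vertical extent (max minus min image `y`) matches `target_height_px`,
#' solved by a bounded 1D search to within 0.5 px.
#'
#' @param skel A `skeleton3d`.
#' @param target_height_px Target projected extent, pixels (> 0).
#' @param proj A [build_projection()] result.
#' @return The scaled `skeleton3d`, with the scale factor in attribute
#'   `scale`.
#' @export
scale_skeleton <- function(skel, target_height_px, proj) {
  stopifnot(inherits(skel, "skeleton3d"))
  if (!is_number(target_height_px) || target_height_px <= 0)
    abort_trackcal("`target_height_px` must be positive.", "invalid_parameter")
  cj <- contact_joint(skel)
  ref <- joint_xyz(skel, cj)
  m0 <- sweep(skeleton_matrix(skel), 2, ref)

  extent_at <- function(s) {
    m <- sweep(m0 * s, 2, ref, `+`)
    p <- project_points(m, proj)
    diff(range(p$y))
  }
  f <- function(s) extent_at(s) - target_height_px

  lo <- 1e-3; hi <- 1e3
  flo <- f(lo); fhi <- f(hi)
  it <- 0
  while (flo * fhi > 0 && it < 8) { # widen the bracket if needed
    lo <- lo / 10; hi <- hi * 10
    flo <- f(lo); fhi <- f(hi); it <- it + 1
  }
  if (flo * fhi > 0)
    abort_trackcal("Projected-height search failed to bracket the target.",
                   "no_convergence")
  fm <- Inf
  for (i in seq_len(200)) {
    mid <- sqrt(lo * hi) # log-scale bisection
    fm <- f(mid)
    if (abs(fm) < 0.25) break
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  if (abs(fm) >= 0.5)
    abort_trackcal("Projected-height search did not converge.", "no_convergence")
  m <- sweep(m0 * mid, 2, ref, `+`)
  out <- skel
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  attr(out, "scale") <- mid
  out
}
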