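# Geometry search: enumerate the one-parameter family of cameras consistent
# with the lane vanishing point.
#
# For a roll-free camera at azimuth a, elevation e with focal length f
# (pixels), the lane vanishing point sits at
#   v0 = centre + f * (tan a / cos e, -tan e),
# independent of camera position. The *direction* from the principal point
# to v0 is independent of f, so each azimuth determines the elevation from
# the direction alone; f (hence fov) then follows from the distance |v0 -
# centre|; and the camera position follows from ray-tracing the detected
# lanes onto the ground and matching the standardised lane spacing.

#' Search configuration
#'
#' @param az_min,az_max,az_step Azimuth sweep range and sampling (degrees).
#' @param el_tol Bisection tolerance for the elevation solve (degrees).
#' @param fov_range Admissible field-of-view interval (degrees).
#' @param vp_tol Sanity tolerance (px): each candidate's analytic lane
#'   vanishing point must land on the input `v0` within this.
#' @return A list of class `search_config`.
#' @export
search_config <- function(az_min = 1, az_max = 89, az_step = 0.5,
                          el_tol = 1e-6, fov_range = c(0.1, 179),
                          vp_tol = 0.5) {
  structure(as.list(environment()), class = "search_config")
}

# fov-independent direction (in focal units) from the principal point to
# the lane vanishing point; azimuth and elevation in degrees.
vp_offset_dir <- function(azimuth, elevation) {
  c(tan(deg2rad(azimuth)) / cos(deg2rad(elevation)), -tan(deg2rad(elevation)))
}

#' Solve the elevation matching a vanishing-point direction
#'
#' Given an azimuth, finds the elevation whose simulated lane vanishing
#' point lies in the given direction from the principal point (the
#' direction is independent of the field of view). Solved by bisection on
#' the signed angular mismatch; the mismatch is monotone in elevation,
#' which is checked at runtime.
#'
#' @param azimuth Candidate azimuth, degrees (sign = pan direction).
#' @param v0_direction Length-2 unit(ish) vector from the principal point
#'   toward the observed vanishing point, image coordinates (y down).
#' @param tol Bisection tolerance, degrees.
#' @return Elevation in degrees, or `NA` if no elevation in (0, 89)
#'   achieves the direction (that azimuth yields no candidate). A direction
#'   exactly along the horizontal returns the elevation-zero limit.
#' @export
solve_elevation <- function(azimuth, v0_direction, tol = 1e-6) {
  d <- as.numeric(v0_direction)
  nd <- sqrt(sum(d^2))
  if (nd == 0) abort_trackcal("Zero direction.", "invalid_parameter")
  d <- d / nd
  a <- azimuth
  if (a < 0) { a <- -a; d[1] <- -d[1] } # mirror: negative pan
  if (a <= 0 || a >= 90)
    abort_trackcal("Azimuth must lie in (0, 90) in magnitude.", "invalid_parameter")
  if (d[1] <= 0) return(NA_real_) # v0 on the wrong side (incl. flipped 180)
  if (abs(d[2]) < 1e-12) return(0) # horizon through the centre: elevation -> 0
  if (d[2] > 0) return(NA_real_) # v0 below the centre: no downward tilt fits

  theta_t <- atan2(d[2], d[1])
  mis <- function(el) {
    g <- vp_offset_dir(a, el)
    atan2(g[2], g[1]) - theta_t
  }
  lo <- 0; hi <- 89
  mlo <- mis(lo); mhi <- mis(hi)
  if (!(mlo >= 0 && mhi <= mlo)) # monotone decreasing from 0
    abort_trackcal("Elevation mismatch is not monotone.", "internal")
  if (mhi > 0) return(NA_real_) # target steeper than 89 deg allows
  while (hi - lo > tol * 0.1) {
    mid <- (lo + hi) / 2
    if (mis(mid) >= 0) lo <- mid else hi <- mid
  }
  el <- (lo + hi) / 2
  if (el <= 0 || el >= 89) return(if (el <= 0) 0 else NA_real_)
  el
}

#' Fit the field of view placing the vanishing point on v0
#'
#' With azimuth and elevation fixed, the vanishing point moves along the
#' ray from the principal point as the field of view changes. The focal
#' length follows in closed form as
#' `f = |v0 - centre| / |(tan az / cos el, -tan el)|`.
#'
#' @param azimuth,elevation Candidate angles, degrees.
#' @param v0 Observed vanishing point, pixels.
#' @param image_size Length-2 `(width, height)`.
#' @param fov_range Admissible interval (degrees); outside it the candidate
#'   is rejected.
#' @return Field of view in degrees, or `NA` if rejected (degenerate `v0`
#'   at the image centre, or fov outside `fov_range`).
#' @export
fit_fov <- function(azimuth, elevation, v0, image_size = c(1280, 720),
                    fov_range = c(0.1, 179)) {
  centre <- image_size / 2
  dv <- as.numeric(v0) - centre
  r <- sqrt(sum(dv^2))
  if (r < 1e-6) return(NA_real_)
  g <- vp_offset_dir(abs(azimuth), elevation)
  f <- r / sqrt(sum(g^2))
  fov <- 2 * rad2deg(atan((image_size[1] / 2) / f))
  if (fov <= fov_range[1] || fov >= fov_range[2]) return(NA_real_)
  fov
}

#' Solve the camera position from detected lanes
#'
#' With `K` and `R` fixed (azimuth, elevation, fov known), ray-traces the
#' detected lane lines onto the ground plane from a reference camera at
#' unit height. Ground-plane lane offsets are affine in the camera's
#' lateral position and height, so matching the standardised lane spacing
#' and aligning the first lane to the lane grid is a two-parameter linear
#' least-squares solve. The position along the lanes (`x`) is
#' unidentifiable from parallel lines and fixed to 0 (the world origin sits
#' at the camera's station along the track); the first detected lane
#' defines lane index 0.
#'
#' @param azimuth,elevation,fov Camera angles/fov, degrees.
#' @param lanes A `lane_set` with at least 2 lanes (extent endpoints are
#'   ray-traced).
#' @param scene A [track_scene()] providing the lane width.
#' @param image_size Length-2 `(width, height)`.
#' @param roll Camera roll, degrees.
#' @return Length-3 camera position `(0, y, z)` in metres.
#' @export
solve_translation <- function(azimuth, elevation, fov, lanes,
                              scene = track_scene(),
                              image_size = c(1280, 720), roll = 0) {
  stopifnot(inherits(lanes, "lane_set"), nrow(lanes) >= 2)
  cam1 <- camera_params(azimuth, elevation, roll, fov,
                        position = c(0, 0, 1), image_size = image_size)
  proj1 <- build_projection(cam1)

  # keep lane evidence clear of the horizon: ray-traced offsets blow up there
  hy <- horizon_y(proj1) + 10
  u_ends <- matrix(NA_real_, nrow(lanes), 2)
  for (i in seq_len(nrow(lanes))) {
    p1 <- c(lanes$x1[i], lanes$y1[i]); p2 <- c(lanes$x2[i], lanes$y2[i])
    if (p1[2] < hy || p2[2] < hy) {
      if (max(p1[2], p2[2]) <= hy)
        abort_trackcal("Lane lies above the horizon for this candidate.",
                       "no_intersection")
      tcut <- (hy - p1[2]) / (p2[2] - p1[2])
      if (p1[2] < hy) p1 <- p1 + tcut * (p2 - p1) else p2 <- p1 + tcut * (p2 - p1)
    }
    g1 <- ray_trace_to_ground(p1, proj1)
    g2 <- ray_trace_to_ground(p2, proj1)
    u_ends[i, ] <- c(g1[2], g2[2])
  }
  u_mean <- rowMeans(u_ends)
  o <- order(u_mean)
  u_ends <- u_ends[o, , drop = FALSE]
  u_mean <- u_mean[o]

  # collapse near-duplicate lanes, then infer integer lane indices from gaps
  gaps <- diff(u_mean)
  if (length(gaps)) {
    med <- stats::median(gaps[gaps > 0])
    keep <- c(TRUE, gaps > 0.25 * med)
    u_ends <- u_ends[keep, , drop = FALSE]
    u_mean <- u_mean[keep]
    gaps <- diff(u_mean)
  }
  if (length(u_mean) < 2)
    abort_trackcal("Fewer than 2 distinct lanes after ray-tracing.",
                   "insufficient_lanes")
  s <- stats::median(gaps)
  for (it in 1:2) {
    r <- pmax(1, round(gaps / s))
    s <- sum(gaps) / sum(r)
  }
  k <- cumsum(c(0, pmax(1, round(gaps / s))))

  # weighted least squares: C_y + C_z * u = k * lane_width for both lane
  # endpoints, down-weighting far (near-horizon) evidence
  u <- as.numeric(t(u_ends))
  A <- cbind(1, u)
  b <- rep(k, each = 2) * scene$lane_width
  w <- 1 / (1 + u^2)
  th <- solve(crossprod(A, w * A), crossprod(A, w * b))
  if (th[2] <= 0)
    abort_trackcal("Inconsistent lane ordering (negative camera height).",
                   "invalid_geometry")
  c(0, th[1], th[2])
}

#' Enumerate all candidate cameras consistent with a vanishing point
#'
#' Sweeps the azimuth over `[az_min, az_max]` in steps of `az_step`
#' (mirrored to negative pan when `v0` lies left of the principal point)
#' and, for each azimuth, solves the elevation from the vanishing-point
#' direction, the field of view from its distance, and the camera position
#' from the detected lanes; roll is fixed at 0 (horizontal horizon).
#' Azimuths failing any stage are omitted and logged. Each candidate
#' records its second vanishing point (the image of the in-plane direction
#' orthogonal to the lanes).
#'
#' @param v0 A `vanishing_point` or length-2 pixel coordinate.
#' @param lanes A `lane_set`.
#' @param scene A [track_scene()].
#' @param config A [search_config()].
#' @param image_size Length-2 `(width, height)`; defaults to the lane
#'   set's.
#' @return A tibble of class `candidate_set`, ordered by azimuth:
#'   `azimuth`, `elevation`, `roll`, `fov` (degrees), position `x, y, z`
#'   (metres), second vanishing point `v1_x, v1_y` (px). Attributes: `v0`,
#'   `image_size`, `scene`, `sweep_step`, and `failures` (tibble of
#'   per-azimuth failure stages).
#' @export
enumerate_candidates <- function(v0, lanes, scene = track_scene(),
                                 config = search_config(),
                                 image_size = attr(lanes, "image_size")) {
  if (inherits(v0, "vanishing_point")) {
    if (v0$at_infinity)
      abort_trackcal("Vanishing point at infinity: no finite candidates.",
                     "vp_at_infinity")
    v0 <- v0$v0
  }
  v0 <- as.numeric(v0)
  centre <- image_size / 2
  dv <- v0 - centre
  if (sqrt(sum(dv^2)) < 1e-6)
    abort_trackcal("v0 at the principal point is degenerate.", "invalid_parameter")
  sgn <- if (dv[1] >= 0) 1 else -1
  dirn <- dv / sqrt(sum(dv^2))

  # drop lanes inconsistent with v0 (spurious clusters): the true lanes are
  # concurrent in v0 by construction
  th <- deg2rad(lanes$angle)
  resid <- abs((v0[1] - lanes$px) * (-sin(th)) + (v0[2] - lanes$py) * cos(th))
  ok <- resid <= pmax(3, 1e-3 * sqrt(sum(dv^2)))
  if (sum(ok) >= 2) lanes <- lanes[ok, ]

  az_grid <- seq(config$az_min, config$az_max, by = config$az_step)
  rows <- list(); fails <- list()
  for (az_mag in az_grid) {
    az <- sgn * az_mag
    el <- solve_elevation(az, dirn, tol = config$el_tol)
    if (is.na(el)) { fails[[length(fails) + 1]] <- c(az, "elevation"); next }
    fov <- fit_fov(az, el, v0, image_size, config$fov_range)
    if (is.na(fov)) { fails[[length(fails) + 1]] <- c(az, "fov"); next }
    pos <- tryCatch(
      solve_translation(az, el, fov, lanes, scene, image_size),
      trackcal_error = function(e) NULL)
    if (is.null(pos)) { fails[[length(fails) + 1]] <- c(az, "translation"); next }
    cam <- camera_params(az, el, 0, fov, pos, image_size)
    proj <- build_projection(cam)
    vp <- lane_vanishing_point(proj)
    if (isTRUE(attr(vp, "at_infinity")) ||
        sqrt(sum((vp - v0)^2)) > config$vp_tol) {
      fails[[length(fails) + 1]] <- c(az, "vp_check"); next
    }
    v1 <- vanishing_point_of_direction(c(0, 1, 0), proj)
    rows[[length(rows) + 1]] <- tibble::tibble(
      azimuth = az, elevation = el, roll = 0, fov = fov,
      x = pos[1], y = pos[2], z = pos[3],
      v1_x = v1[1], v1_y = v1[2])
  }
  fail_tbl <- if (length(fails)) {
    tibble::tibble(azimuth = as.numeric(vapply(fails, `[`, "", 1)),
                   stage = vapply(fails, `[`, "", 2))
  } else tibble::tibble(azimuth = double(), stage = character())
  if (!length(rows))
    abort_trackcal("No candidate geometry found for this vanishing point.",
                   "empty_candidate_set", failures = fail_tbl)
  out <- dplyr::arrange(dplyr::bind_rows(rows), abs(.data$azimuth))
  structure(out, v0 = v0, image_size = as.numeric(image_size), scene = scene,
            sweep_step = config$az_step, failures = fail_tbl,
            class = c("candidate_set", class(tibble::tibble())))
}

#' Extract one candidate as camera parameters
#'
#' @param cands A `candidate_set`.
#' @param i Row index.
#' @return A [camera_params()].
#' @export
candidate_camera <- function(cands, i) {
  stopifnot(inherits(cands, "candidate_set"))
  r <- cands[i, ]
  camera_params(r$azimuth, r$elevation, r$roll, r$fov,
                c(r$x, r$y, r$z), attr(cands, "image_size"))
}

#' Selection constraints for picking one candidate
#'
#' Exactly one auxiliary piece of knowledge disambiguates the candidate
#' family: the second vanishing point, the camera height, or the camera's
#' lateral offset from the first lane.
#'
#' @param v1 Known second vanishing point (length-2 px, or its x
#'   coordinate: all candidates share the horizon so only x discriminates).
#' @return A list of class `selection_constraint`.
#' @export
constraint_v1 <- function(v1) {
  structure(list(type = "v1", value = as.numeric(v1)[1]),
            class = "selection_constraint")
}

#' @param height Known camera height, metres.
#' @rdname constraint_v1
#' @export
constraint_height <- function(height) {
  structure(list(type = "height", value = height), class = "selection_constraint")
}

#' @param lateral Known lateral camera offset (world `y`), metres.
#' @rdname constraint_v1
#' @export
constraint_lateral <- function(lateral) {
  structure(list(type = "lateral", value = lateral), class = "selection_constraint")
}

constraint_residuals <- function(cands, constraint) {
  switch(constraint$type,
         v1 = cands$v1_x - constraint$value,
         height = cands$z - constraint$value,
         lateral = cands$y - constraint$value,
         abort_trackcal("Unknown constraint type.", "invalid_parameter"))
}

#' Select the candidate minimising a constraint residual
#'
#' Computes the signed residual of the constraint along the sweep, locates
#' the sign change (or the global minimum of its magnitude if none), and
#' linearly interpolates all camera parameters between the two bracketing
#' azimuth samples. Two equally good candidates resolve to the lower
#' azimuth; a residual that is not unimodal across the sweep triggers a
#' warning and returns the global minimum.
#'
#' @param cands A `candidate_set`.
#' @param constraint A `selection_constraint`.
#' @return A [camera_params()] with attributes `residual` and
#'   `interpolated`.
#' @export
select_candidate <- function(cands, constraint) {
  stopifnot(inherits(cands, "candidate_set"),
            inherits(constraint, "selection_constraint"))
  n <- nrow(cands)
  if (n == 0) abort_trackcal("Empty candidate set.", "empty_candidate_set")
  r <- constraint_residuals(cands, constraint)
  ar <- abs(r)

  # unimodality check on |r|
  if (n >= 3) {
    mins <- which(diff(sign(diff(ar))) > 0) + 1L
    n_min <- length(mins) + (ar[1] < ar[2]) + (ar[n] < ar[n - 1])
    if (n_min > 1)
      rlang::warn("Constraint residual is not unimodal across the sweep; returning the global minimum.")
  }

  br <- which(r[-n] * r[-1] <= 0)
  if (length(br)) {
    # choose the bracket with the smallest endpoint residual (tie: lower az)
    score <- pmin(ar[br], ar[br + 1])
    i <- br[which.min(score)]
    w <- if (r[i] == r[i + 1]) 0 else r[i] / (r[i] - r[i + 1])
    lerp <- function(col) (1 - w) * cands[[col]][i] + w * cands[[col]][i + 1]
    cam <- camera_params(lerp("azimuth"), lerp("elevation"), 0, lerp("fov"),
                         c(lerp("x"), lerp("y"), lerp("z")),
                         attr(cands, "image_size"))
    attr(cam, "residual") <- 0
    attr(cam, "interpolated") <- TRUE
    return(cam)
  }
  i <- which.min(ar) # first index on ties = lower azimuth (sorted by |az|)
  cam <- candidate_camera(cands, i)
  attr(cam, "residual") <- r[i]
  attr(cam, "interpolated") <- FALSE
  cam
}
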