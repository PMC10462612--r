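# Lane clustering and vanishing-point voting.

#' Construct a lane set programmatically
#'
#' A lane set is a tibble of image lines (point + angle) with per-lane
#' support, as produced by [cluster_lanes()]; this constructor lets lanes
#' be supplied directly (e.g. analytic lines in tests or external input).
#'
#' @param px,py A point on each lane line, pixels.
#' @param angle Line angle, degrees in `[0, 180)`.
#' @param support Per-lane support (total segment length, px).
#' @param x1,y1,x2,y2 Optional lane extent endpoints; default to a short
#'   span about `(px, py)`.
#' @param image_size Length-2 `(width, height)`.
#' @return A tibble of class `lane_set`.
#' @export
lane_set <- function(px, py, angle, support = rep(1, length(px)),
                     x1 = NULL, y1 = NULL, x2 = NULL, y2 = NULL,
                     image_size = c(1280, 720)) {
  th <- deg2rad(angle)
  if (is.null(x1)) { x1 <- px - 100 * cos(th); y1 <- py - 100 * sin(th) }
  if (is.null(x2)) { x2 <- px + 100 * cos(th); y2 <- py + 100 * sin(th) }
  structure(tibble::tibble(lane = seq_along(px), px = px, py = py,
                           angle = angle, support = support,
                           x1 = x1, y1 = y1, x2 = x2, y2 = y2),
            image_size = as.numeric(image_size),
            class = c("lane_set", class(tibble::tibble())))
}

# Signed perpendicular distance from points to the line through (px, py)
# with direction angle `angle` (degrees).
line_point_dist <- function(px, py, angle, x, y) {
  th <- deg2rad(angle)
  (x - px) * (-sin(th)) + (y - py) * cos(th)
}

#' Cluster line segments into running lanes
#'
#' Filters segments to the dominant direction family (length-weighted
#' angular histogram, 2 degree bins, keep within `cluster_angle_window` of
#' the modal direction), then greedily merges collinear segments into one
#' lane each: the longest member defines the lane's line, the remaining
#' members extend its extent and support. Lanes are sorted by signed
#' perpendicular offset from the image centre.
#'
#' @param segments A [detect_segments()] result.
#' @param config A [detect_config()].
#' @return A `lane_set` tibble: `lane`, line point `px, py`, `angle`
#'   (degrees), `support` (total segment length), extent endpoints
#'   `x1, y1, x2, y2`.
#' @export
cluster_lanes <- function(segments, config = detect_config()) {
  if (nrow(segments) == 0)
    abort_trackcal("No segments to cluster.", "insufficient_lanes")
  size <- attr(segments, "image_size") %||% c(1280, 720)

  # dominant direction: length-weighted circular histogram (period 180)
  bins <- seq(0, 178, by = 2)
  wts <- vapply(bins, function(b) {
    sum(segments$length[angle_gap180(segments$angle, b + 1) <= 1])
  }, numeric(1))
  modal <- bins[which.max(wts)] + 1
  fam <- segments[angle_gap180(segments$angle, modal) <= config$cluster_angle_window, ]
  if (nrow(fam) == 0)
    abort_trackcal("No segments in the dominant direction family.",
                   "insufficient_lanes")
  fam <- fam[order(-fam$length), ]

  lanes <- list()
  for (i in seq_len(nrow(fam))) {
    sg <- fam[i, ]
    mx <- (sg$x1 + sg$x2) / 2; my <- (sg$y1 + sg$y2) / 2
    assigned <- FALSE
    for (k in seq_along(lanes)) {
      ln <- lanes[[k]]
      if (angle_gap180(ln$angle, sg$angle) <= config$merge_angle_tol &&
          abs(line_point_dist(ln$px, ln$py, ln$angle, mx, my)) <= config$merge_dist_tol) {
        # segments arrive sorted by length, so the first (dominant) member
        # defines the lane line; later members only extend the lane extent
        lanes[[k]]$segs <- dplyr::bind_rows(ln$segs, sg)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      lanes[[length(lanes) + 1]] <- list(
        px = mx, py = my, angle = sg$angle, segs = sg)
    }
  }
  if (length(lanes) < 2)
    abort_trackcal("Fewer than 2 lanes detected.", "insufficient_lanes")

  rows <- lapply(lanes, function(ln) {
    ss <- ln$segs
    th <- deg2rad(ln$angle)
    u <- c(cos(th), sin(th))
    tp <- (c(ss$x1, ss$x2) - ln$px) * u[1] + (c(ss$y1, ss$y2) - ln$py) * u[2]
    t0 <- min(tp); t1 <- max(tp)
    tibble::tibble(px = ln$px, py = ln$py, angle = ln$angle,
                   support = sum(ss$length),
                   x1 = ln$px + t0 * u[1], y1 = ln$py + t0 * u[2],
                   x2 = ln$px + t1 * u[1], y2 = ln$py + t1 * u[2])
  })
  out <- dplyr::bind_rows(rows)
  # sort by signed offset of the line from the image centre
  off <- line_point_dist(out$px, out$py, out$angle, size[1] / 2, size[2] / 2)
  out <- out[order(-off), ]
  out$lane <- seq_len(nrow(out))
  out <- out[, c("lane", "px", "py", "angle", "support",
                 "x1", "y1", "x2", "y2")]
  structure(out, image_size = size,
            class = c("lane_set", class(tibble::tibble())))
}

# Intersection of two lines given as (point, angle deg); NULL if the angle
# gap is below `min_gap` degrees.
line_intersection <- function(p1, a1, p2, a2, min_gap = 0) {
  if (angle_gap180(a1, a2) < min_gap) return(NULL)
  t1 <- deg2rad(a1); t2 <- deg2rad(a2)
  A <- rbind(c(cos(t1), -cos(t2)), c(sin(t1), -sin(t2)))
  if (abs(det(A)) < 1e-12) return(NULL)
  s <- solve(A, p2 - p1)
  p1 + s[1] * c(cos(t1), sin(t1))
}

geometric_median <- function(pts, iters = 100, tol = 1e-9) {
  m <- colMeans(pts)
  for (i in seq_len(iters)) {
    d <- sqrt(rowSums(sweep(pts, 2, m)^2))
    d <- pmax(d, 1e-12)
    m2 <- colSums(pts / d) / sum(1 / d)
    if (sqrt(sum((m2 - m)^2)) < tol) return(m2)
    m <- m2
  }
  m
}

#' Estimate the main vanishing point from a lane set
#'
#' Collects the pairwise intersections of the lane lines (pairs with an
#' angle gap below `min_angle_gap` contribute no vote), grid-hashes them at
#' `vote_cell` pixels, takes the modal cell, and takes the geometric median
#' of all intersections within `vote_radius` of the modal cell centre. The
#' result is then refined to the support-weighted least-squares concurrency
#' point of the lanes consistent with the vote, which suppresses the
#' along-line scatter that pairwise intersections of near-parallel lanes
#' suffer from; outlier lanes rejected by the vote contribute nothing.
#'
#' @param lanes A `lane_set` with at least 2 lanes.
#' @param config A [detect_config()].
#' @return An object of class `vanishing_point`: `v0` (pixels), `n_votes`
#'   (inlier intersections), `inlier_spread` (mean inlier distance to
#'   `v0`, px) and `at_infinity`. If every pair is near-parallel the result
#'   is at infinity (`v0 = c(NA, NA)`).
#' @export
estimate_vanishing_point <- function(lanes, config = detect_config()) {
  stopifnot(inherits(lanes, "lane_set"))
  n <- nrow(lanes)
  if (n < 2)
    abort_trackcal("Need at least 2 lanes.", "insufficient_lanes")
  collect <- function(min_gap) {
    pts <- list(); wts <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      p <- line_intersection(c(lanes$px[i], lanes$py[i]), lanes$angle[i],
                             c(lanes$px[j], lanes$py[j]), lanes$angle[j],
                             min_gap = min_gap)
      if (!is.null(p)) {
        pts[[length(pts) + 1]] <- p
        wts <- c(wts, min(lanes$support[i], lanes$support[j]))
      }
    }
    list(pts = pts, wts = wts)
  }
  got <- collect(config$min_angle_gap)
  if (!length(got$pts)) {
    # long-lens frames: every pair is under the exclusion threshold, yet
    # the family can still converge consistently; fall back to any
    # measurable gap and let the least-squares refinement do the work.
    # A family parallel within angular noise stays at infinity.
    got <- collect(config$min_angle_gap / 10)
  }
  pts <- got$pts; wts <- got$wts
  if (!length(pts)) {
    return(structure(list(v0 = c(NA_real_, NA_real_), n_votes = 0L,
                          inlier_spread = NA_real_, at_infinity = TRUE),
                     class = "vanishing_point"))
  }
  P <- do.call(rbind, pts)
  if (nrow(P) == 1) {
    return(structure(list(v0 = as.numeric(P[1, ]), n_votes = 1L,
                          inlier_spread = 0, at_infinity = FALSE),
                     class = "vanishing_point"))
  }
  cell <- config$vote_cell
  keyx <- floor(P[, 1] / cell); keyy <- floor(P[, 2] / cell)
  key <- paste(keyx, keyy)
  tab <- sort(tapply(wts, key, sum), decreasing = TRUE) # support-weighted vote
  modal <- names(tab)[1]
  kk <- as.numeric(strsplit(modal, " ")[[1]])
  centre <- (kk + 0.5) * cell
  d <- sqrt((P[, 1] - centre[1])^2 + (P[, 2] - centre[2])^2)
  inl_sel <- d <= config$vote_radius
  if (!any(inl_sel)) inl_sel <- seq_len(nrow(P)) == which.min(d)
  inl <- P[inl_sel, , drop = FALSE]
  v0 <- if (nrow(inl) == 1) as.numeric(inl[1, ]) else geometric_median(inl)
  spread <- mean(sqrt(rowSums(sweep(inl, 2, v0)^2)))

  # refine: support-weighted least-squares concurrency point over the lanes
  # consistent with the vote (intersections along near-parallel lanes
  # scatter hugely along the lines; the lateral line evidence does not),
  # iterated with a shrinking consistency gate
  th <- deg2rad(lanes$angle)
  nx <- -sin(th); ny <- cos(th)
  cc <- nx * lanes$px + ny * lanes$py
  w0 <- lanes$support
  for (gate_frac in c(0.02, 0.008, 0.003)) {
    resid <- abs(nx * v0[1] + ny * v0[2] - cc)
    gate <- pmax(config$vote_radius * gate_frac / 0.02, gate_frac * sqrt(
      (v0[1] - mean(lanes$px))^2 + (v0[2] - mean(lanes$py))^2))
    ok <- resid <= gate
    if (sum(ok) < 2) break
    w <- w0[ok]
    A <- rbind(c(sum(w * nx[ok]^2), sum(w * nx[ok] * ny[ok])),
               c(sum(w * nx[ok] * ny[ok]), sum(w * ny[ok]^2)))
    if (abs(det(A)) <= 1e-12) break
    v0 <- as.numeric(solve(A, c(sum(w * cc[ok] * nx[ok]),
                                sum(w * cc[ok] * ny[ok]))))
  }
  structure(list(v0 = v0, n_votes = nrow(inl), inlier_spread = spread,
                 at_infinity = FALSE),
            class = "vanishing_point")
}

#' @export
print.vanishing_point <- function(x, ...) {
  if (x$at_infinity) cat("<vanishing_point> at infinity\n")
  else cat(sprintf("<vanishing_point> v0 = (%.2f, %.2f) px | %d votes | spread %.2f px\n",
                   x$v0[1], x$v0[2], x$n_votes, x$inlier_spread))
  invisible(x)
}

#' Temporally smooth a sequence of vanishing points
#'
#' Applies a per-coordinate sliding median over an ordered frame sequence;
#' frames with a missing vanishing point are first filled by linear
#' interpolation from their neighbours.
#'
#' @param vps A tibble with columns `frame`, `x`, `y` (NA for missing), or
#'   a list of `vanishing_point` objects.
#' @param window Odd window length for the running median.
#' @return A tibble with columns `frame`, `x`, `y`.
#' @export
smooth_vanishing_points <- function(vps, window = 5) {
  if (is.list(vps) && !is.data.frame(vps) && length(vps) &&
      inherits(vps[[1]], "vanishing_point")) {
    vps <- tibble::tibble(
      frame = seq_along(vps),
      x = vapply(vps, function(v) v$v0[1], numeric(1)),
      y = vapply(vps, function(v) v$v0[2], numeric(1)))
  }
  stopifnot(all(c("frame", "x", "y") %in% names(vps)))
  if (all(is.na(vps$x)))
    abort_trackcal("All vanishing points missing.", "all_missing")
  fill <- function(v) {
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      v <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
    }
    if (length(v) >= window)
      as.numeric(stats::runmed(v, window, endrule = "median")) else v
  }
  tibble::tibble(frame = vps$frame, x = fill(vps$x), y = fill(vps$y))
}
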