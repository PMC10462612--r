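# Lane detection: Sobel edge map -> Hough line transform -> sub-pixel
# segment refinement. The Hough transform is implemented here (voting over
# the (rho, theta) parameterisation x cos(theta) + y sin(theta) = rho) since
# line evidence on the track is the raw input of the whole calibration.

#' Detection configuration
#'
#' @param edge_threshold Gradient-magnitude threshold for the edge map
#'   (image intensities in `[0, 1]`).
#' @param theta_step_deg,rho_step Hough accumulator resolution (degrees /
#'   pixels).
#' @param min_votes Minimum accumulator votes for a line peak.
#' @param max_lines Maximum number of Hough peaks extracted.
#' @param nms_rho,nms_theta_deg Non-maximum-suppression window around each
#'   accepted peak.
#' @param seg_dist_tol Distance (px) within which edge pixels support a
#'   line; wide enough to span both edge ridges of a painted line so the
#'   refined fit recovers the line centre.
#' @param seg_max_gap Maximum along-line gap (px) within one segment.
#' @param seg_min_length Minimum segment length (px).
#' @param ridge_floor Intensity above which pixels count as painted-line
#'   ridge; segment refinement fits the ridge centre (falling back to edge
#'   pixels when too few ridge pixels support a segment).
#' @param max_line_rms Maximum weighted RMS lateral residual (px) of a
#'   refined segment fit; larger residuals indicate a fit mixing several
#'   converging lines and are rejected.
#' @param cluster_angle_window Half-width (deg) of the dominant-direction
#'   filter around the modal segment direction.
#' @param merge_angle_tol,merge_dist_tol Angle (deg) / perpendicular
#'   distance (px) tolerances for merging collinear segments into one lane.
#' @param vote_cell Grid-hash cell size (px) for the vanishing-point
#'   majority vote.
#' @param vote_radius Refinement radius (px) around the modal cell.
#' @param min_angle_gap Pairs of lanes closer than this in angle (deg)
#'   contribute no intersection vote (numerically unstable).
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(edge_threshold = 0.18, theta_step_deg = 0.5,
                          rho_step = 1, min_votes = 50, max_lines = 25,
                          nms_rho = 8, nms_theta_deg = 2,
                          seg_dist_tol = 3.5, seg_max_gap = 25,
                          seg_min_length = 50, ridge_floor = 0.7,
                          max_line_rms = 1,
                          cluster_angle_window = 10,
                          merge_angle_tol = 1.5, merge_dist_tol = 4,
                          vote_cell = 10, vote_radius = 25,
                          min_angle_gap = 0.5) {
  structure(as.list(environment()), class = "detect_config")
}

sobel_gradient <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (H >= 3 && W >= 3) {
    i <- 2:(H - 1); j <- 2:(W - 1)
    gx[i, j] <- (img[i - 1, j + 1] + 2 * img[i, j + 1] + img[i + 1, j + 1] -
                   img[i - 1, j - 1] - 2 * img[i, j - 1] - img[i + 1, j - 1]) / 4
    gy[i, j] <- (img[i + 1, j - 1] + 2 * img[i + 1, j] + img[i + 1, j + 1] -
                   img[i - 1, j - 1] - 2 * img[i - 1, j] - img[i - 1, j + 1]) / 4
  }
  sqrt(gx^2 + gy^2)
}

# Weighted total-least-squares line fit; returns centroid, unit direction
# and angle in [0, 180).
tls_line <- function(x, y, w = rep(1, length(x))) {
  W <- sum(w)
  mx <- sum(w * x) / W; my <- sum(w * y) / W
  dx <- x - mx; dy <- y - my
  sxx <- sum(w * dx * dx); syy <- sum(w * dy * dy); sxy <- sum(w * dx * dy)
  th <- 0.5 * atan2(2 * sxy, sxx - syy)
  u <- c(cos(th), sin(th))
  list(px = mx, py = my, ux = u[1], uy = u[2],
       angle = angle_mod180(rad2deg(th)))
}

#' Detect straight line segments in a frame
#'
#' Computes a Sobel gradient edge map, runs a Hough line transform, and for
#' each accumulator peak extracts contiguous runs of supporting edge pixels
#' as segments. Each segment is then refined to sub-pixel accuracy by a
#' gradient-weighted total-least-squares fit over its supporting pixels
#' (two passes with a shrinking inlier band), which recovers the centre
#' line of painted lane lines.
#'
#' @param image An H x W numeric matrix in `[0, 1]` (or a `synthetic_frame`,
#'   or a PNG path).
#' @param config A [detect_config()].
#' @return A tibble of class `line_segments` with columns `x1, y1, x2, y2`
#'   (pixels), `angle` (degrees in `[0, 180)`), `length` (pixels) and
#'   `support` (edge-pixel count). The image size is kept in attribute
#'   `image_size`. An empty image yields an empty tibble.
#' @export
detect_segments <- function(image, config = detect_config()) {
  if (inherits(image, "synthetic_frame")) image <- image$image
  if (is.character(image)) image <- read_frame_png(image)
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  empty <- structure(
    tibble::tibble(x1 = double(), y1 = double(), x2 = double(), y2 = double(),
                   angle = double(), length = double(), support = integer()),
    image_size = c(W, H), class = c("line_segments", class(tibble::tibble())))

  mag <- sobel_gradient(image)
  idx <- which(mag > config$edge_threshold, arr.ind = TRUE)
  if (nrow(idx) < config$min_votes) return(empty)
  ex <- idx[, 2] - 0.5 # pixel centres
  ey <- idx[, 1] - 0.5
  ew <- mag[idx]

  thetas <- deg2rad(seq(0, 180 - config$theta_step_deg, by = config$theta_step_deg))
  nt <- length(thetas)
  diag_len <- sqrt(W^2 + H^2)
  nr <- ceiling(2 * diag_len / config$rho_step) + 1L
  acc <- matrix(0L, nr, nt)
  ct <- cos(thetas); st <- sin(thetas)
  for (k in seq_len(nt)) {
    r <- ex * ct[k] + ey * st[k]
    bin <- floor((r + diag_len) / config$rho_step) + 1L
    acc[, k] <- tabulate(bin, nbins = nr)
  }

  # iterative peak extraction with non-maximum suppression
  peaks <- list()
  nms_r <- ceiling(config$nms_rho / config$rho_step)
  nms_t <- ceiling(config$nms_theta_deg / config$theta_step_deg)
  a <- acc
  while (length(peaks) < config$max_lines) {
    m <- max(a)
    if (m < config$min_votes) break
    ij <- which(a == m, arr.ind = TRUE)[1, ] # deterministic: first index
    ri <- as.integer(ij[[1]]); tj <- as.integer(ij[[2]])
    peaks[[length(peaks) + 1]] <- c(
      rho = (ri - 1) * config$rho_step - diag_len + config$rho_step / 2,
      theta = thetas[tj])
    tw <- ((tj - nms_t):(tj + nms_t) - 1L) %% nt + 1L
    rw <- max(1L, ri - nms_r):min(nr, ri + nms_r)
    a[rw, tw] <- 0L
  }
  if (!length(peaks)) return(empty)

  # bright-ridge pixels: centre evidence for the painted lines
  ridx <- which(image > config$ridge_floor, arr.ind = TRUE)
  rx <- ridx[, 2] - 0.5; ry <- ridx[, 1] - 0.5
  rw <- image[ridx] - config$ridge_floor

  # refine a line over ridge (preferred) or edge pixels near it, iterating
  # with a shrinking inlier band; returns NULL if support is too thin.
  # Records the weighted RMS lateral residual: clean centre-line fits are
  # tight, fits mixing several converging lines are not.
  refine_line <- function(fit, t0, t1, bands = c(3.5, 2.5, 2.5)) {
    for (b in bands) {
      use_ridge <- length(rx) > 0
      if (use_ridge) {
        d <- (rx - fit$px) * (-fit$uy) + (ry - fit$py) * fit$ux
        tp <- (rx - fit$px) * fit$ux + (ry - fit$py) * fit$uy
        sel <- which(abs(d) <= b & tp >= t0 - 2 & tp <= t1 + 2)
      } else sel <- integer(0)
      if (length(sel) >= 0.5 * (t1 - t0)) {
        xs <- rx[sel]; ys <- ry[sel]; ws <- rw[sel]
      } else {
        d <- (ex - fit$px) * (-fit$uy) + (ey - fit$py) * fit$ux
        tp <- (ex - fit$px) * fit$ux + (ey - fit$py) * fit$uy
        sel <- which(abs(d) <= b & tp >= t0 - 2 & tp <= t1 + 2)
        if (length(sel) < 2) return(NULL)
        xs <- ex[sel]; ys <- ey[sel]; ws <- ew[sel]
      }
      fit <- tls_line(xs, ys, ws)
    }
    dres <- (xs - fit$px) * (-fit$uy) + (ys - fit$py) * fit$ux
    fit$rms <- sqrt(sum(ws * dres^2) / sum(ws))
    fit$support <- length(xs)
    fit
  }

  segs <- list()
  for (p in peaks) {
    rho <- p[["rho"]]; th <- p[["theta"]]
    dist <- abs(ex * cos(th) + ey * sin(th) - rho)
    inl <- which(dist <= config$seg_dist_tol)
    if (length(inl) < 2) next
    tpar <- -ex[inl] * sin(th) + ey[inl] * cos(th)
    o <- order(tpar)
    inl <- inl[o]; tpar <- tpar[o]
    gaps <- which(diff(tpar) > config$seg_max_gap)
    starts <- c(1L, gaps + 1L)
    ends <- c(gaps, length(tpar))
    for (s in seq_along(starts)) {
      run <- inl[starts[s]:ends[s]]
      if (tpar[ends[s]] - tpar[starts[s]] < config$seg_min_length) next
      fit <- tls_line(ex[run], ey[run], ew[run])
      tp0 <- (ex[run] - fit$px) * fit$ux + (ey[run] - fit$py) * fit$uy
      fit <- refine_line(fit, min(tp0), max(tp0))
      if (is.null(fit)) next
      # segment extent: run inliers projected onto the refined line
      d <- (ex[run] - fit$px) * (-fit$uy) + (ey[run] - fit$py) * fit$ux
      tpk <- ((ex[run] - fit$px) * fit$ux + (ey[run] - fit$py) * fit$uy)[abs(d) <= 3.5]
      if (!length(tpk)) next
      t0 <- min(tpk); t1 <- max(tpk)
      if (t1 - t0 < config$seg_min_length) next
      if (fit$rms > config$max_line_rms) next # mixed-line fit: reject
      segs[[length(segs) + 1]] <- tibble::tibble(
        x1 = fit$px + t0 * fit$ux, y1 = fit$py + t0 * fit$uy,
        x2 = fit$px + t1 * fit$ux, y2 = fit$py + t1 * fit$uy,
        angle = fit$angle, length = t1 - t0, support = fit$support)
    }
  }
  if (!length(segs)) return(empty)
  out <- dplyr::bind_rows(segs)

  # dedupe: refits of the same physical line (close along their whole
  # overlap, not just at one crossing point) keep the longest
  out <- out[order(-out$length), ]
  kept <- integer(0)
  for (i in seq_len(nrow(out))) {
    dup <- FALSE
    for (k in kept) {
      if (angle_gap180(out$angle[i], out$angle[k]) <= 2.5 &&
          abs(line_point_dist(out$x1[k], out$y1[k], out$angle[k],
                              out$x1[i], out$y1[i])) <= 4 &&
          abs(line_point_dist(out$x1[k], out$y1[k], out$angle[k],
                              out$x2[i], out$y2[i])) <= 4) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  out <- out[kept, ]
  structure(out, image_size = c(W, H),
            class = c("line_segments", class(tibble::tibble())))
}
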