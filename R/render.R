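# Synthetic track renderer: lane images with exact ground truth, so the
# detection -> calibration pipeline can be validated end to end without any
# external footage.

#' Rendering style for synthetic track frames
#'
#' @param line_width_px Painted line width in pixels (default 3, anti-aliased).
#' @param line_intensity Line brightness in `[0, 1]`.
#' @param bg_base,bg_gradient Background grey level and top-to-bottom
#'   gradient amplitude, emulating the track surface.
#' @param bg_noise_sd Standard deviation of the additive background noise, so
#'   edge detection faces non-trivial input.
#' @return A list of class `render_style`.
#' @export
render_style <- function(line_width_px = 3, line_intensity = 1,
                         bg_base = 0.32, bg_gradient = 0.12, bg_noise_sd = 0.03) {
  structure(list(line_width_px = line_width_px, line_intensity = line_intensity,
                 bg_base = bg_base, bg_gradient = bg_gradient,
                 bg_noise_sd = bg_noise_sd), class = "render_style")
}

#' Radial lens distortion (renderer robustness knob)
#'
#' Distortion is applied only at render time; the calibration path is
#' strictly pinhole. `k1 = k2 = 0` is the pinhole case. Radii are
#' normalised by half the image width.
#'
#' @param k1,k2 Radial distortion coefficients (unitless).
#' @return A list of class `distortion_model`.
#' @export
distortion_model <- function(k1 = 0, k2 = 0) {
  structure(list(k1 = k1, k2 = k2), class = "distortion_model")
}

distort_pixels <- function(xy, centre, half_width, dist) {
  if (dist$k1 == 0 && dist$k2 == 0) return(xy)
  dx <- (xy[, 1] - centre[1]) / half_width
  dy <- (xy[, 2] - centre[2]) / half_width
  r2 <- dx^2 + dy^2
  fac <- 1 + dist$k1 * r2 + dist$k2 * r2^2
  cbind(centre[1] + dx * fac * half_width, centre[2] + dy * fac * half_width)
}

# Run expr with a private RNG state seeded by `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Anti-aliased segment rasteriser. Pixel (row i, col j) has centre
# (j - 0.5, i - 0.5); coverage falls off linearly over one pixel at the
# line boundary. Draws with max-compositing.
draw_segment_aa <- function(img, p1, p2, width, intensity) {
  H <- nrow(img); W <- ncol(img)
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < 1e-9) return(img)
  halfw <- width / 2 + 0.5
  if (abs(d[1]) >= abs(d[2])) { # x-major
    cosang <- abs(d[1]) / len
    xs <- sort(c(p1[1], p2[1]))
    cols <- seq(max(1L, floor(xs[1] + 0.5)), min(W, ceiling(xs[2] + 0.5)))
    if (!length(cols)) return(img)
    xc <- cols - 0.5
    t <- (xc - p1[1]) / d[1]
    keep <- t >= 0 & t <= 1
    cols <- cols[keep]; xc <- xc[keep]
    if (!length(cols)) return(img)
    yc <- p1[2] + (xc - p1[1]) / d[1] * d[2]
    k <- ceiling(halfw / cosang) + 1L
    offs <- -k:k
    rows <- outer(round(yc + 0.5), offs, `+`)
    ycpix <- rows - 0.5
    dist <- abs(ycpix - yc) * cosang
    cov <- clamp(halfw - dist, 0, 1) * intensity
    jj <- matrix(cols, nrow = length(cols), ncol = length(offs))
    ok <- rows >= 1 & rows <= H & cov > 0
    idx <- cbind(rows[ok], jj[ok])
    img[idx] <- pmax(img[idx], cov[ok])
  } else { # y-major
    cosang <- abs(d[2]) / len
    ys <- sort(c(p1[2], p2[2]))
    rows <- seq(max(1L, floor(ys[1] + 0.5)), min(H, ceiling(ys[2] + 0.5)))
    if (!length(rows)) return(img)
    yc <- rows - 0.5
    t <- (yc - p1[2]) / d[2]
    keep <- t >= 0 & t <= 1
    rows <- rows[keep]; yc <- yc[keep]
    if (!length(rows)) return(img)
    xc <- p1[1] + (yc - p1[2]) / d[2] * d[1]
    k <- ceiling(halfw / cosang) + 1L
    offs <- -k:k
    colsm <- outer(round(xc + 0.5), offs, `+`)
    xcpix <- colsm - 0.5
    dist <- abs(xcpix - xc) * cosang
    cov <- clamp(halfw - dist, 0, 1) * intensity
    ii <- matrix(rows, nrow = length(rows), ncol = length(offs))
    ok <- colsm >= 1 & colsm <= W & cov > 0
    idx <- cbind(ii[ok], colsm[ok])
    img[idx] <- pmax(img[idx], cov[ok])
  }
  img
}

# Liang-Barsky clipping of a 2D segment to [x0,x1] x [y0,y1]; NULL if outside.
clip_segment_rect <- function(p1, p2, x0, x1, y0, y1) {
  d <- p2 - p1
  p <- c(-d[1], d[1], -d[2], d[2])
  q <- c(p1[1] - x0, x1 - p1[1], p1[2] - y0, y1 - p1[2])
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 > t1) return(NULL)
  list(p1 = p1 + t0 * d, p2 = p1 + t1 * d)
}

#' Render lane lines from a known camera
#'
#' Projects the scene's lane demarcations through the camera and rasterises
#' them as anti-aliased bright lines over a textured background. The exact
#' (pre-distortion) analytic image lines and the analytic lane vanishing
#' point are recorded as ground truth.
#'
#' @param camera A [camera_params()].
#' @param scene A [track_scene()].
#' @param style A [render_style()].
#' @param distortion A [distortion_model()]; applied only to rendered pixels,
#'   never to the recorded ground truth.
#' @param seed Integer seed for the background noise.
#' @return An object of class `synthetic_frame`: `image` (H x W matrix in
#'   `[0, 1]`), `camera`, `scene`, `lanes_true` (tibble of visible analytic
#'   image lines: `lane`, endpoints `x1, y1, x2, y2`, `angle`), `v0_true`
#'   (pixels) and the render settings.
#' @export
render_track <- function(camera, scene = track_scene(), style = render_style(),
                         distortion = distortion_model(), seed = 1) {
  stopifnot(inherits(camera, "camera_params"), inherits(scene, "track_scene"))
  proj <- build_projection(camera)
  W <- round(camera$image_size[1]); H <- round(camera$image_size[2])

  img <- with_local_seed(seed, {
    base <- style$bg_base + style$bg_gradient * (row(matrix(0, H, W)) / H)
    base + matrix(stats::rnorm(H * W, 0, style$bg_noise_sd), H, W)
  })
  img <- clamp(img, 0, 1)

  lanes <- lane_lines_3d(scene)
  eps <- 0.2 # metres of clearance in front of the camera
  truth <- list()
  for (i in seq_len(nrow(lanes))) {
    A <- c(lanes$x1[i], lanes$y1[i], 0)
    B <- c(lanes$x2[i], lanes$y2[i], 0)
    wA <- sum(proj$R[3, ] * A) + proj$t[3]
    wB <- sum(proj$R[3, ] * B) + proj$t[3]
    if (wA <= eps && wB <= eps) next
    if (wA <= eps) A <- A + (B - A) * (eps - wA) / (wB - wA)
    if (wB <= eps) B <- A + (B - A) * (eps - wA) / (wB - wA)
    pa <- project_points(rbind(A, B), proj)
    seg <- clip_segment_rect(c(pa$x[1], pa$y[1]), c(pa$x[2], pa$y[2]),
                             -2, W + 2, -2, H + 2)
    if (is.null(seg)) next
    if (sqrt(sum((seg$p2 - seg$p1)^2)) < 2) next
    if (distortion$k1 == 0 && distortion$k2 == 0) {
      img <- draw_segment_aa(img, seg$p1, seg$p2, style$line_width_px,
                             style$line_intensity)
    } else {
      n <- max(2L, ceiling(sqrt(sum((seg$p2 - seg$p1)^2)) / 5))
      tt <- seq(0, 1, length.out = n + 1)
      pts <- cbind(seg$p1[1] + tt * (seg$p2[1] - seg$p1[1]),
                   seg$p1[2] + tt * (seg$p2[2] - seg$p1[2]))
      pts <- distort_pixels(pts, c(W / 2, H / 2), W / 2, distortion)
      for (s in seq_len(n))
        img <- draw_segment_aa(img, pts[s, ], pts[s + 1, ],
                               style$line_width_px, style$line_intensity)
    }
    ang <- angle_mod180(rad2deg(atan2(seg$p2[2] - seg$p1[2],
                                      seg$p2[1] - seg$p1[1])))
    truth[[length(truth) + 1]] <- tibble::tibble(
      lane = lanes$lane[i], x1 = seg$p1[1], y1 = seg$p1[2],
      x2 = seg$p2[1], y2 = seg$p2[2], angle = ang)
  }
  if (!length(truth))
    abort_trackcal("Track is fully out of frame for this camera.", "out_of_frame")

  structure(list(image = img, camera = camera, scene = scene,
                 lanes_true = dplyr::bind_rows(truth),
                 v0_true = lane_vanishing_point(proj),
                 style = style, distortion = distortion, seed = seed),
            class = "synthetic_frame")
}

#' @export
print.synthetic_frame <- function(x, ...) {
  cat(sprintf("<synthetic_frame> %d x %d px, %d visible lane lines, v0 = (%.1f, %.1f)\n",
              ncol(x$image), nrow(x$image), nrow(x$lanes_true),
              x$v0_true[1], x$v0_true[2]))
  invisible(x)
}

#' Write a frame image as PNG
#'
#' @param frame A `synthetic_frame` or a numeric image matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_frame_png <- function(frame, path) {
  img <- if (inherits(frame, "synthetic_frame")) frame$image else frame
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

#' Read a frame image
#'
#' Reads a PNG and converts it to a grayscale matrix in `[0, 1]`.
#'
#' @param path PNG file path.
#' @return An H x W numeric matrix.
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    # luma conversion for RGB(A)
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a
}
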