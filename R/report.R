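#' Evaluate 3D pose predictions against reference 2D skeletons
#'
#' Runs the full per-frame auditing pipeline: ray-trace the reference
#' skeleton's lowest ankle onto the ground to place the predicted 3D
#' skeleton, scale it to the reference's projected height, optionally apply
#' a correction strategy, project, align, and compute all four error
#' metrics (reprojection px and height-scaled mm, 2D knee error, and
#' sensitivity-rescaled approximate 3D knee error, each averaged over both
#' legs). Frames failing placement are skipped and logged, not fatal.
#'
#' Strategies: `"base"` audits the predictions as-is; `"movement"`
#' straightens the predicted ground path ([straighten_path()]);
#' `"rotation"` additionally rotates each skeleton to face the finish line
#' ([rotate_to_facing()]).
#'
#' @param reference2d List of reference `skeleton2d` (one per frame).
#' @param predicted3d List of predicted `skeleton3d`.
#' @param cameras A single [camera_params()] or a list, one per frame.
#' @param strategy `"base"`, `"movement"` or `"rotation"`.
#' @param athlete_height_mm Athlete height used for the mm scaling.
#' @param delta Knee perturbation magnitude (degrees) for the 3D
#'   approximation.
#' @param ankle_height_m Ground clearance of the ankle joint, metres: the
#'   reference ankle pixel is ray-traced onto the plane `z = ankle_height_m`
#'   (the ankle sits above the sole), and the predicted skeleton's
#'   same-named ankle is placed there.
#' @return An object of class `pose_eval`: `per_frame` (tibble of
#'   per-frame metrics), `summary` (one-row tibble of means and standard
#'   deviations), `strategy`, `skipped` (frame indices that failed
#'   placement).
#' @export
evaluate_skeletons <- function(reference2d, predicted3d, cameras,
                               strategy = c("base", "movement", "rotation"),
                               athlete_height_mm = 1800, delta = 1,
                               ankle_height_m = 0.08) {
  strategy <- match.arg(strategy)
  n <- length(reference2d)
  stopifnot(length(predicted3d) == n, n >= 1)
  if (inherits(cameras, "camera_params")) cameras <- rep(list(cameras), n)
  stopifnot(length(cameras) == n)
  projs <- lapply(cameras, build_projection)

  # pass 1: place and scale every frame
  placed <- vector("list", n)
  anchors <- matrix(NA_real_, n, 2)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ref <- reference2d[[i]]
    sides <- c("ankle_l", "ankle_r")
    ay <- ref$y[match(sides, ref$joint)]
    ax <- ref$x[match(sides, ref$joint)]
    low <- which.max(ay) # image-lowest ankle is the contact foot
    ok <- tryCatch({
      anchor <- ray_trace_to_height(c(ax[low], ay[low]), projs[[i]],
                                    ankle_height_m)
      s <- predicted3d[[i]]
      shift <- c(anchor, ankle_height_m) - joint_xyz(s, sides[low])
      s$x <- s$x + shift[1]; s$y <- s$y + shift[2]; s$z <- s$z + shift[3]
      s <- scale_skeleton(s, skeleton_height(ref), projs[[i]])
      placed[[i]] <- s
      anchors[i, ] <- anchor
      TRUE
    }, trackcal_error = function(e) FALSE)
    if (!ok) skipped <- c(skipped, i)
  }
  kept <- setdiff(seq_len(n), skipped)
  if (!length(kept))
    abort_trackcal("Every frame failed placement.", "degenerate")

  if (strategy %in% c("movement", "rotation") && length(kept) >= 2) {
    st <- straighten_path(placed[kept],
                          tibble::tibble(x = anchors[kept, 1],
                                         y = anchors[kept, 2]))
    placed[kept] <- st$skeletons
  }
  if (strategy == "rotation") {
    placed[kept] <- lapply(placed[kept], rotate_to_facing, facing = c(1, 0))
  }

  rows <- lapply(kept, function(i) {
    ref <- reference2d[[i]]
    proj <- projs[[i]]
    s <- placed[[i]]
    re <- reprojection_error(s, proj, ref, athlete_height_mm)
    p2 <- apply_alignment(project_skeleton(s, proj),
                          align_2d(project_skeleton(s, proj), ref))
    k2 <- k3 <- numeric(2)
    for (j in 1:2) {
      side <- c("left", "right")[j]
      k2[j] <- abs(knee_angle_2d(p2, side) - knee_angle_2d(ref, side))
      k3[j] <- as.numeric(approx_3d_knee_error(s, proj, k2[j], side,
                                               delta = delta))
    }
    tibble::tibble(frame = i, reproj_px = re$px, reproj_mm = re$mm,
                   knee2d_deg = mean(k2), knee3d_deg = mean(k3))
  })
  per_frame <- dplyr::bind_rows(rows)
  summ <- dplyr::summarise(
    per_frame,
    dplyr::across(c("reproj_px", "reproj_mm", "knee2d_deg", "knee3d_deg"),
                  list(mean = mean, sd = stats::sd)))
  structure(list(per_frame = per_frame, summary = summ, strategy = strategy,
                 skipped = skipped),
            class = "pose_eval")
}

#' @export
print.pose_eval <- function(x, ...) {
  cat(sprintf("<pose_eval> strategy '%s', %d frames (%d skipped)\n",
              x$strategy, nrow(x$per_frame), length(x$skipped)))
  s <- x$summary
  cat(sprintf("  reprojection %.2f (%.2f) px | %.2f (%.2f) mm\n",
              s$reproj_px_mean, s$reproj_px_sd, s$reproj_mm_mean, s$reproj_mm_sd))
  cat(sprintf("  knee 2D %.2f (%.2f) deg | approx 3D %.2f (%.2f) deg\n",
              s$knee2d_deg_mean, s$knee2d_deg_sd,
              s$knee3d_deg_mean, s$knee3d_deg_sd))
  invisible(x)
}

#' Convenience wrapper: evaluate a synthetic case
#'
#' @param case A [make_case()] result.
#' @param strategy See [evaluate_skeletons()].
#' @param ... Passed to [evaluate_skeletons()].
#' @return A `pose_eval`.
#' @export
evaluate_case <- function(case, strategy = "base", ...) {
  stopifnot(inherits(case, "synthetic_case"))
  evaluate_skeletons(case$skeletons2d, case$skeletons3d_pred, case$camera,
                     strategy = strategy, ...)
}
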