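#' Read and write skeletons as JSON
#'
#' A single skeleton is stored as
#' `{"joints": {"head": [x, y, z], ...}, "space": "metric"}` (2D skeletons
#' use two coordinates and `"space": "pixel"`). Frame sequences use JSON
#' lines: one object per line with an additional `"frame"` index.
#'
#' @param skel A skeleton.
#' @param path File path.
#' @return `read_skeleton()` returns a skeleton; `read_skeleton_seq()` a
#'   list of skeletons named by frame index; writers return `path`
#'   invisibly.
#' @export
write_skeleton <- function(skel, path) {
  jsonlite::write_json(skeleton_to_list(skel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

skeleton_to_list <- function(skel, frame = NULL) {
  m <- skeleton_matrix(skel)
  out <- list(joints = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  names(out$joints) <- rownames(m)
  out$space <- attr(skel, "space")
  if (!is.null(frame)) out$frame <- frame
  out
}

skeleton_from_list <- function(lst) {
  j <- lst$joints
  m <- unname(do.call(rbind, j[joint_names()]))
  if (identical(lst$space, "metric")) skeleton_3d(m) else skeleton_2d(m)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  skeleton_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @param skels A list of skeletons.
#' @param frames Optional integer frame indices (defaults to 1-based order).
#' @rdname write_skeleton
#' @export
write_skeleton_seq <- function(skels, path, frames = seq_along(skels)) {
  lines <- vapply(seq_along(skels), function(i) {
    jsonlite::toJSON(skeleton_to_list(skels[[i]], frame = frames[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton_seq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  skels <- lapply(objs, skeleton_from_list)
  names(skels) <- vapply(objs, function(o) as.character(o$frame), character(1))
  skels
}
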