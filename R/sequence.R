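# Motion-sequence container: ordered per-frame femoral/patellar geometry.

#' Single motion frame
#'
#' @param frame_index integer frame number.
#' @param femur a [surface_model()] (scanner mm).
#' @param patella_points n x 3 matrix of patellar points (scanner mm).
#' @param flexion_angle optional flexion angle (degrees).
#' @return object of class `frame_data`.
#' @export
frame_data <- function(frame_index, femur, patella_points,
                       flexion_angle = NULL) {
  stopifnot(inherits(femur, "surface_model"))
  pts <- as_points(patella_points)
  if (nrow(pts) == 0L) stop("frame ", frame_index, ": empty patellar cloud")
  if (nrow(femur$vertices) < 4L) stop("frame ", frame_index, ": femur too small")
  structure(list(frame_index = as.integer(frame_index), femur = femur,
                 patella_points = pts,
                 flexion_angle = if (is.null(flexion_angle)) NULL
                                 else as.numeric(flexion_angle)),
            class = "frame_data")
}

#' Knee motion sequence
#'
#' Ordered per-frame geometry for one knee over an active flexion cycle
#' (typically 20-30 time-resolved CT frames covering about 0-90 degrees).
#'
#' @param subject_id character label.
#' @param side `"right"` or `"left"`.
#' @param frames list of [frame_data()] objects with strictly increasing
#'   frame indices; at least 3 frames.
#' @return object of class `knee_sequence`.
#' @export
knee_sequence <- function(subject_id, side = c("right", "left"), frames) {
  side <- match.arg(side)
  if (length(frames) < 3L) stop("a knee sequence needs at least 3 frames")
  stopifnot(all(vapply(frames, inherits, logical(1L), "frame_data")))
  idx <- vapply(frames, `[[`, integer(1L), "frame_index")
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("frame indices must be strictly increasing")
  }
  structure(list(subject_id = as.character(subject_id), side = side,
                 frames = frames, N = length(frames)),
            class = "knee_sequence")
}

#' @export
print.knee_sequence <- function(x, ...) {
  ang <- vapply(x$frames, function(fr) if (is.null(fr$flexion_angle))
    NA_real_ else fr$flexion_angle, numeric(1L))
  cat("Knee sequence '", x$subject_id, "' (", x$side, "): ", x$N,
      " frames\n", sep = "")
  if (all(is.finite(ang))) {
    cat("  flexion ", paste(round(range(ang), 1), collapse = " to "),
        " deg\n", sep = "")
  }
  invisible(x)
}
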