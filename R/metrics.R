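# MPFL length profiles and normalized length-change (MPFL%) summaries.

#' Frame-wise MPFL lengths for a femoral attachment
#'
#' Straight-line (attachment to patellar centroid) distance per frame, the
#' modeled ligament length. Uses the raw per-frame C-points of the
#' trajectory, not the smoothed curve.
#'
#' @param attachment femoral point (length-3, local mm).
#' @param traj a [fit_trajectory()] result.
#' @return numeric vector of lengths (mm), one per frame. A warning is
#'   issued if any length is (near) zero.
#' @export
length_series <- function(attachment, traj) {
  stopifnot(inherits(traj, "trajectory"))
  attachment <- drop(as_points(attachment))
  L <- sqrt(rowSums(sweep(traj$points, 2L, attachment)^2))
  if (any(L < 1e-9)) {
    warning("attachment coincides with a patellar centroid; ",
            "degenerate zero length")
  }
  L
}

#' Normalized MPFL length change
#'
#' Converts a length series to percent deviation from a reference length:
#' `MPFL% = 100 * (L_i - L_ref) / L_ref`. The default reference is the
#' per-subject mean length over the motion; alternatively the length at a
#' stated flexion angle (evaluated on the fitted trajectory) or an explicit
#' reference in mm can be used.
#'
#' @param lengths positive length series (mm).
#' @param reference `"mean"`, a numeric reference length (mm), or
#'   `list(at_angle = theta)` together with `attachment` and `traj`.
#' @param attachment,traj required only for `list(at_angle = )` references.
#' @param angles optional per-frame flexion angles (degrees); defaults to
#'   the trajectory's angles if `traj` is supplied.
#' @return object of class `length_profile`: `lengths`, `reference`,
#'   `percent` (per frame), `angles`, `binned` (mean MPFL% per 10-degree
#'   bin, 0-90), `min_pct`, `max_pct`.
#' @export
mpfl_percent <- function(lengths, reference = "mean", attachment = NULL,
                         traj = NULL, angles = NULL) {
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (is.list(reference) && !is.null(reference$at_angle)) {
    if (is.null(attachment) || is.null(traj)) {
      stop("reference at an angle needs `attachment` and `traj`")
    }
    cref <- evaluate_trajectory(traj, reference$at_angle)
    L_ref <- vnorm(drop(cref) - drop(as_points(attachment)))
  } else if (is.numeric(reference)) {
    L_ref <- reference
  } else if (identical(reference, "mean")) {
    L_ref <- mean(lengths)
  } else {
    stop("unknown reference specification")
  }
  if (L_ref <= 0) stop("reference length must be positive")
  pct <- 100 * (lengths - L_ref) / L_ref
  if (is.null(angles) && !is.null(traj)) angles <- traj$angles
  prof <- structure(list(lengths = lengths, reference = L_ref,
                         percent = pct, angles = angles, binned = NULL,
                         min_pct = min(pct), max_pct = max(pct)),
                    class = "length_profile")
  if (!is.null(traj) && !is.null(attachment)) {
    prof$binned <- bin_by_angle(prof, traj, attachment = attachment)
  }
  prof
}

#' Mean MPFL% per 10-degree flexion bin
#'
#' Frames are assigned to the bins centered at 0, 10, ..., 90 degrees by the
#' half-open rule `[theta - 5, theta + 5)` (end bins clamped to the 0-90
#' range). A bin with no frames is filled by evaluating the fitted
#' trajectory at its center angle.
#'
#' @param profile a [mpfl_percent()] result with per-frame angles.
#' @param traj the fitted [fit_trajectory()] (for empty-bin evaluation).
#' @param attachment femoral attachment used for empty-bin evaluation.
#' @return named numeric vector of 10 mean MPFL% values.
#' @export
bin_by_angle <- function(profile, traj, attachment = NULL) {
  stopifnot(inherits(profile, "length_profile"))
  ang <- profile$angles
  if (is.null(ang)) ang <- traj$angles
  centers <- seq(0, 90, by = 10)
  out <- rep(NA_real_, 10L)
  bin_of <- pmin(pmax(floor((ang + 5) / 10), 0), 9)
  for (b in 0:9) {
    sel <- bin_of == b
    if (any(sel)) out[b + 1L] <- mean(profile$percent[sel])
  }
  empty <- which(is.na(out))
  if (length(empty)) {
    if (is.null(attachment)) {
      stop("empty bins at ", paste(centers[empty], collapse = ", "),
           " degrees and no attachment given to evaluate the fitted curve")
    }
    a <- drop(as_points(attachment))
    cpts <- evaluate_trajectory(traj, centers[empty])
    Lhat <- sqrt(rowSums(sweep(cpts, 2L, a)^2))
    out[empty] <- 100 * (Lhat - profile$reference) / profile$reference
  }
  names(out) <- paste0(centers, "deg")
  out
}

#' Extreme MPFL% values of a profile
#'
#' @param profile a [mpfl_percent()] result.
#' @return named vector `c(min = , max = )` in percent.
#' @export
max_variation <- function(profile) {
  stopifnot(inherits(profile, "length_profile"))
  c(min = profile$min_pct, max = profile$max_pct)
}

#' Full length profile for one attachment
#'
#' Convenience wrapper: [length_series()] then [mpfl_percent()] with binning.
#'
#' @param attachment femoral point (local mm).
#' @param traj fitted trajectory.
#' @param reference see [mpfl_percent()].
#' @return a `length_profile`.
#' @export
mpfl_profile <- function(attachment, traj, reference = "mean") {
  L <- length_series(attachment, traj)
  mpfl_percent(L, reference = reference, attachment = attachment, traj = traj)
}

#' @export
print.length_profile <- function(x, ...) {
  cat("MPFL length profile: ", length(x$lengths), " frames, reference ",
      format(round(x$reference, 2)), " mm\n", sep = "")
  cat("  MPFL% range: ", format(round(x$min_pct, 2)), " to ",
      format(round(x$max_pct, 2)), " %\n", sep = "")
  if (!is.null(x$binned)) {
    print(round(x$binned, 3))
  }
  invisible(x)
}
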