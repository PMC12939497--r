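# Patellar centroid extraction and trajectory fitting over knee flexion.

#' Geometric centroid of the patellar point cloud
#'
#' Arithmetic mean of the supplied points. If a logical `mask` marking the
#' articular-surface subset is given, only masked points contribute.
#'
#' @param patella_points n x 3 matrix (mm).
#' @param mask optional logical vector of length n.
#' @return length-3 centroid (mm).
#' @export
patellar_centroid <- function(patella_points, mask = NULL) {
  pts <- as_points(patella_points)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(pts))
    pts <- pts[mask, , drop = FALSE]
  }
  if (nrow(pts) == 0L) stop("empty patellar point set")
  colMeans(pts)
}

#' Fit the patellar centroid trajectory across the motion
#'
#' Extracts the patellar centroid (C-point) of every frame, expresses it in
#' the femoral frame, and fits an independent least-squares polynomial of the
#' given degree to each local coordinate. The fit parameter is the per-frame
#' flexion angle when available (and non-decreasing); otherwise the
#' normalized frame index in \[0, 1\] is used and flexion angles are later
#' assigned by normalized arc length along the fitted curve scaled to 0-90
#' degrees.
#'
#' The raw per-frame C-points (not the smoothed curve) are what the I-point
#' optimizer targets; the fitted curve serves angle-grid evaluation.
#'
#' @param sequence a [knee_sequence()].
#' @param frame a [femoral_frame()].
#' @param degree polynomial degree per coordinate (default 3).
#' @return object of class `trajectory`: `points` (N x 3 raw C-points, local
#'   mm), `param` (fit parameter per frame), `angles` (flexion degrees per
#'   frame), `param_is_angle`, `coef` (3-column coefficient matrix, ascending
#'   powers), `rms_residual` (per-coordinate RMS fit residual, mm), `range`
#'   (parameter range).
#' @export
fit_trajectory <- function(sequence, frame, degree = 3L) {
  stopifnot(inherits(sequence, "knee_sequence"), inherits(frame, "femoral_frame"))
  degree <- as.integer(degree)
  n <- length(sequence$frames)
  if (n <= degree) {
    stop("need more frames (", n, ") than the polynomial degree (", degree, ")")
  }
  cpts <- t(vapply(sequence$frames,
                   function(fr) patellar_centroid(fr$patella_points),
                   numeric(3L)))
  local <- to_local(frame, cpts)

  angles <- vapply(sequence$frames,
                   function(fr) if (is.null(fr$flexion_angle)) NA_real_
                                else as.numeric(fr$flexion_angle),
                   numeric(1L))
  have_angles <- all(is.finite(angles))
  param_is_angle <- FALSE
  if (have_angles) {
    if (is.unsorted(angles)) {
      warning("flexion angles are not monotone; falling back to ",
              "frame-index parameterization")
    } else {
      param_is_angle <- TRUE
    }
  }
  t_par <- if (param_is_angle) angles else (seq_len(n) - 1) / (n - 1)

  basis <- stats::poly(t_par, degree = degree, raw = TRUE, simple = TRUE)
  coefs <- matrix(0, degree + 1L, 3L,
                  dimnames = list(NULL, c("X", "Y", "Z")))
  res2 <- 0
  for (j in 1:3) {
    fit <- stats::lm.fit(cbind(1, basis), local[, j])
    coefs[, j] <- fit$coefficients
    res2 <- res2 + sum(fit$residuals^2)
  }
  coefs[is.na(coefs)] <- 0

  traj <- structure(list(points = local, param = t_par, angles = angles,
                         param_is_angle = param_is_angle, degree = degree,
                         coef = coefs,
                         rms_residual = sqrt(res2 / (3 * n)),
                         range = range(t_par)),
                    class = "trajectory")
  if (!param_is_angle) {
    traj$angles <- arc_length_angles(traj)
  }
  traj
}

# Normalized cumulative arc length along the fitted curve at the frame
# parameters, scaled to 0-90 degrees. Convention used when no flexion-angle
# metadata exists.
arc_length_angles <- function(traj, grid_n = 400L) {
  tt <- seq(traj$range[1L], traj$range[2L], length.out = grid_n)
  pts <- poly_eval(traj$coef, tt)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[grid_n]
  if (total < 1e-12) return(rep(0, length(traj$param)))
  s_at <- stats::approx(tt, s, xout = traj$param, rule = 2L)$y
  90 * s_at / total
}

poly_eval <- function(coefs, tt) {
  deg <- nrow(coefs) - 1L
  basis <- outer(tt, 0:deg, "^")
  out <- basis %*% coefs
  colnames(out) <- c("X", "Y", "Z")
  out
}

# Map a flexion angle to the fit parameter: identity when the fit parameter
# is the angle, otherwise inverse of the arc-length angle map.
angle_to_param <- function(traj, angles) {
  if (traj$param_is_angle) return(angles)
  tt <- seq(traj$range[1L], traj$range[2L], length.out = 400L)
  pts <- poly_eval(traj$coef, tt)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  ang <- if (s[length(s)] < 1e-12) rep(0, length(tt)) else 90 * s / s[length(s)]
  stats::approx(ang, tt, xout = angles, rule = 2L, ties = "ordered")$y
}

#' Evaluate a fitted trajectory on an angle grid
#'
#' @param traj a [fit_trajectory()] result.
#' @param angles flexion angles (degrees).
#' @return n x 3 matrix of C-point positions (local mm). If any requested
#'   angle extrapolates more than 5 degrees beyond the fitted range, the
#'   attribute `"extrapolated"` lists the offending angles.
#' @export
evaluate_trajectory <- function(traj, angles) {
  stopifnot(inherits(traj, "trajectory"))
  angles <- as.numeric(angles)
  obs <- range(traj$angles)
  over <- angles[angles < obs[1L] - 5 | angles > obs[2L] + 5]
  if (length(over)) {
    warning("evaluating > 5 degrees outside the observed flexion range: ",
            paste(round(over, 1), collapse = ", "))
  }
  out <- poly_eval(traj$coef, angle_to_param(traj, angles))
  if (length(over)) attr(out, "extrapolated") <- over
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Patellar centroid trajectory: ", nrow(x$points), " frames, degree ",
      x$degree, " fit, RMS residual ", format(signif(x$rms_residual, 4)),
      " mm\n", sep = "")
  cat("  parameterization: ",
      if (x$param_is_angle) "flexion angle" else "normalized frame index",
      "; flexion span ", paste(round(range(x$angles), 1), collapse = "-"),
      " deg\n", sep = "")
  invisible(x)
}
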