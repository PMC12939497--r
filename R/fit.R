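# Front-end model fit: from a knee sequence and landmarks to the
# individualized femoral attachment and its length-change profile.

#' Fit the individualized femoral attachment (I-point) for one knee
#'
#' End-to-end estimator: builds the femur-centered anatomical frame from the
#' landmarks, expresses the femoral surface and per-frame patellar centroids
#' in it, fits the centroid trajectory over flexion, and solves the
#' constrained program that minimizes the variance of the modeled MPFL
#' length subject to the attachment lying on the femoral surface within the
#' `r_min`-`r_max` annulus around the Schottle point. Length-change (MPFL%)
#' profiles for both the Schottle point and the fitted I-point are computed
#' on the same motion.
#'
#' @param sequence a [knee_sequence()].
#' @param landmarks a [landmark_set()] (scanner coordinates, mm).
#' @param r_min,r_max annulus radii (mm, defaults 5 and 15).
#' @param eps_surf surface tolerance during iterations (mm, default 0.1).
#' @param degree trajectory polynomial degree (default 3).
#' @param reference reference-length rule for MPFL% (see [mpfl_percent()]).
#' @param n_starts multi-start seeds for the SQP driver (default 10).
#' @param ... further arguments to [sqp_solve()] (`tol_f`, `tol_kkt`,
#'   `max_iter`).
#' @return object of class `mpfl_fit` with components `frame`, `trajectory`,
#'   `problem`, `result` (the `ipoint_result`), `I_point` / `S_point` (local
#'   mm), `I_point_scanner`, `profile_I`, `profile_S`, and `call`.
#' @examples
#' spec <- synthetic_spec(n_frames = 12, mesh_density = 0.6)
#' fem <- make_femur(spec)
#' seq <- make_motion(spec, fem, seed = 1)
#' fit <- fit_ipoint(seq, fem$landmarks, n_starts = 4)
#' coef(fit)
#' @export
fit_ipoint <- function(sequence, landmarks, r_min = 5, r_max = 15,
                       eps_surf = 0.1, degree = 3L, reference = "mean",
                       n_starts = 10L, ...) {
  stopifnot(inherits(sequence, "knee_sequence"),
            inherits(landmarks, "landmark_set"))
  frame <- femoral_frame(landmarks)
  traj <- fit_trajectory(sequence, frame, degree = degree)
  surf_local <- surface_to_local(sequence$frames[[1L]]$femur, frame)
  s_local <- to_local(frame, landmarks$S_point)
  problem <- optimization_problem(traj$points, s_local, surf_local,
                                  r_min = r_min, r_max = r_max,
                                  eps_surf = eps_surf)
  result <- optimize_ipoint(problem, n_starts = n_starts, ...)
  structure(list(
    frame = frame,
    trajectory = traj,
    problem = problem,
    result = result,
    I_point = result$I_point,
    S_point = s_local,
    I_point_scanner = from_local(frame, result$I_point),
    profile_I = mpfl_profile(result$I_point, traj, reference = reference),
    profile_S = mpfl_profile(s_local, traj, reference = reference),
    subject_id = sequence$subject_id,
    side = sequence$side,
    call = match.call()),
    class = "mpfl_fit")
}

#' @export
print.mpfl_fit <- function(x, ...) {
  cat("Motion-informed femoral attachment fit - subject '", x$subject_id,
      "' (", x$side, ")\n", sep = "")
  cat("  I-point (local mm): ", paste(sprintf("%.2f", x$I_point),
                                      collapse = ", "), "\n", sep = "")
  cat("  S-point (local mm): ", paste(sprintf("%.2f", x$S_point),
                                      collapse = ", "), "\n", sep = "")
  cat("  |I - S| = ", sprintf("%.2f", vnorm(x$I_point - x$S_point)),
      " mm\n", sep = "")
  cat("  length SD: I ", sprintf("%.3f", x$result$length_sd), " mm vs S ",
      sprintf("%.3f", stats::sd(x$profile_S$lengths) *
                sqrt((length(x$profile_S$lengths) - 1) /
                       length(x$profile_S$lengths))), " mm\n", sep = "")
  invisible(x)
}

#' @export
coef.mpfl_fit <- function(object, space = c("local", "scanner"), ...) {
  space <- match.arg(space)
  p <- if (space == "local") object$I_point else object$I_point_scanner
  stats::setNames(as.numeric(p), c("X", "Y", "Z"))
}

#' @export
fitted.mpfl_fit <- function(object, ...) object$profile_I$lengths

#' @export
residuals.mpfl_fit <- function(object, ...) {
  object$profile_I$lengths - object$profile_I$reference
}

#' Predicted MPFL lengths on a flexion-angle grid
#'
#' Evaluates the fitted patellar trajectory at the requested angles and
#' returns the modeled ligament length and MPFL% for both attachments.
#'
#' @param object an [fit_ipoint()] result.
#' @param angles flexion angles in degrees (default 0, 10, ..., 90).
#' @param ... unused.
#' @return data frame with columns `angle`, `length_I`, `pct_I`,
#'   `length_S`, `pct_S`.
#' @export
predict.mpfl_fit <- function(object, angles = seq(0, 90, by = 10), ...) {
  cpts <- evaluate_trajectory(object$trajectory, angles)
  li <- sqrt(rowSums(sweep(cpts, 2L, object$I_point)^2))
  ls <- sqrt(rowSums(sweep(cpts, 2L, object$S_point)^2))
  data.frame(angle = angles,
             length_I = li,
             pct_I = 100 * (li - object$profile_I$reference) /
               object$profile_I$reference,
             length_S = ls,
             pct_S = 100 * (ls - object$profile_S$reference) /
               object$profile_S$reference)
}

#' @export
summary.mpfl_fit <- function(object, ...) {
  n <- length(object$profile_I$lengths)
  pop_sd <- function(v) stats::sd(v) * sqrt((n - 1) / n)
  out <- list(
    subject_id = object$subject_id,
    side = object$side,
    n_frames = n,
    I_point = object$I_point,
    S_point = object$S_point,
    separation = vnorm(object$I_point - object$S_point),
    mean_length_I = mean(object$profile_I$lengths),
    mean_length_S = mean(object$profile_S$lengths),
    sd_I = pop_sd(object$profile_I$lengths),
    sd_S = pop_sd(object$profile_S$lengths),
    range_I = max_variation(object$profile_I),
    range_S = max_variation(object$profile_S),
    binned = data.frame(angle = seq(0, 90, by = 10),
                        S_pct = unname(object$profile_S$binned),
                        I_pct = unname(object$profile_I$binned)),
    converged = object$result$converged,
    iterations = object$result$iterations,
    trajectory_rms = object$trajectory$rms_residual)
  class(out) <- "summary.mpfl_fit"
  out
}

#' @export
print.summary.mpfl_fit <- function(x, ...) {
  cat("Subject '", x$subject_id, "' (", x$side, "), ", x$n_frames,
      " frames\n", sep = "")
  cat(sprintf("  I-point: (%.2f, %.2f, %.2f) mm; |I - S| = %.2f mm\n",
              x$I_point[1L], x$I_point[2L], x$I_point[3L], x$separation))
  cat(sprintf("  mean length: I %.2f mm, S %.2f mm\n",
              x$mean_length_I, x$mean_length_S))
  cat(sprintf("  length SD:   I %.3f mm, S %.3f mm\n", x$sd_I, x$sd_S))
  cat(sprintf("  MPFL%% range: I [%.2f, %.2f], S [%.2f, %.2f]\n",
              x$range_I[1L], x$range_I[2L], x$range_S[1L], x$range_S[2L]))
  cat("  MPFL% per 10 deg bin:\n")
  bf <- x$binned
  bf$S_pct <- round(bf$S_pct, 3); bf$I_pct <- round(bf$I_pct, 3)
  print(bf, row.names = FALSE)
  cat("  optimizer:", if (x$converged) "converged" else "not converged",
      "in", x$iterations, "iterations; trajectory RMS",
      format(signif(x$trajectory_rms, 3)), "mm\n")
  invisible(x)
}

#' Plot MPFL% profiles of both attachments
#'
#' Per-frame MPFL% against flexion angle for the Schottle point and the
#' fitted I-point, with the binned means overlaid.
#'
#' @param x an `mpfl_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mpfl_fit <- function(x, ...) {
  ang <- x$trajectory$angles
  ps <- x$profile_S$percent
  pi_ <- x$profile_I$percent
  ylim <- range(ps, pi_, 0)
  graphics::plot(ang, ps, col = "firebrick", pch = 1,
                 xlab = "Flexion angle (deg)", ylab = "MPFL length change (%)",
                 ylim = ylim, ...)
  graphics::points(ang, pi_, col = "steelblue", pch = 2)
  ctr <- seq(0, 90, by = 10)
  graphics::lines(ctr, x$profile_S$binned, col = "firebrick", lwd = 2)
  graphics::lines(ctr, x$profile_I$binned, col = "steelblue", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", legend = c("S-point", "I-point"),
                   col = c("firebrick", "steelblue"), pch = c(1, 2),
                   lwd = 2, bty = "n")
  invisible(x)
}
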