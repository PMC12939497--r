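# Constrained search for the individualized femoral attachment (I-point):
# minimize the variance of the attachment-to-centroid distance over the
# motion frames, subject to the point lying on the femoral surface and
# within a 5-15 mm annulus around the Schottle point. Solved by sequential
# quadratic programming (damped BFGS Hessian, l1 merit line search,
# multi-start), with an exhaustive vertex scan as independent oracle.

#' Define the I-point optimization problem
#'
#' All geometry must be expressed in one coordinate system (conventionally
#' the local femoral frame).
#'
#' @param targets N x 3 matrix of per-frame patellar centroids (mm), N >= 2.
#' @param S_point length-3 Schottle point (mm).
#' @param surface femoral [surface_model()] in the same coordinates.
#' @param r_min,r_max annulus radii around the S-point (mm; default 5 and 15).
#' @param eps_surf surface-distance tolerance (mm): the on-surface equality
#'   is relaxed to `dist <= eps_surf` during iterations, with an exact
#'   projection at the end.
#' @param initial optional starting point; default is the best annulus
#'   vertex.
#' @return object of class `optimization_problem`.
#' @export
optimization_problem <- function(targets, S_point, surface,
                                 r_min = 5, r_max = 15, eps_surf = 0.1,
                                 initial = NULL) {
  stopifnot(inherits(surface, "surface_model"))
  targets <- as_points(targets)
  if (nrow(targets) < 2L) stop("need at least 2 target frames")
  S_point <- drop(as_points(S_point))
  if (!(r_min < r_max)) stop("r_min must be < r_max")
  rad <- sqrt(rowSums(sweep(surface$vertices, 2L, S_point)^2))
  in_annulus <- which(rad >= r_min - 1e-9 & rad <= r_max + 1e-9)
  if (length(in_annulus) == 0L) {
    stop("infeasible problem: no surface vertex lies in the ", r_min, "-",
         r_max, " mm annulus around the S-point")
  }
  # query subset: triangles with a vertex near the annulus, for fast
  # closest-point evaluation during iterations (solutions live there)
  near <- rad <= r_max + 8
  tri_keep <- which(near[surface$triangles[, 1L]] |
                    near[surface$triangles[, 2L]] |
                    near[surface$triangles[, 3L]])
  if (length(tri_keep) == 0L) tri_keep <- seq_len(nrow(surface$triangles))
  qsurf <- surface
  qsurf$triangles <- surface$triangles[tri_keep, , drop = FALSE]
  structure(list(targets = targets, S_point = S_point, surface = surface,
                 query_surface = qsurf, r_min = r_min, r_max = r_max,
                 eps_surf = eps_surf, initial = initial,
                 annulus_vertices = in_annulus),
            class = "optimization_problem")
}

#' Length-variability objective
#'
#' Population variance (mm^2) of the Euclidean distances from a candidate
#' femoral point to the per-frame patellar centroids; its square root is the
#' length standard deviation reported alongside.
#'
#' @param P candidate point (length-3, mm).
#' @param targets N x 3 centroid matrix (mm), N >= 2.
#' @return scalar mm^2.
#' @export
objective_f <- function(P, targets) {
  targets <- as_points(targets)
  if (nrow(targets) < 2L) stop("need at least 2 target frames")
  P <- drop(as_points(P))
  d <- sqrt(rowSums(sweep(targets, 2L, P)^2))
  mean(d^2) - mean(d)^2
}

objective_grad <- function(P, targets) {
  diffs <- sweep(-targets, 2L, P, "+")   # row i = P - C_i
  d <- sqrt(rowSums(diffs^2))
  u <- diffs / pmax(d, 1e-12)
  colSums((d - mean(d)) * u) * (2 / nrow(targets))
}

#' Constraint values
#'
#' Returns `c(g1, g2, g3)` with `g1 = r_min - |P - S|`,
#' `g2 = |P - S| - r_max`, `g3 = dist_to_surface(P) - eps_surf`; the point
#' is feasible iff all are `<= 0`.
#'
#' @param P candidate point (length-3, mm).
#' @param problem an [optimization_problem()].
#' @return numeric length-3 vector (mm).
#' @export
constraints_g <- function(P, problem) {
  P <- drop(as_points(P))
  r <- vnorm(P - problem$S_point)
  ds <- dist_to_surface(problem$query_surface, P)
  c(problem$r_min - r, r - problem$r_max, ds - problem$eps_surf)
}

# Constraint Jacobian (rows = constraints). The surface-distance gradient is
# the unit vector away from the closest point (analytic per closest-triangle
# region); central finite differences take over on the surface itself where
# that gradient is undefined.
constraints_jac <- function(P, problem, proj = NULL) {
  u_s <- P - problem$S_point
  r <- vnorm(u_s)
  u_s <- if (r > 1e-12) u_s / r else c(1, 0, 0)
  if (is.null(proj)) proj <- project_to_surface(problem$query_surface, P)
  if (proj$distance > 1e-7) {
    gd <- (P - proj$point) / proj$distance
  } else {
    h <- 1e-5
    gd <- vapply(1:3, function(k) {
      e <- c(0, 0, 0); e[k] <- h
      (dist_to_surface(problem$query_surface, P + e) -
       dist_to_surface(problem$query_surface, P - e)) / (2 * h)
    }, numeric(1L))
  }
  rbind(-u_s, u_s, gd)
}

#' Exhaustive vertex-scan oracle
#'
#' Evaluates the objective at every surface vertex inside the annulus and
#' returns the minimizer. Deterministic tie-break: smaller objective, then
#' smaller distance to the S-point, then lexicographic coordinates.
#'
#' @param problem an [optimization_problem()].
#' @return list with `point`, `f` (mm^2), and `vertex` (index).
#' @export
brute_force_ipoint <- function(problem) {
  V <- problem$surface$vertices[problem$annulus_vertices, , drop = FALSE]
  tg <- problem$targets
  d2 <- outer(rowSums(V^2), rowSums(tg^2), "+") - 2 * V %*% t(tg)
  D <- sqrt(pmax(d2, 0))
  f <- rowMeans(D^2) - rowMeans(D)^2
  rs <- sqrt(rowSums(sweep(V, 2L, problem$S_point)^2))
  ord <- order(f, rs, V[, 1L], V[, 2L], V[, 3L])
  i <- ord[1L]
  list(point = V[i, ], f = f[i],
       vertex = problem$annulus_vertices[i])
}

#' Multi-start seed points
#'
#' The `k` annulus vertices with the lowest objective values, plus the
#' surface projection of the S-point when it is itself feasible,
#' deduplicated. These are the SQP starting points.
#'
#' @param problem an [optimization_problem()].
#' @param k number of seeds.
#' @return m x 3 matrix of starting points (m <= k + 1).
#' @export
seed_candidates <- function(problem, k = 10L) {
  V <- problem$surface$vertices[problem$annulus_vertices, , drop = FALSE]
  tg <- problem$targets
  d2 <- outer(rowSums(V^2), rowSums(tg^2), "+") - 2 * V %*% t(tg)
  D <- sqrt(pmax(d2, 0))
  f <- rowMeans(D^2) - rowMeans(D)^2
  rs <- sqrt(rowSums(sweep(V, 2L, problem$S_point)^2))
  ord <- order(f, rs, V[, 1L], V[, 2L], V[, 3L])
  seeds <- V[ord[seq_len(min(k, nrow(V)))], , drop = FALSE]
  ps <- project_to_surface(problem$query_surface, problem$S_point)$point
  rps <- vnorm(ps - problem$S_point)
  if (rps >= problem$r_min && rps <= problem$r_max) {
    seeds <- rbind(seeds, ps)
  }
  if (nrow(seeds) > 1L) {
    keep <- !duplicated(round(seeds, 9L))
    seeds <- seeds[keep, , drop = FALSE]
  }
  seeds
}

#' Solve the I-point program by SQP from one starting point
#'
#' At each iterate a quadratic subproblem (damped-BFGS model Hessian,
#' linearized constraints) is solved with `quadprog`, the step is accepted
#' by backtracking on an l1 merit function, and multipliers come from the
#' subproblem. Iterations stop when the objective change is below `tol_f`
#' and the KKT residual below `tol_kkt`, or at `max_iter`. The final iterate
#' is projected exactly onto the surface (alternating with a radial clamp
#' into the annulus) and feasibility is re-checked.
#'
#' @param problem an [optimization_problem()].
#' @param initial starting point; default `problem$initial`, else the best
#'   annulus vertex.
#' @param tol_f objective-change tolerance (mm^2).
#' @param tol_kkt KKT residual tolerance.
#' @param max_iter iteration cap.
#' @return list: `I_point`, `f` (mm^2), `length_sd` (mm), `mean_length`
#'   (mm), `iterations`, `converged`, `max_violation` (mm).
#' @export
sqp_solve <- function(problem, initial = NULL, tol_f = 1e-10,
                      tol_kkt = 1e-6, max_iter = 200L) {
  stopifnot(inherits(problem, "optimization_problem"))
  x <- if (!is.null(initial)) drop(as_points(initial))
       else if (!is.null(problem$initial)) drop(as_points(problem$initial))
       else brute_force_ipoint(problem)$point
  tg <- problem$targets
  H <- diag(3)
  mu <- 10
  lambda <- rep(0, 3L)
  f <- objective_f(x, tg)
  g <- constraints_g(x, problem)
  gf <- objective_grad(x, tg)
  J <- constraints_jac(x, problem)
  converged <- FALSE
  it <- 0L
  step_cap <- 0.25 * (problem$r_max - problem$r_min) + 1

  merit <- function(p) {
    objective_f(p, tg) + mu * sum(pmax(constraints_g(p, problem), 0))
  }

  while (it < max_iter) {
    it <- it + 1L
    qp <- tryCatch(
      quadprog::solve.QP(Dmat = H, dvec = -gf, Amat = t(-J), bvec = g),
      error = function(e) NULL)
    if (is.null(qp)) {
      # relaxed subproblem: do not ask for more feasibility than we have
      qp <- tryCatch(
        quadprog::solve.QP(Dmat = H, dvec = -gf, Amat = t(-J),
                           bvec = pmin(g, 0)),
        error = function(e) NULL)
    }
    if (is.null(qp)) {
      delta <- -solve(H, gf)
      lambda_new <- lambda
    } else {
      delta <- qp$solution
      lambda_new <- pmax(qp$Lagrangian, 0)
    }
    nd <- vnorm(delta)
    if (nd > step_cap) delta <- delta * (step_cap / nd)
    if (nd < 1e-12) {
      converged <- TRUE
      break
    }
    mu <- max(mu, 2 * max(lambda_new) + 1)
    pred <- sum(gf * delta) - mu * sum(pmax(g, 0))
    phi0 <- f + mu * sum(pmax(g, 0))
    alpha <- 1
    x_new <- x
    accepted <- FALSE
    while (alpha > 1e-8) {
      cand <- x + alpha * delta
      if (merit(cand) <= phi0 + 0.1 * alpha * min(pred, 0) + 1e-14) {
        x_new <- cand
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      converged <- TRUE  # no merit descent available: stationary
      break
    }
    f_new <- objective_f(x_new, tg)
    g_new <- constraints_g(x_new, problem)
    gf_new <- objective_grad(x_new, tg)
    J_new <- constraints_jac(x_new, problem)

    # damped BFGS on the Lagrangian gradient (keeps H positive definite)
    s <- x_new - x
    yv <- (gf_new + drop(t(J_new) %*% lambda_new)) -
          (gf + drop(t(J) %*% lambda_new))
    Hs <- drop(H %*% s)
    sHs <- sum(s * Hs)
    sy <- sum(s * yv)
    if (sHs > 1e-16) {
      if (sy < 0.2 * sHs) {
        th <- 0.8 * sHs / (sHs - sy)
        yv <- th * yv + (1 - th) * Hs
        sy <- sum(s * yv)
      }
      if (sy > 1e-16) {
        H <- H - tcrossprod(Hs) / sHs + tcrossprod(yv) / sy
        H <- (H + t(H)) / 2
      }
    }

    kkt <- max(max(abs(gf_new + drop(t(J_new) %*% lambda_new))),
               max(0, max(g_new)),
               max(lambda_new * abs(g_new)))
    dfv <- abs(f_new - f)
    x <- x_new; f <- f_new; g <- g_new; gf <- gf_new; J <- J_new
    lambda <- lambda_new
    if (dfv < tol_f && kkt < tol_kkt) {
      converged <- TRUE
      break
    }
  }

  x <- restore_feasibility(x, problem)
  f <- objective_f(x, tg)
  g <- constraints_g(x, problem)
  d <- sqrt(rowSums(sweep(tg, 2L, x)^2))
  list(I_point = x, f = f, length_sd = sqrt(max(f, 0)),
       mean_length = mean(d), iterations = it, converged = converged,
       max_violation = max(0, g[1L], g[2L],
                           dist_to_surface(problem$query_surface, x)))
}

# Exact surface projection alternated with a radial clamp into the annulus.
restore_feasibility <- function(x, problem, iters = 25L) {
  for (i in seq_len(iters)) {
    x <- project_to_surface(problem$query_surface, x)$point
    r <- vnorm(x - problem$S_point)
    if (r >= problem$r_min - 1e-9 && r <= problem$r_max + 1e-9) break
    target_r <- min(max(r, problem$r_min + 1e-7), problem$r_max - 1e-7)
    if (r > 1e-12) {
      x <- problem$S_point + (x - problem$S_point) * (target_r / r)
    } else {
      x <- problem$S_point + c(target_r, 0, 0)
    }
  }
  x
}

#' Find the I-point (multi-start driver)
#'
#' Runs [sqp_solve()] from each [seed_candidates()] start and returns the
#' best feasible solution; the feasible seeds themselves remain candidates,
#' so the result can never be worse than the best annulus vertex. Ties are
#' broken by distance to the S-point, then lexicographically.
#'
#' @param problem an [optimization_problem()].
#' @param n_starts number of multi-start seeds (default 10).
#' @param ... passed to [sqp_solve()].
#' @return object of class `ipoint_result`: fields of [sqp_solve()] plus
#'   `seeds_evaluated` and `S_point`.
#' @export
optimize_ipoint <- function(problem, n_starts = 10L, ...) {
  seeds <- seed_candidates(problem, k = n_starts)
  best <- NULL
  tol_feas <- 1e-6
  consider <- function(res) {
    r <- vnorm(res$I_point - problem$S_point)
    feas <- r >= problem$r_min - tol_feas && r <= problem$r_max + tol_feas &&
      dist_to_surface(problem$query_surface, res$I_point) <=
        problem$eps_surf + tol_feas
    if (!feas) return()
    if (is.null(best) || res$f < best$f - 1e-15 ||
        (abs(res$f - best$f) <= 1e-15 &&
         r < vnorm(best$I_point - problem$S_point))) {
      best <<- res
    }
  }
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    d <- sqrt(rowSums(sweep(problem$targets, 2L, s)^2))
    consider(list(I_point = s, f = objective_f(s, problem$targets),
                  length_sd = NA_real_, mean_length = mean(d),
                  iterations = 0L, converged = TRUE, max_violation = 0))
    consider(sqp_solve(problem, initial = s, ...))
  }
  if (is.null(best)) stop("no feasible solution found")
  # polish: restart from the incumbent with a fresh Hessian until the
  # objective stops improving (guards against premature line-search exits)
  for (k in 1:3) {
    f_before <- best$f
    consider(sqp_solve(problem, initial = best$I_point, ...))
    if (best$f >= f_before - 1e-14) break
  }
  best$length_sd <- sqrt(max(best$f, 0))
  best$seeds_evaluated <- nrow(seeds)
  best$S_point <- problem$S_point
  class(best) <- "ipoint_result"
  best
}

#' @export
print.ipoint_result <- function(x, ...) {
  cat("I-point search result\n")
  cat("  I-point (mm):", format(round(x$I_point, 3)), "\n")
  cat("  length SD:", format(signif(x$length_sd, 4)), "mm  (objective",
      format(signif(x$f, 4)), "mm^2)\n")
  cat("  mean length:", format(round(x$mean_length, 2)), "mm\n")
  cat("  |I - S|:", format(round(vnorm(x$I_point - x$S_point), 2)),
      "mm;", x$seeds_evaluated, "starts;",
      if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}
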