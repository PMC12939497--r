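small_problem <- function(seed = 1, sigma = 0, n_frames = 15) {
  spec <- random_synthetic_spec(seed, sigma = sigma, n_frames = n_frames,
                                mesh_density = 0.8)
  femur <- make_femur(spec)
  seqq <- make_motion(spec, femur, seed = seed + 999)
  frame <- femoral_frame(femur$landmarks)
  traj <- fit_trajectory(seqq, frame)
  surf <- femur$surface
  surf$vertices <- to_local(frame, surf$vertices)
  prob <- optimization_problem(traj$points, to_local(frame,
                                                     femur$landmarks$S_point),
                               surf)
  list(problem = prob, p_star = to_local(frame, femur$P_star),
       frame = frame)
}

test_that("objective is the population variance of attachment distances", {
  expect_equal(objective_f(c(0, 0, 0), rbind(c(1, 0, 0), c(3, 0, 0))), 1.0)
  set.seed(4)
  u <- matrix(rnorm(60), ncol = 3); u <- 7 * u / sqrt(rowSums(u^2))
  ctr <- c(3, -2, 5)
  expect_equal(objective_f(ctr, sweep(u, 2, ctr, "+")), 0, tolerance = 1e-18)
  expect_error(objective_f(c(0, 0, 0), matrix(c(1, 0, 0), 1)), "at least 2")
  # rigid invariance of the objective
  tg <- matrix(rnorm(45, sd = 20), ncol = 3)
  p <- rnorm(3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(4, -8, 2)
  expect_equal(objective_f(drop(R %*% p) + shift,
                           sweep(tg %*% t(R), 2, shift, "+")),
               objective_f(p, tg), tolerance = 1e-10)
})

test_that("objective gradient matches finite differences", {
  set.seed(6)
  tg <- matrix(rnorm(30, sd = 15), ncol = 3)
  p <- c(25, 3, -4)
  g <- mpflopt:::objective_grad(p, tg)
  h <- 1e-6
  fd <- vapply(1:3, function(k) {
    e <- c(0, 0, 0); e[k] <- h
    (objective_f(p + e, tg) - objective_f(p - e, tg)) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("constraint values encode the annulus and surface conditions", {
  sp <- small_problem(3)
  prob <- sp$problem
  g_center <- constraints_g(prob$S_point, prob)
  expect_equal(g_center[1], prob$r_min)       # infeasible at the center
  expect_gt(g_center[1], 0)
  # a point exactly mid-annulus on the surface
  v <- prob$surface$vertices
  r <- sqrt(rowSums(sweep(v, 2, prob$S_point)^2))
  i <- which.min(abs(r - 10))
  g_mid <- constraints_g(v[i, ], prob)
  expect_equal(g_mid[1], prob$r_min - r[i])
  expect_equal(g_mid[2], r[i] - prob$r_max)
  expect_equal(g_mid[3], -prob$eps_surf, tolerance = 1e-9)
  # boundary activation at exactly r_max
  dir <- c(1, 0, 0)
  g_b <- constraints_g(prob$S_point + prob$r_max * dir, prob)
  expect_equal(g_b[2], 0, tolerance = 1e-12)
})

test_that("brute force returns the annulus-vertex minimizer", {
  tg <- rbind(c(0, 0, 10), c(0, 0, -10), c(0, 10, 0), c(0, -10, 0))
  # two candidate vertices: A equidistant-ish, B worse; hand-computed f
  vA <- c(8, 0, 0)    # distances all sqrt(164): f = 0
  vB <- c(6, 0, 2)    # mixed distances
  surf <- surface_model(rbind(vA, vB, c(7, 1, 0), c(7, -1, 0)),
                        rbind(c(1, 2, 3), c(1, 2, 4)))
  prob <- optimization_problem(tg, c(0, 0, 0), surf, r_min = 5, r_max = 15,
                               eps_surf = 0.5)
  bf <- brute_force_ipoint(prob)
  expect_equal(bf$point, vA, ignore_attr = TRUE)
  expect_equal(bf$f, 0, tolerance = 1e-12)
  dB <- sqrt(rowSums(sweep(tg, 2, vB)^2))
  expect_equal(objective_f(vB, tg), mean(dB^2) - mean(dB)^2)
  expect_error(optimization_problem(tg, c(500, 0, 0), surf), "infeasible")
})

test_that("seed candidates are the best annulus vertices, clamped and deduped", {
  sp <- small_problem(4)
  prob <- sp$problem
  s1 <- seed_candidates(prob, k = 1)
  bf <- brute_force_ipoint(prob)
  expect_equal(s1[1, ], bf$point, ignore_attr = TRUE)
  huge <- seed_candidates(prob, k = 1e6)
  expect_lte(nrow(huge), length(prob$annulus_vertices) + 1L)
  expect_false(any(duplicated(round(huge, 9))))
})

test_that("planted isometric optimum is recovered by the SQP driver", {
  sp <- small_problem(7)
  res <- optimize_ipoint(sp$problem, n_starts = 6)
  expect_lt(sqrt(sum((res$I_point - sp$p_star)^2)), 0.5)
  expect_lt(res$f, 1e-6)
  expect_true(res$converged)
  r <- sqrt(sum((res$I_point - sp$problem$S_point)^2))
  expect_gte(r, sp$problem$r_min - 1e-6)
  expect_lte(r, sp$problem$r_max + 1e-6)
  expect_lte(res$max_violation, sp$problem$eps_surf + 1e-6)
})

test_that("solver never loses to the vertex oracle and restarts are stable", {
  for (s in c(12, 13)) {
    sp <- small_problem(s, sigma = 0.4)
    res <- optimize_ipoint(sp$problem, n_starts = 6)
    bf <- brute_force_ipoint(sp$problem)
    expect_lte(res$f, bf$f + 1e-9)
    res2 <- sqp_solve(sp$problem, initial = res$I_point)
    expect_lt(abs(res2$f - res$f), 1e-8)
  }
})

test_that("multi-start never degrades with more seeds", {
  sp <- small_problem(17, sigma = 0.3)
  f1 <- optimize_ipoint(sp$problem, n_starts = 1)$f
  f5 <- optimize_ipoint(sp$problem, n_starts = 5)$f
  expect_lte(f5, f1 + 1e-12)
})

test_that("recovered length SD tracks the planted radial noise", {
  set.seed(40)
  sds <- vapply(1:10, function(s) {
    sp <- small_problem(s + 100, sigma = 0.3, n_frames = 25)
    optimize_ipoint(sp$problem, n_starts = 4)$length_sd
  }, numeric(1))
  expect_true(all(sds >= 0.5 * 0.3 & sds <= 1.5 * 0.3))
})

test_that("whole-problem rigid motion leaves the optimum value unchanged", {
  sp <- small_problem(23, sigma = 0.2)
  prob <- sp$problem
  res1 <- optimize_ipoint(prob, n_starts = 4)
  th <- 0.9
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- c(12, -7, 30)
  surf2 <- prob$surface
  surf2$vertices <- sweep(surf2$vertices %*% t(R), 2, shift, "+")
  prob2 <- optimization_problem(sweep(prob$targets %*% t(R), 2, shift, "+"),
                                drop(R %*% prob$S_point) + shift, surf2,
                                r_min = prob$r_min, r_max = prob$r_max,
                                eps_surf = prob$eps_surf)
  res2 <- optimize_ipoint(prob2, n_starts = 4)
  expect_equal(res2$f, res1$f, tolerance = 1e-6)
})
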