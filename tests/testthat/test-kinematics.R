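# helpers: a sequence whose centroids follow a known per-coordinate cubic
make_poly_sequence <- function(angles, coefs, noise_sd = 0, seed = NULL,
                               femur = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(femur)) {
    femur <- surface_model(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0),
                                 c(0, 0, 50)),
                           rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4),
                                 c(2, 3, 4)))
  }
  frames <- lapply(seq_along(angles), function(i) {
    th <- angles[i]
    c_i <- vapply(1:3, function(j) sum(coefs[, j] * th^(0:3)), numeric(1))
    if (noise_sd > 0) c_i <- c_i + rnorm(3, sd = noise_sd)
    cloud <- matrix(rnorm(30, sd = 2), ncol = 3)
    cloud <- sweep(cloud, 2, colMeans(cloud))          # exactly zero-mean
    frame_data(i, femur, sweep(cloud, 2, c_i, "+"), flexion_angle = th)
  })
  knee_sequence("poly", "right", frames)
}

id_frame <- function() {
  femoral_frame(landmark_set(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 10),
                             c(0, 0, 0)))
}

test_that("patellar centroid is the arithmetic mean, with optional mask", {
  expect_equal(patellar_centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(patellar_centroid(c(3, -1, 2)), c(3, -1, 2))
  expect_error(patellar_centroid(matrix(numeric(0), ncol = 3)), "empty")
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(100, 100, 100))
  expect_equal(patellar_centroid(pts, mask = c(TRUE, TRUE, FALSE)),
               c(1, 0, 0))
})

test_that("centroid of uniform sphere samples recovers the center", {
  set.seed(2)
  n <- 1e4
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ctr <- c(5, -3, 8)
  got <- patellar_centroid(sweep(u, 2, ctr, "+"))
  expect_lt(max(abs(got - ctr)), 3 / sqrt(n / 3) * 1.2)  # ~3 sigma
})

test_that("exact cubic data is interpolated with vanishing residual", {
  coefs <- cbind(c(30, 0.2, -0.003, 1e-5), c(-5, 0.1, 0, -2e-5),
                 c(10, 0.5, -0.004, 2e-5))
  seqq <- make_poly_sequence(seq(0, 90, length.out = 20), coefs)
  tr <- fit_trajectory(seqq, id_frame(), degree = 3)
  expect_lt(tr$rms_residual, 1e-9)
  # coefficient recovery checked through evaluation on a fresh grid
  got <- evaluate_trajectory(tr, c(15, 42.5, 77))
  want <- t(vapply(c(15, 42.5, 77), function(th) {
    vapply(1:3, function(j) sum(coefs[, j] * th^(0:3)), numeric(1))
  }, numeric(3)))
  expect_equal(unname(got), unname(want), tolerance = 1e-8)
})

test_that("underdetermined fits are rejected", {
  coefs <- cbind(c(30, 0.2, 0, 0), c(-5, 0.1, 0, 0), c(10, 0.5, 0, 0))
  seqq <- make_poly_sequence(c(0, 45, 90), coefs)
  expect_error(fit_trajectory(seqq, id_frame(), degree = 3), "more frames")
})

test_that("noisy cubic residuals sit at the noise level", {
  coefs <- cbind(c(30, 0.2, -0.003, 1e-5), c(-5, 0.1, 0, -2e-5),
                 c(10, 0.5, -0.004, 2e-5))
  set.seed(31)
  for (k in 1:100) {
    seqq <- make_poly_sequence(seq(0, 90, length.out = 25), coefs,
                               noise_sd = 0.2)
    tr <- fit_trajectory(seqq, id_frame(), degree = 3)
    expect_gt(tr$rms_residual, 0.1)
    expect_lt(tr$rms_residual, 0.4)
  }
})

test_that("fitting commutes with rigid re-expression", {
  coefs <- cbind(c(30, 0.2, -0.003, 1e-5), c(-5, 0.1, 0, -2e-5),
                 c(10, 0.5, -0.004, 2e-5))
  seqq <- make_poly_sequence(seq(0, 90, length.out = 18), coefs,
                             noise_sd = 0.1, seed = 8)
  set.seed(9)
  lmA <- random_landmarks(); lmB <- random_landmarks()
  frA <- femoral_frame(lmA); frB <- femoral_frame(lmB)
  trA <- fit_trajectory(seqq, frA)
  trB <- fit_trajectory(seqq, frB)
  grid <- c(10, 30, 50, 80)
  inB_via_A <- to_local(frB, from_local(frA, evaluate_trajectory(trA, grid)))
  expect_equal(unname(inB_via_A), unname(evaluate_trajectory(trB, grid)),
               tolerance = 1e-6)
})

test_that("residual is non-increasing in polynomial degree", {
  coefs <- cbind(c(30, 0.2, -0.003, 1e-5), c(-5, 0.1, 0, -2e-5),
                 c(10, 0.5, -0.004, 2e-5))
  seqq <- make_poly_sequence(seq(0, 90, length.out = 22), coefs,
                             noise_sd = 0.3, seed = 12)
  fr <- id_frame()
  res <- vapply(1:5, function(d) {
    fit_trajectory(seqq, fr, degree = d)$rms_residual
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("trajectory evaluation handles linear and constant content", {
  coefs <- cbind(c(10, 0.5, 0, 0), c(0, -0.2, 0, 0), c(5, 0, 0, 0))
  seqq <- make_poly_sequence(seq(0, 90, length.out = 10), coefs)
  tr <- fit_trajectory(seqq, id_frame(), degree = 1)
  p20 <- evaluate_trajectory(tr, 20)
  p40 <- evaluate_trajectory(tr, 40)
  p30 <- evaluate_trajectory(tr, 30)
  expect_equal(unname((p20 + p40) / 2), unname(p30), tolerance = 1e-9)
  expect_warning(evaluate_trajectory(tr, 120), "outside")
})

test_that("non-monotone flexion angles fall back to index parameterization", {
  coefs <- cbind(c(30, 0.2, 0, 0), c(-5, 0.1, 0, 0), c(10, 0.5, 0, 0))
  femur <- surface_model(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0),
                               c(0, 0, 50)),
                         rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4),
                               c(2, 3, 4)))
  frames <- lapply(1:8, function(i) {
    frame_data(i, femur, matrix(rnorm(30, sd = 2), ncol = 3) + 40,
               flexion_angle = c(0, 20, 10, 30, 40, 50, 70, 60)[i])
  })
  seqq <- knee_sequence("nm", "right", frames)
  expect_warning(tr <- fit_trajectory(seqq, id_frame()), "not monotone")
  expect_false(tr$param_is_angle)
  expect_true(all(tr$angles >= 0 & tr$angles <= 90))
})
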