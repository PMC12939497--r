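test_that("permanova pseudo-F matches hand computation and full enumeration", {
  A <- matrix(c(0, 0.1), ncol = 1)
  B <- matrix(c(10, 10.1), ncol = 1)
  res <- permanova(A, B, exhaustive = TRUE)
  # hand: SS_total = 400.04/4 = 100.01, SS_within = 0.005 + 0.005,
  # F = (100.01 - 0.01) / (0.01 / 2) = 20000
  expect_equal(res$pseudo_F, 20000, tolerance = 1e-9)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$n_permutations, 6L)
})

test_that("permanova agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  A <- matrix(rnorm(36), ncol = 3)
  B <- matrix(rnorm(45, mean = 0.8), ncol = 3)
  mine <- permanova(A, B, n_perm = 99, seed = 5)
  df <- data.frame(g = c(rep("a", nrow(A)), rep("b", nrow(B))))
  ref <- vegan::adonis2(rbind(A, B) ~ g, data = df, permutations = 99,
                        method = "euclidean")
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("permanova is rigid-motion invariant and seed-reproducible", {
  set.seed(3)
  A <- matrix(rnorm(30), ncol = 3)
  B <- matrix(rnorm(30, 1), ncol = 3)
  r1 <- permanova(A, B, n_perm = 199, seed = 42)
  shift <- c(5, -2, 9)
  r2 <- permanova(sweep(A, 2, shift, "+"), sweep(B, 2, shift, "+"),
                  n_perm = 199, seed = 42)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-10)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- permanova(A, B, n_perm = 199, seed = 42)
  expect_identical(r1$p_value, r3$p_value)
  expect_error(permanova(matrix(1), matrix(1:2)), "at least 2")
})

test_that("axis partitioning reproduces the published proximal-shift share", {
  m <- reference_point_means()
  share <- axis_contribution(m$S, m$I)
  expect_equal(sum(share), 1, tolerance = 1e-12)
  expect_true(all(share >= 0))
  expect_equal(round(100 * unname(share["Z"]), 1), 95.1)
  expect_equal(unname(share), c(0.0389, 0.0097, 0.9514), tolerance = 5e-4)
  expect_equal(unname(axis_contribution(c(0, 0, 0), c(0, 0, 2))), c(0, 0, 1))
  expect_error(axis_contribution(c(1, 2, 3), c(1, 2, 3)), "identical")
})

test_that("signed-rank exact p matches direct 2^n enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p_value, 0.25)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$statistic, 6)
  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p_value, 1.0)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
  set.seed(77)
  for (k in 1:30) {
    n <- sample(3:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties guaranteed
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, enum_signrank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank exact and approximate p agree at the switchover", {
  set.seed(15)
  for (k in 1:10) {
    d <- rnorm(30, mean = 0.4)
    p_exact <- wilcoxon_signed_rank(d, exact_max = 30)$p_value
    p_approx <- wilcoxon_signed_rank(d, exact_max = 25)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
  # tie-free exact case cross-checked against the standard routine
  set.seed(16)
  x <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(x)$p_value,
               wilcox.test(x, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("classical MDS embeds planar clouds exactly", {
  set.seed(8)
  X2 <- cbind(rnorm(12), rnorm(12))
  emb <- mds_embedding(cbind(X2, 0 * X2[, 1]), dims = 2)
  expect_lt(max(abs(dist(emb) - dist(X2))), 1e-9)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  e3 <- mds_embedding(tri, dims = 2)
  expect_equal(as.numeric(dist(e3)), rep(1, 3), tolerance = 1e-9)
  # stress is non-increasing with embedding dimension
  X3 <- matrix(rnorm(60), ncol = 3)
  stress <- vapply(1:3, function(k) {
    sqrt(sum((dist(mds_embedding(X3, dims = k)) - dist(X3))^2))
  }, numeric(1))
  expect_true(all(diff(stress) <= 1e-9))
  expect_error(mds_embedding(X3[1:2, ]), "at least 3")
})

test_that("kernel density integrates to one and matches the normal at 0", {
  set.seed(23)
  v <- rnorm(1e4)
  k <- kde_1d(v)
  integral <- sum(diff(k$x) * (head(k$y, -1) + tail(k$y, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_true(all(k$y >= 0))
  at0 <- k$y[which.min(abs(k$x))]
  expect_lt(abs(at0 - dnorm(0)) / dnorm(0), 0.15)
  expect_error(kde_1d(rep(3, 10)), "zero-variance")
  k2 <- kde_1d(c(2, 2), bandwidth = 0.5)
  expect_equal(k2$x[which.max(k2$y)], 2, tolerance = 0.05)
})

test_that("normality gate has power on uniform and holds level on normal", {
  set.seed(12)
  rej_u <- mean(vapply(1:200, function(i) {
    normality_check(runif(100))$p_value < 0.05
  }, logical(1)))
  expect_gte(rej_u, 0.9)
  rej_n <- mean(vapply(1:200, function(i) {
    normality_check(rnorm(100))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej_n - 0.05), 0.03)
  expect_error(normality_check(rep(1, 10)), "degenerate")
  expect_error(normality_check(1:2), "3 <= n")
})

test_that("cohort summary pairs coordinates, angles, and the PERMANOVA", {
  cohort <- make_cohort(n_subjects = 40, seed = 6)
  ang <- seq(0, 90, by = 10)
  for (k in seq_along(ang)) {
    cohort[[paste0("S_pct_", ang[k])]] <- rnorm(40, mean = -2 + 0.05 * ang[k])
    cohort[[paste0("I_pct_", ang[k])]] <- rnorm(40, mean = -0.5 + 0.01 * ang[k])
  }
  sm <- cohort_summary(cohort, n_perm = 99, seed = 2)
  expect_s3_class(sm, "cohort_summary")
  expect_equal(nrow(sm$coordinates), 3L)
  expect_equal(sm$coordinates$S_mean, colMeans(as.matrix(
    cohort[, c("Sx", "Sy", "Sz")])), ignore_attr = TRUE)
  expect_equal(nrow(sm$angles), 10L)
  expect_true(all(sm$angles$p >= 0 & sm$angles$p <= 1))
  expect_s3_class(sm$permanova, "permanova_result")
  expect_equal(sum(sm$axis_share), 1)
  expect_output(print(sm), "PERMANOVA")
  expect_error(cohort_table(data.frame(subject_id = "a", Sx = 1)),
               "missing columns")
})
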