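test_that("femoral frame axes follow the anatomical conventions", {
  lm_r <- landmark_set(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 10), c(0.5, 0, 0.2),
                       side = "right")
  fr <- femoral_frame(lm_r)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(unname(fr$rotation["X", ]), c(1, 0, 0))
  expect_equal(unname(fr$rotation["Z", ]), c(0, 0, 1))
  expect_equal(unname(fr$rotation["Y", ]), c(0, 1, 0))

  lm_l <- landmark_set(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 10), c(0.5, 0, 0.2),
                       side = "left")
  fl <- femoral_frame(lm_l)
  expect_equal(unname(fl$rotation["X", ]), c(-1, 0, 0))
  expect_equal(unname(fl$rotation["Z", ]), c(0, 0, 1))
  expect_equal(unname(fl$rotation["Y", ]), c(0, -1, 0))
  expect_equal(det(fl$rotation), 1)

  lm3 <- landmark_set(c(2, 1, 0), c(0, 1, 0), c(1, 1, 5), c(1.5, 1, 1))
  f3 <- femoral_frame(lm3)
  expect_equal(f3$origin, c(1, 1, 0))
  expect_equal(t(f3$rotation) %*% f3$rotation, diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate landmark configurations are rejected", {
  expect_error(landmark_set(c(1, 0, 0), c(1, 0, 0), c(0, 0, 5), c(0, 0, 0)),
               "coincide")
  lm <- landmark_set(c(1, 0, 0), c(-1, 0, 0), c(3, 0, 0), c(0, 0, 0))
  expect_error(femoral_frame(lm), "collinear")
})

test_that("random frames are orthonormal, right-handed, origin-exact", {
  set.seed(11)
  for (i in 1:200) {
    lm <- random_landmarks()
    fr <- femoral_frame(lm)
    expect_lt(max(abs(t(fr$rotation) %*% fr$rotation - diag(3))), 1e-12)
    expect_equal(det(fr$rotation), 1, tolerance = 1e-10)
    expect_identical(fr$origin, (lm$MFC + lm$LFC) / 2)
  }
})

test_that("to_local/from_local is an exact rigid round trip", {
  set.seed(7)
  lm <- random_landmarks()
  fr <- femoral_frame(lm)
  expect_equal(to_local(fr, fr$origin), c(X = 0, Y = 0, Z = 0))
  pts <- matrix(rnorm(300, sd = 50), ncol = 3)
  back <- from_local(fr, to_local(fr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  a <- pts[1, ]; b <- pts[2, ]
  expect_equal(sqrt(sum((to_local(fr, a) - to_local(fr, b))^2)),
               sqrt(sum((a - b)^2)))
  d_orig <- as.matrix(dist(pts))
  d_loc <- as.matrix(dist(to_local(fr, pts)))
  expect_lt(max(abs(d_orig - d_loc)), 1e-9)
})

test_that("left/right mirroring preserves proximal-distal coordinates", {
  set.seed(21)
  for (i in 1:20) {
    lm <- random_landmarks()
    mirror <- function(p) c(-p[1], p[2], p[3])
    lm_m <- landmark_set(mirror(lm$MFC), mirror(lm$LFC), mirror(lm$RA),
                         mirror(lm$S_point),
                         side = if (lm$side == "right") "left" else "right")
    z1 <- to_local(femoral_frame(lm), lm$S_point)["Z"]
    z2 <- to_local(femoral_frame(lm_m), lm_m$S_point)["Z"]
    expect_equal(z1, z2, tolerance = 1e-9)
  }
})

test_that("alpha-shape surface of a sphere sample is closed with the right area", {
  set.seed(1)
  u <- matrix(rnorm(1500), ncol = 3)
  sph <- 20 * u / sqrt(rowSums(u^2))
  surf <- build_surface(sph, alpha = 10)
  expect_s3_class(surf, "surface_model")
  expect_identical(surf$provenance, "delaunay-derived")
  # closed orientable surface: T = 2V - 4 (Euler), every edge shared twice
  expect_equal(nrow(surf$triangles), 2L * nrow(surf$vertices) - 4L)
  expect_lt(abs(mesh_area(surf) - 4 * pi * 20^2) / (4 * pi * 20^2), 0.10)
})

test_that("tetrahedron and degenerate point clouds behave", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  st <- build_surface(tet, alpha = 10)
  expect_equal(nrow(st$triangles), 4L)
  coplanar <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 0))
  expect_error(build_surface(coplanar), "coplanar")
  expect_error(build_surface(tet[1:3, ]), "at least 4")
})

test_that("mesh pass-through cleans up degenerate triangles", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1e-9, 1e-9, 0), c(0, 0, 1))
  tr <- rbind(c(1, 2, 3), c(1, 2, 5), c(1, 4, 4))  # third is degenerate
  s <- build_surface(list(vertices = v, triangles = tr))
  expect_equal(nrow(s$triangles), 2L)
  expect_equal(nrow(s$vertices), 4L)  # unreferenced vertex dropped
  expect_true(all(s$triangles >= 1 & s$triangles <= nrow(s$vertices)))
})

test_that("surface projection matches the QP per-triangle oracle", {
  set.seed(5)
  u <- matrix(rnorm(330), ncol = 3)
  sph <- 12 * u / sqrt(rowSums(u^2))
  surf <- build_surface(sph, alpha = 8)
  expect_lte(nrow(surf$triangles), 500L)
  for (i in 1:15) {
    p <- rnorm(3, sd = 15)
    got <- project_to_surface(surf, p)
    expect_equal(got$distance, qp_closest_on_mesh(p, surf), tolerance = 1e-9)
    expect_true(all(got$bary >= -1e-9))
    expect_equal(sum(got$bary), 1, tolerance = 1e-9)
    tri <- surf$triangles[got$triangle, ]
    recon <- colSums(surf$vertices[tri, ] * got$bary)
    expect_equal(unname(recon), unname(got$point), tolerance = 1e-9)
  }
  v <- surf$vertices[10, ]
  hit <- project_to_surface(surf, v)
  expect_equal(hit$distance, 0, tolerance = 1e-12)
  expect_equal(hit$point, v, tolerance = 1e-12)
})

test_that("perpendicular projection over a triangle interior is exact", {
  s <- surface_model(rbind(c(-10, -10, 0), c(10, -10, 0), c(0, 10, 0)),
                     matrix(1:3, 1))
  got <- project_to_surface(s, c(0.5, 0.2, 3))
  expect_equal(got$distance, 3)
  expect_equal(got$point, c(0.5, 0.2, 0))
})
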