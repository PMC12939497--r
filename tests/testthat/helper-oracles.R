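# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closest point on one triangle by constrained quadratic programming:
# min |a + u*ab + v*ac - p|^2 over u >= 0, v >= 0, u + v <= 1.
qp_closest_point <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a
  G <- 2 * rbind(c(sum(ab * ab), sum(ab * ac)),
                 c(sum(ab * ac), sum(ac * ac)))
  d <- 2 * c(sum(ab * (p - a)), sum(ac * (p - a)))
  A <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  sol <- quadprog::solve.QP(Dmat = G + diag(2) * 1e-12, dvec = d,
                            Amat = t(A), bvec = c(0, 0, -1))
  uv <- sol$solution
  q <- a + uv[1L] * ab + uv[2L] * ac
  sqrt(sum((p - q)^2))
}

# Minimum distance from p to a whole mesh via the QP oracle.
qp_closest_on_mesh <- function(p, surface) {
  v <- surface$vertices; tr <- surface$triangles
  min(vapply(seq_len(nrow(tr)), function(i) {
    qp_closest_point(p, v[tr[i, 1L], ], v[tr[i, 2L], ], v[tr[i, 3L], ])
  }, numeric(1L)))
}

# Two-sided signed-rank p by direct enumeration of all 2^n sign patterns.
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_ge <- mean(Ws >= W - 1e-9)
  p_le <- mean(Ws <= W + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# Random valid landmark set (well-separated, non-collinear).
random_landmarks <- function() {
  repeat {
    mfc <- stats::rnorm(3, sd = 30)
    lfc <- mfc + stats::rnorm(3, sd = 25)
    ra <- stats::rnorm(3, sd = 40)
    if (sqrt(sum((mfc - lfc)^2)) < 5) next
    org <- (mfc + lfc) / 2
    x <- (mfc - lfc) / sqrt(sum((mfc - lfc)^2))
    perp <- (ra - org) - sum((ra - org) * x) * x
    if (sqrt(sum(perp^2)) < 5) next
    return(landmark_set(mfc, lfc, ra, org + perp / 2,
                        side = sample(c("right", "left"), 1L)))
  }
}

mesh_area <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  ab <- v[tr[, 2L], , drop = FALSE] - a
  ac <- v[tr[, 3L], , drop = FALSE] - a
  cr <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  sum(0.5 * sqrt(rowSums(cr^2)))
}

pop_sd <- function(v) stats::sd(v) * sqrt((length(v) - 1) / length(v))
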