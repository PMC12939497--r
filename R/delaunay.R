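# Incremental 3D Delaunay tetrahedralization (Bowyer-Watson) and the
# alpha-complex boundary used for surface reconstruction from point clouds.

# Circumcenters and squared circumradii of tetrahedra, vectorized via
# Cramer's rule. Degenerate (near-flat) tetrahedra get r2 = Inf so that any
# later insertion carves them away and the alpha criterion drops them.
tet_circumspheres <- function(pts, tets) {
  p1 <- pts[tets[, 1L], , drop = FALSE]
  p2 <- pts[tets[, 2L], , drop = FALSE]
  p3 <- pts[tets[, 3L], , drop = FALSE]
  p4 <- pts[tets[, 4L], , drop = FALSE]
  a <- 2 * (p2 - p1); b <- 2 * (p3 - p1); d <- 2 * (p4 - p1)
  ra <- rowSums(p2^2) - rowSums(p1^2)
  rb <- rowSums(p3^2) - rowSums(p1^2)
  rd <- rowSums(p4^2) - rowSums(p1^2)
  det <- a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) -
         a[, 2L] * (b[, 1L] * d[, 3L] - b[, 3L] * d[, 1L]) +
         a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])
  scale2 <- rowSums(a^2) + rowSums(b^2) + rowSums(d^2)
  ok <- is.finite(det) & abs(det) > 1e-10 * (scale2^1.5 * 1e-6 + 1e-30)
  cx <- (ra * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) -
         rb * (a[, 2L] * d[, 3L] - a[, 3L] * d[, 2L]) +
         rd * (a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L])) / det
  cy <- -(ra * (b[, 1L] * d[, 3L] - b[, 3L] * d[, 1L]) -
          rb * (a[, 1L] * d[, 3L] - a[, 3L] * d[, 1L]) +
          rd * (a[, 1L] * b[, 3L] - a[, 3L] * b[, 1L])) / det
  cz <- (ra * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L]) -
         rb * (a[, 1L] * d[, 2L] - a[, 2L] * d[, 1L]) +
         rd * (a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])) / det
  cc <- cbind(cx, cy, cz)
  r2 <- rowSums((cc - p1)^2)
  r2[!ok] <- Inf
  cc[!ok, ] <- 0
  list(center = cc, r2 = r2)
}

# Deterministic symmetry-breaking jitter (relative to the bounding-box
# diagonal). Cospherical inputs such as points sampled on a sphere make the
# in-circumsphere predicate ill-conditioned; the jitter perturbs only the
# combinatorial construction, never the returned coordinates.
delaunay_jitter <- function(pts, rel = 1e-7) {
  diag_len <- sqrt(sum((apply(pts, 2L, max) - apply(pts, 2L, min))^2))
  n <- nrow(pts)
  idx <- seq_len(n)
  j <- sapply(1:3, function(k) {
    x <- sin(idx * 12.9898 + k * 78.233) * 43758.5453
    (x - floor(x)) - 0.5
  })
  pts + j * (rel * max(diag_len, 1))
}

#' 3D Delaunay tetrahedralization
#'
#' Incremental Bowyer-Watson construction with a super-tetrahedron and a
#' deterministic micro-jitter that breaks cospherical degeneracies (the
#' output indices refer to the original, unjittered points).
#'
#' @param pts n x 3 point matrix, n >= 4, not all coplanar.
#' @return integer matrix (k x 4) of tetrahedron vertex indices.
#' @keywords internal
delaunay3d <- function(pts) {
  n <- nrow(pts)
  work <- delaunay_jitter(pts)
  ctr <- colMeans(work)
  rad <- sqrt(max(rowSums(sweep(work, 2L, ctr)^2)))
  s <- 60 * max(rad, 1)
  super <- rbind(ctr + s * c(1, 1, 1), ctr + s * c(1, -1, -1),
                 ctr + s * c(-1, 1, -1), ctr + s * c(-1, -1, 1))
  work <- rbind(work, super)

  cap <- 2048L
  tets <- matrix(0L, cap, 4L)
  centers <- matrix(0, cap, 3L)
  r2 <- numeric(cap)
  alive <- logical(cap)
  ntet <- 0L

  push <- function(new_tets) {
    k <- nrow(new_tets)
    if (ntet + k > cap) {
      newcap <- max(cap * 2L, ntet + k)
      tets <<- rbind(tets, matrix(0L, newcap - cap, 4L))
      centers <<- rbind(centers, matrix(0, newcap - cap, 3L))
      r2 <<- c(r2, numeric(newcap - cap))
      alive <<- c(alive, logical(newcap - cap))
      cap <<- newcap
    }
    cs <- tet_circumspheres(work, new_tets)
    idx <- ntet + seq_len(k)
    tets[idx, ] <<- new_tets
    centers[idx, ] <<- cs$center
    r2[idx] <<- cs$r2
    alive[idx] <<- TRUE
    ntet <<- ntet + k
  }

  push(matrix(n + 1:4, nrow = 1L))

  key_base <- as.numeric(n + 5L)
  for (i in seq_len(n)) {
    p <- work[i, ]
    live <- which(alive[seq_len(ntet)])
    d2 <- rowSums(sweep(centers[live, , drop = FALSE], 2L, p)^2)
    bad <- live[d2 < r2[live] * (1 + 1e-10) + 1e-9]
    if (length(bad) == 0L) {
      # numerical fallback: use the tetrahedron with the nearest circumcenter
      bad <- live[which.min(d2 - r2[live])]
    }
    bt <- tets[bad, , drop = FALSE]
    faces <- rbind(bt[, c(1L, 2L, 3L)], bt[, c(1L, 2L, 4L)],
                   bt[, c(1L, 3L, 4L)], bt[, c(2L, 3L, 4L)])
    fs <- t(apply(faces, 1L, sort.int))
    key <- (fs[, 1L] * key_base + fs[, 2L]) * key_base + fs[, 3L]
    once <- !(key %in% key[duplicated(key)])
    boundary <- faces[once, , drop = FALSE]
    alive[bad] <- FALSE
    push(cbind(boundary, i))
  }

  keep <- alive[seq_len(ntet)]
  out <- tets[seq_len(ntet), , drop = FALSE][keep, , drop = FALSE]
  out <- out[apply(out, 1L, max) <= n, , drop = FALSE]
  if (nrow(out) == 0L) stop("Delaunay tetrahedralization is empty")
  out
}

# Circumcenters and circumradii of triangles embedded in 3D, vectorized.
tri_circumspheres <- function(pts, tris) {
  a <- pts[tris[, 1L], , drop = FALSE]
  b <- pts[tris[, 2L], , drop = FALSE]
  c3 <- pts[tris[, 3L], , drop = FALSE]
  u <- b - a; v <- c3 - a
  crossm <- function(x, y) cbind(x[, 2L] * y[, 3L] - x[, 3L] * y[, 2L],
                                 x[, 3L] * y[, 1L] - x[, 1L] * y[, 3L],
                                 x[, 1L] * y[, 2L] - x[, 2L] * y[, 1L])
  w <- crossm(u, v)
  w2 <- rowSums(w^2)
  ctr <- a + (crossm(w, u) * rowSums(v^2) +
              crossm(v, w) * rowSums(u^2)) / pmax(2 * w2, 1e-300)
  r2 <- rowSums((ctr - a)^2)
  r2[w2 < 1e-20] <- Inf
  list(center = ctr, r2 = r2)
}

#' Alpha-complex boundary triangles
#'
#' The surface combines (i) the regular boundary of the solid part -
#' triangles incident to exactly one tetrahedron with circumradius at most
#' `alpha` - and (ii) singular alpha-complex faces: Delaunay triangles
#' incident to no retained tetrahedron whose own circumradius is at most
#' `alpha` and whose diametral ball is empty of other input points (Gabriel
#' condition). The singular faces are what reconstructs a thin, hollow
#' surface sample, where every tetrahedron spans the cavity and is dropped.
#'
#' @param pts n x 3 point matrix.
#' @param tets k x 4 tetrahedra from [delaunay3d()].
#' @param alpha circumradius threshold (mm).
#' @return m x 3 integer triangle matrix (possibly 0 rows).
#' @keywords internal
alpha_boundary <- function(pts, tets, alpha) {
  cs <- tet_circumspheres(pts, tets)
  kept <- is.finite(cs$r2) & sqrt(cs$r2) <= alpha

  all_faces <- rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
                     tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)])
  face_kept <- rep(kept, 4L)
  fs <- t(apply(all_faces, 1L, sort.int))
  key_base <- as.numeric(nrow(pts) + 1L)
  key <- (fs[, 1L] * key_base + fs[, 2L]) * key_base + fs[, 3L]

  kept_count <- rowsum(as.numeric(face_kept), key)
  first <- !duplicated(key)
  ufaces <- fs[first, , drop = FALSE]
  ukey <- key[first]
  ucount <- kept_count[match(as.character(ukey), rownames(kept_count)), 1L]

  regular <- ufaces[ucount == 1, , drop = FALSE]

  cand <- which(ucount == 0)
  singular <- matrix(0L, 0L, 3L)
  if (length(cand)) {
    ct <- ufaces[cand, , drop = FALSE]
    tc <- tri_circumspheres(pts, ct)
    small <- which(is.finite(tc$r2) & sqrt(tc$r2) <= alpha)
    if (length(small)) {
      ct <- ct[small, , drop = FALSE]
      ctr <- tc$center[small, , drop = FALSE]
      r2 <- tc$r2[small]
      # Gabriel test in chunks: diametral ball empty of other points
      ok <- logical(nrow(ct))
      step <- 256L
      psq <- rowSums(pts^2)
      for (i0 in seq(1L, nrow(ct), by = step)) {
        idx <- i0:min(nrow(ct), i0 + step - 1L)
        d2 <- outer(rowSums(ctr[idx, , drop = FALSE]^2), psq, "+") -
          2 * ctr[idx, , drop = FALSE] %*% t(pts)
        inside <- d2 < (r2[idx] - 1e-9 * pmax(r2[idx], 1))
        inside[cbind(seq_along(idx), ct[idx, 1L])] <- FALSE
        inside[cbind(seq_along(idx), ct[idx, 2L])] <- FALSE
        inside[cbind(seq_along(idx), ct[idx, 3L])] <- FALSE
        ok[idx] <- rowSums(inside) == 0L
      }
      singular <- ct[ok, , drop = FALSE]
    }
  }
  rbind(regular, singular)
}
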