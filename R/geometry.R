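# Anatomical coordinate frames and surface geometry. All lengths in mm.

#' Coerce points to an n x 3 matrix
#'
#' Accepts a length-3 numeric vector, an n x 3 matrix, or a data frame with
#' columns x, y, z (any case). Used internally by every geometric operation.
#'
#' @param p points in any of the accepted forms.
#' @return numeric matrix with 3 columns.
#' @keywords internal
as_points <- function(p) {
  if (is.data.frame(p)) {
    nm <- tolower(names(p))
    if (all(c("x", "y", "z") %in% nm)) {
      p <- as.matrix(p[, match(c("x", "y", "z"), nm), drop = FALSE])
    } else {
      p <- as.matrix(p)
    }
  }
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a point must have exactly 3 coordinates")
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  p <- unname(as.matrix(p))
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must be n x 3")
  if (!all(is.finite(p))) stop("non-finite coordinates")
  p
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero ", what)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Landmark set for the femoral coordinate system
#'
#' Bundles the medial (MFC) and lateral (LFC) femoral condyle points, a point
#' on the reconstructed femoral shaft axis (RA), the radiographic Schottle
#' point, and the knee side. Coordinates are scanner-space mm.
#'
#' @param MFC,LFC,RA,S_point length-3 numeric vectors (mm).
#' @param side `"right"` or `"left"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(MFC, LFC, RA, S_point, side = c("right", "left")) {
  side <- match.arg(side)
  lm <- list(MFC = drop(as_points(MFC)), LFC = drop(as_points(LFC)),
             RA = drop(as_points(RA)), S_point = drop(as_points(S_point)),
             side = side)
  if (vnorm(lm$MFC - lm$LFC) < 1e-9) {
    stop("degenerate landmarks: MFC and LFC coincide")
  }
  structure(lm, class = "landmark_set")
}

#' Build the femur-centered anatomical coordinate frame
#'
#' The origin is the midpoint of MFC and LFC. X is the medial-lateral axis
#' (unit vector from LFC to MFC, flipped for left knees so +X always points
#' medially), Z is the proximal-distal axis (the component of RA - origin
#' orthogonal to X, pointing proximally toward the shaft), and Y = Z x X is
#' anterior-posterior, giving a right-handed orthonormal frame. Left knees
#' are thereby mirrored into a common right-knee convention so that cohort
#' coordinates are poolable.
#'
#' @param landmarks a [landmark_set()].
#' @return object of class `femoral_frame` with fields `origin` (mm) and
#'   `rotation` (3 x 3 orthonormal, rows = local X, Y, Z axes expressed in
#'   scanner coordinates; `det = +1`).
#' @examples
#' fr <- femoral_frame(landmark_set(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 10),
#'                                  c(0.5, 0, 0.3), side = "right"))
#' to_local(fr, c(0, 0, 0))
#' @export
femoral_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  origin <- (landmarks$MFC + landmarks$LFC) / 2
  x <- unitize(landmarks$MFC - landmarks$LFC, "MFC-LFC axis")
  if (landmarks$side == "left") x <- -x
  ra <- landmarks$RA - origin
  z <- ra - sum(ra * x) * x
  if (vnorm(z) < 1e-9) {
    stop("degenerate landmarks: RA is collinear with the MFC-LFC axis")
  }
  z <- z / vnorm(z)
  y <- cross3(z, x)
  rot <- rbind(X = x, Y = y, Z = z)
  structure(list(origin = origin, rotation = rot, side = landmarks$side),
            class = "femoral_frame")
}

#' @export
print.femoral_frame <- function(x, ...) {
  cat("Femoral coordinate frame (", x$side, " knee)\n", sep = "")
  cat("  origin (mm):", format(round(x$origin, 3)), "\n")
  cat("  axes (rows = local X,Y,Z in scanner coords):\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Map points between scanner and local femoral coordinates
#'
#' `to_local()` expresses scanner-space points in the anatomical frame;
#' `from_local()` is its exact inverse. Both are rigid transforms
#' (distance-preserving to machine precision).
#'
#' @param frame a [femoral_frame()].
#' @param p a point (length-3) or n x 3 matrix, mm.
#' @return points in the same shape as the input.
#' @export
to_local <- function(frame, p) {
  stopifnot(inherits(frame, "femoral_frame"))
  pm <- as_points(p)
  out <- sweep(pm, 2L, frame$origin) %*% t(frame$rotation)
  colnames(out) <- c("X", "Y", "Z")
  if (is.null(dim(p)) && !is.data.frame(p)) drop(out) else out
}

#' @rdname to_local
#' @export
from_local <- function(frame, p) {
  stopifnot(inherits(frame, "femoral_frame"))
  pm <- as_points(p)
  out <- sweep(pm %*% frame$rotation, 2L, frame$origin, "+")
  colnames(out) <- c("x", "y", "z")
  if (is.null(dim(p)) && !is.data.frame(p)) drop(out) else out
}

#' Triangle surface model
#'
#' Stores a triangulated surface as vertices (n x 3, mm) and triangles
#' (m x 3 vertex indices). Construction removes triangles with area below
#' `area_tol` (they destabilize barycentric projection) and drops vertices no
#' longer referenced, reindexing the triangles.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param provenance `"mesh-input"` or `"delaunay-derived"`.
#' @param area_tol minimum retained triangle area (mm^2).
#' @return object of class `surface_model`.
#' @export
surface_model <- function(vertices, triangles,
                          provenance = c("mesh-input", "delaunay-derived"),
                          area_tol = 1e-6) {
  provenance <- match.arg(provenance)
  v <- as_points(vertices)
  tr <- as.matrix(triangles)
  storage.mode(tr) <- "integer"
  if (ncol(tr) != 3L) stop("triangles must be m x 3 vertex indices")
  if (nrow(tr) == 0L) stop("surface has no triangles")
  if (min(tr) < 1L || max(tr) > nrow(v)) stop("triangle index out of range")
  a <- v[tr[, 1L], , drop = FALSE]
  ab <- v[tr[, 2L], , drop = FALSE] - a
  ac <- v[tr[, 3L], , drop = FALSE] - a
  cr <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  area <- 0.5 * sqrt(rowSums(cr^2))
  tr <- tr[area >= area_tol, , drop = FALSE]
  if (nrow(tr) == 0L) stop("all triangles degenerate")
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  tr <- matrix(remap[tr], ncol = 3L)
  v <- v[used, , drop = FALSE]
  structure(list(vertices = v, triangles = tr, provenance = provenance),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat("Surface model: ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Re-express a surface in another coordinate frame
#' @param surface a [surface_model()] in scanner coordinates.
#' @param frame a [femoral_frame()].
#' @return a `surface_model` with vertices in local coordinates.
#' @keywords internal
surface_to_local <- function(surface, frame) {
  s <- surface
  s$vertices <- to_local(frame, surface$vertices)
  s
}

#' Build a surface from a point cloud or pass a mesh through
#'
#' For a raw point cloud the surface is reconstructed as the boundary of the
#' alpha complex of the 3D Delaunay tetrahedralization: tetrahedra with
#' circumradius at most `alpha` are retained and faces belonging to exactly
#' one retained tetrahedron form the surface. An existing triangle mesh (a
#' `surface_model` or a `list(vertices, triangles)`) is passed through with
#' degenerate-triangle cleanup only.
#'
#' The default `alpha` is twice the median nearest-neighbor spacing of the
#' cloud, which adapts to sampling density without per-subject tuning.
#'
#' @param x point matrix (>= 4 non-coplanar points), `surface_model`, or
#'   `list(vertices, triangles)`.
#' @param alpha alpha-shape radius (mm); `NULL` for the adaptive default.
#' @return a [surface_model()].
#' @examples
#' set.seed(1)
#' u <- matrix(rnorm(300), ncol = 3)
#' sph <- 20 * u / sqrt(rowSums(u^2))
#' surf <- build_surface(sph, alpha = 10)
#' @export
build_surface <- function(x, alpha = NULL) {
  if (inherits(x, "surface_model")) {
    return(surface_model(x$vertices, x$triangles, provenance = x$provenance))
  }
  if (is.list(x) && !is.data.frame(x) && !is.null(x$triangles)) {
    return(surface_model(x$vertices, x$triangles, provenance = "mesh-input"))
  }
  pts <- as_points(x)
  if (nrow(pts) < 4L) stop("need at least 4 points to build a surface")
  sv <- svd(sweep(pts, 2L, colMeans(pts)))$d
  if (sv[3L] < 1e-8 * max(sv[1L], 1)) {
    stop("points are coplanar; cannot build a 3D surface")
  }
  if (is.null(alpha)) alpha <- 2 * median_nn_spacing(pts)
  tets <- delaunay3d(pts)
  tri <- alpha_boundary(pts, tets, alpha)
  if (nrow(tri) == 0L) stop("alpha = ", alpha, " retained no tetrahedra")
  surface_model(pts, tri, provenance = "delaunay-derived")
}

#' Median nearest-neighbor spacing of a point cloud
#' @param pts n x 3 matrix.
#' @return scalar mm.
#' @keywords internal
median_nn_spacing <- function(pts) {
  n <- nrow(pts)
  # chunked to avoid an n x n allocation on large clouds
  step <- max(1L, min(n, 512L))
  nn <- numeric(n)
  sq <- rowSums(pts^2)
  for (i0 in seq(1L, n, by = step)) {
    idx <- i0:min(n, i0 + step - 1L)
    d2 <- outer(sq[idx], sq, "+") - 2 * pts[idx, , drop = FALSE] %*% t(pts)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  stats::median(nn)
}

#' Closest point on a triangulated surface
#'
#' Exact minimum-distance projection of a query point onto a triangle mesh,
#' scanning every triangle with the vectorized closest-point-on-triangle
#' test (Voronoi-region case analysis).
#'
#' @param surface a [surface_model()].
#' @param p query point, length-3 (mm).
#' @return list with `point` (closest point on the surface), `distance` (mm),
#'   `triangle` (index), and `bary` (barycentric coordinates on it).
#' @export
project_to_surface <- function(surface, p) {
  stopifnot(inherits(surface, "surface_model"))
  p <- drop(as_points(p))
  cp <- closest_on_triangles(p, surface$vertices, surface$triangles)
  i <- which.min(cp$d2)
  list(point = cp$points[i, ], distance = sqrt(max(cp$d2[i], 0)),
       triangle = i, bary = cp$bary[i, ])
}

#' Distance from a point to a surface
#' @inheritParams project_to_surface
#' @return scalar mm.
#' @keywords internal
dist_to_surface <- function(surface, p) project_to_surface(surface, p)$distance

# Vectorized closest point on each triangle (Ericson's region test).
# Returns squared distances, closest points and barycentric coords per
# triangle; the caller takes the argmin.
closest_on_triangles <- function(p, vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c3 <- vertices[triangles[, 3L], , drop = FALSE]
  m <- nrow(a)
  pm <- matrix(p, nrow = m, ncol = 3L, byrow = TRUE)
  ab <- b - a; ac <- c3 - a; ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- pm - c3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  u <- numeric(m); v <- numeric(m); w <- numeric(m)
  done <- logical(m)

  set_bary <- function(mask, uu, vv, ww) {
    mask <- mask & !done
    u[mask] <<- uu[mask]; v[mask] <<- vv[mask]; w[mask] <<- ww[mask]
    done[mask] <<- TRUE
  }
  one <- rep(1, m); zero <- rep(0, m)
  set_bary(d1 <= 0 & d2 <= 0, one, zero, zero)                      # vertex A
  set_bary(d3 >= 0 & d4 <= d3, zero, one, zero)                     # vertex B
  set_bary(d6 >= 0 & d5 <= d6, zero, zero, one)                     # vertex C
  t_ab <- d1 / pmax(d1 - d3, .Machine$double.eps)
  set_bary(vc <= 0 & d1 >= 0 & d3 <= 0, 1 - t_ab, t_ab, zero)       # edge AB
  t_ac <- d2 / pmax(d2 - d6, .Machine$double.eps)
  set_bary(vb <= 0 & d2 >= 0 & d6 <= 0, 1 - t_ac, zero, t_ac)       # edge AC
  t_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), .Machine$double.eps)
  set_bary(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
           zero, 1 - t_bc, t_bc)                                    # edge BC
  denom <- va + vb + vc
  vi <- vb / denom; wi <- vc / denom
  set_bary(rep(TRUE, m), 1 - vi - wi, vi, wi)                       # interior

  q <- a * u + b * v + c3 * w
  d2q <- rowSums((pm - q)^2)
  list(d2 = d2q, points = q, bary = cbind(u, v, w))
}
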