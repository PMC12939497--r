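# Synthetic joint-motion generator: parametric condyle/shaft femurs with
# analytic landmarks, flexion-parameterized patellar motion with a planted
# best-isometry point, and paired S/I coordinate cohorts. Default scales
# mirror an adult femur (intercondylar width ~81 mm, modeled ligament
# length ~55 mm).

#' Specification of a synthetic knee
#'
#' @param condyle_radius condylar sphere radius (mm, default 22).
#' @param intercondylar_width MFC-LFC distance (mm, default 81).
#' @param shaft_length proximal extent of the shaft cylinder (mm, 110).
#' @param shaft_radius shaft cylinder radius (mm, 15).
#' @param L_star planted attachment-to-centroid distance (mm, default 55).
#' @param planted_offset geodesic offset of the planted point from the
#'   S-point along the condyle (mm, default 10; must land in the 5-15 mm
#'   annulus).
#' @param n_frames motion frames (default 25, matching a 20-30 frame scan).
#' @param angle_range flexion range in degrees (default `c(0, 90)`).
#' @param sigma radial noise SD on the planted distance (mm, default 0).
#' @param side `"right"` or `"left"`.
#' @param mesh_density resolution multiplier (1 gives ~900 vertices).
#' @param s_direction unit-ish direction of the S-point on the medial
#'   condyle (from its center), in the canonical +X-medial pose.
#' @param pose optional rigid pose `list(R = 3x3, t = length-3)` applied to
#'   everything, emulating an arbitrary scanner orientation.
#' @param subject_id label for generated sequences.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(condyle_radius = 22, intercondylar_width = 81,
                           shaft_length = 110, shaft_radius = 15,
                           L_star = 55, planted_offset = 10,
                           n_frames = 25L, angle_range = c(0, 90),
                           sigma = 0, side = c("right", "left"),
                           mesh_density = 1,
                           s_direction = c(0.55, -0.35, 0.75),
                           pose = NULL, subject_id = "synthetic") {
  side <- match.arg(side)
  if (intercondylar_width <= 2 * condyle_radius * 0.8) {
    stop("intercondylar width too small for the condyle radius")
  }
  if (sigma < 0) stop("sigma must be >= 0")
  if (diff(range(angle_range)) <= 0) stop("empty angle range")
  if (is.null(pose)) pose <- list(R = diag(3), t = c(0, 0, 0))
  structure(list(condyle_radius = condyle_radius,
                 intercondylar_width = intercondylar_width,
                 shaft_length = shaft_length, shaft_radius = shaft_radius,
                 L_star = L_star, planted_offset = planted_offset,
                 n_frames = as.integer(n_frames), angle_range = angle_range,
                 sigma = sigma, side = side, mesh_density = mesh_density,
                 s_direction = s_direction / vnorm(s_direction),
                 pose = pose, subject_id = subject_id),
            class = "synthetic_spec")
}

#' Randomized synthetic knee within realistic anatomical ranges
#'
#' Samples condyle radius, width, planted distance and offset, S-point
#' direction, and a random rigid scanner pose. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param sigma radial noise SD (mm).
#' @param n_frames motion frames.
#' @param mesh_density resolution multiplier.
#' @return a [synthetic_spec()].
#' @export
random_synthetic_spec <- function(seed, sigma = 0, n_frames = 25L,
                                  mesh_density = 1) {
  with_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / vnorm(ax)
    th <- stats::runif(1, 0, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
               c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    sdir <- c(0.55, -0.35, 0.75) + stats::rnorm(3, sd = 0.12)
    synthetic_spec(
      condyle_radius = stats::runif(1, 18, 26),
      intercondylar_width = stats::runif(1, 72, 92),
      L_star = stats::runif(1, 48, 62),
      planted_offset = stats::runif(1, 7, 13),
      n_frames = n_frames, sigma = sigma,
      side = sample(c("right", "left"), 1L),
      mesh_density = mesh_density,
      s_direction = sdir,
      pose = list(R = R, t = stats::runif(3, -60, 60)),
      subject_id = paste0("sim", seed))
  })
}

# Latitude-longitude triangulated sphere.
uv_sphere <- function(center, r, n_lat, n_lon) {
  lat <- seq(0, pi, length.out = n_lat + 2L)[-c(1L, n_lat + 2L)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  ring <- function(phi) cbind(r * sin(phi) * cos(lon),
                              r * sin(phi) * sin(lon),
                              r * cos(phi))
  v <- rbind(c(0, 0, r), do.call(rbind, lapply(lat, ring)), c(0, 0, -r))
  v <- sweep(v, 2L, center, "+")
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tri <- list()
  for (j in seq_len(n_lon)) {             # top fan
    tri[[length(tri) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  for (i in seq_len(n_lat - 1L)) {        # quad strips
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tri[[length(tri) + 1L]] <- c(a, c2, b)
      tri[[length(tri) + 1L]] <- c(b, c2, d)
    }
  }
  bot <- nrow(v)
  for (j in seq_len(n_lon)) {             # bottom fan
    tri[[length(tri) + 1L]] <- c(bot, idx(n_lat, j + 1L), idx(n_lat, j))
  }
  list(vertices = v, triangles = do.call(rbind, tri))
}

# Open cylinder along +Z.
cylinder_mesh <- function(center_xy, z0, z1, r, n_z, n_lon) {
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  zz <- seq(z0, z1, length.out = n_z)
  v <- do.call(rbind, lapply(zz, function(z) {
    cbind(center_xy[1L] + r * cos(lon), center_xy[2L] + r * sin(lon), z)
  }))
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tri <- list()
  for (i in seq_len(n_z - 1L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tri[[length(tri) + 1L]] <- c(a, b, c2)
      tri[[length(tri) + 1L]] <- c(b, d, c2)
    }
  }
  list(vertices = v, triangles = do.call(rbind, tri))
}

apply_pose <- function(pts, pose, mirror_x = FALSE) {
  pm <- as_points(pts)
  if (mirror_x) pm[, 1L] <- -pm[, 1L]
  out <- sweep(pm %*% t(pose$R), 2L, pose$t, "+")
  if (is.null(dim(pts))) drop(out) else out
}

#' Generate a synthetic femur with analytic landmarks
#'
#' The surface is the union of two condylar spheres bridged by a shaft
#' cylinder running proximally. MFC and LFC are the extreme medial/lateral
#' condylar points (so their distance equals the intercondylar width
#' exactly), RA lies on the shaft axis, and the S-point is a designated
#' medial-condyle surface point; the planted point P* sits a geodesic
#' `planted_offset` away from it on the same condyle. Both S-point and P*
#' are snapped exactly onto the triangulated surface.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `surface` ([surface_model()]), `landmarks`
#'   ([landmark_set()]), `P_star` (planted point, scanner mm),
#'   `condyle_center` (medial condyle center, scanner mm), and `spec`.
#' @export
make_femur <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rc <- spec$condyle_radius
  w <- spec$intercondylar_width
  cm <- c(w / 2 - rc, 0, 0)     # medial condyle center (+X medial)
  cl <- c(-(w / 2 - rc), 0, 0)
  dens <- spec$mesh_density
  n_lat <- max(8L, as.integer(round(14 * dens)))
  n_lon <- max(10L, as.integer(round(20 * dens)))
  s1 <- uv_sphere(cm, rc, n_lat, n_lon)
  s2 <- uv_sphere(cl, rc, n_lat, n_lon)
  cyl <- cylinder_mesh(c(0, 0), 0.6 * rc, spec$shaft_length,
                       spec$shaft_radius,
                       max(6L, as.integer(round(9 * dens))),
                       max(10L, as.integer(round(16 * dens))))
  v <- rbind(s1$vertices, s2$vertices, cyl$vertices)
  tr <- rbind(s1$triangles,
              s2$triangles + nrow(s1$vertices),
              cyl$triangles + nrow(s1$vertices) + nrow(s2$vertices))

  mfc <- c(w / 2, 0, 0)
  lfc <- c(-w / 2, 0, 0)
  ra <- c(0, 0, 0.8 * spec$shaft_length)
  us <- spec$s_direction
  s0 <- cm + rc * us
  phi <- 2 * asin(min(spec$planted_offset, 2 * rc - 1e-6) / (2 * rc))
  zh <- c(0, 0, 1)
  axis <- cross3(us, zh)
  if (vnorm(axis) < 1e-9) axis <- c(0, 1, 0) else axis <- axis / vnorm(axis)
  K <- rbind(c(0, -axis[3L], axis[2L]), c(axis[3L], 0, -axis[1L]),
             c(-axis[2L], axis[1L], 0))
  Rphi <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  p0 <- cm + rc * drop(Rphi %*% us)

  mir <- spec$side == "left"
  v <- apply_pose(v, spec$pose, mir)
  if (mir) tr <- tr[, c(1L, 3L, 2L)]    # keep outward orientation
  surface <- surface_model(v, tr, provenance = "mesh-input")
  mfc <- apply_pose(mfc, spec$pose, mir)
  lfc <- apply_pose(lfc, spec$pose, mir)
  ra <- apply_pose(ra, spec$pose, mir)
  s0 <- apply_pose(s0, spec$pose, mir)
  p0 <- apply_pose(p0, spec$pose, mir)
  cm_s <- apply_pose(cm, spec$pose, mir)

  s_pt <- project_to_surface(surface, s0)$point
  p_star <- project_to_surface(surface, p0)$point
  sep <- vnorm(p_star - s_pt)
  if (sep <= 5 || sep >= 15) {
    stop("planted point fell outside the 5-15 mm annulus (", round(sep, 2),
         " mm); adjust planted_offset or mesh_density")
  }
  list(surface = surface,
       landmarks = landmark_set(mfc, lfc, ra, s_pt, side = spec$side),
       P_star = p_star, condyle_center = cm_s, spec = spec)
}

#' Generate a flexion motion with a planted isometric point
#'
#' Sweeps a rigid zero-mean ellipsoidal patellar point cloud along a
#' non-planar flexion-parameterized arc such that the cloud centroid lies at
#' distance `L_star + eps_i` from the planted point `P*`, with
#' `eps_i ~ N(0, sigma)`. With `sigma = 0` the centroid is exactly
#' equidistant from `P*` in every frame, so `P*` is the global optimum of
#' the length-variability objective (objective value 0). Frames carry the
#' true flexion angles.
#'
#' @param spec a [synthetic_spec()].
#' @param femur a [make_femur()] result.
#' @param seed integer seed driving all randomness (noise and cloud shape).
#' @return a [knee_sequence()] with attribute `"truth"` = list(P_star,
#'   L_star, sigma, angles).
#' @export
make_motion <- function(spec, femur, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_frames
  if (n < 3L) stop("need at least 3 frames")
  angles <- seq(spec$angle_range[1L], spec$angle_range[2L], length.out = n)
  tt <- (angles - spec$angle_range[1L]) / diff(range(spec$angle_range))

  e1 <- unitize(femur$P_star - femur$condyle_center)
  tmp <- if (abs(e1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- unitize(cross3(e1, tmp))
  e3 <- cross3(e1, e2)

  dat <- with_seed(seed, {
    eps <- if (spec$sigma > 0) stats::rnorm(n, 0, spec$sigma) else numeric(n)
    cloud <- cbind(stats::rnorm(60, sd = 12), stats::rnorm(60, sd = 9),
                   stats::rnorm(60, sd = 4))
    list(eps = eps, cloud = sweep(cloud, 2L, colMeans(cloud)))
  })

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    d <- e1 + 0.55 * sin(1.3 * (tt[i] - 0.45)) * e2 +
      0.40 * sin(2.3 * tt[i] + 0.4) * e3
    d <- d / vnorm(d)
    ci <- femur$P_star + (spec$L_star + dat$eps[i]) * d
    frames[[i]] <- frame_data(i, femur$surface,
                              sweep(dat$cloud, 2L, ci, "+"),
                              flexion_angle = angles[i])
  }
  seq_out <- knee_sequence(spec$subject_id, spec$side, frames)
  attr(seq_out, "truth") <- list(P_star = femur$P_star,
                                 L_star = spec$L_star,
                                 sigma = spec$sigma, angles = angles,
                                 seed = seed)
  seq_out
}

#' Generate a paired S/I coordinate cohort
#'
#' Per subject the S-point is drawn from a multivariate normal around the
#' cohort mean and the I-point is the S-point plus a fixed shift `delta`
#' plus independent per-axis noise - the structure of a paired cohort with a
#' systematic proximal (Z) displacement. Defaults reproduce the reference
#' cohort scale: mean S at (39.15, -1.29, 9.32) mm and a shift of
#' (-0.38, -0.19, 1.88) mm, i.e. ~1.9 mm proximal.
#'
#' @param n_subjects cohort size (default 58).
#' @param delta length-3 I-minus-S mean shift (mm).
#' @param sigma length-3 per-axis SD of the added I noise (mm).
#' @param mu_S length-3 cohort mean of the S-point (mm).
#' @param sigma_S length-3 per-axis SD of the S-point (mm).
#' @param seed integer seed.
#' @return a [cohort_table()] data frame.
#' @export
make_cohort <- function(n_subjects = 58L,
                        delta = c(-0.38, -0.19, 1.88),
                        sigma = c(1.3, 1.4, 3.0),
                        mu_S = c(39.15, -1.29, 9.32),
                        sigma_S = c(3.1, 2.1, 2.2),
                        seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  with_seed(seed, {
    S <- sapply(1:3, function(j) stats::rnorm(n_subjects, mu_S[j], sigma_S[j]))
    E <- sapply(1:3, function(j) stats::rnorm(n_subjects, 0, sigma[j]))
    I <- S + matrix(delta, n_subjects, 3L, byrow = TRUE) + E
    cohort_table(data.frame(
      subject_id = sprintf("subj%02d", seq_len(n_subjects)),
      Sx = S[, 1L], Sy = S[, 2L], Sz = S[, 3L],
      Ix = I[, 1L], Iy = I[, 2L], Iz = I[, 3L]))
  })
}
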