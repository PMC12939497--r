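# File IO: ASCII meshes (PLY/OBJ), point clouds (XYZ/CSV), landmark files
# (JSON/CSV), sequence manifests, simulated datasets, and result export.

#' Read a triangle mesh or point cloud file
#'
#' Supported: ASCII PLY and OBJ triangle meshes, and XYZ/CSV point clouds
#' (columns x, y, z in mm, with or without header). Meshes return a
#' [surface_model()]; point clouds return an n x 3 matrix.
#'
#' @param path file path; format inferred from the extension.
#' @return `surface_model` or point matrix.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         xyz = ,
         csv = read_xyz(path),
         stop("unsupported mesh format: .", ext))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "ply")) stop(path, ": not a PLY file")
  hdr_end <- which(lines == "end_header")[1L]
  if (is.na(hdr_end)) stop(path, ": missing end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (any(grepl("^format binary", hdr))) {
    stop(path, ": binary PLY unsupported; export ASCII")
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", hdr, value = TRUE)[1L]))
  body <- lines[-seq_len(hdr_end)]
  vmat <- do.call(rbind, lapply(body[seq_len(nv)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:3])
  }))
  if (is.na(nf) || nf == 0L) return(vmat)
  fmat <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
    if (x[1L] != 3L) stop(path, ": non-triangular face")
    x[2:4] + 1L
  }))
  surface_model(vmat, fmat, provenance = "mesh-input")
}

write_ply <- function(x, path) {
  if (inherits(x, "surface_model")) {
    v <- x$vertices; f <- x$triangles
  } else {
    v <- as_points(x); f <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", if (is.null(f)) 0L else nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(format(v, digits = 10, trim = TRUE, scientific = FALSE),
                   1L, paste, collapse = " "), con)
  if (!is.null(f)) {
    writeLines(paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  v <- do.call(rbind, lapply(vlines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][2:4])
  }))
  if (length(flines) == 0L) return(v)
  f <- do.call(rbind, lapply(flines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]][-1L]
    if (length(tok) != 3L) stop(path, ": non-triangular face")
    as.integer(sub("/.*", "", tok))
  }))
  surface_model(v, f, provenance = "mesh-input")
}

read_xyz <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[a-df-wyzA-DF-WYZ]", first) ||
    grepl("^\\s*[xX]\\b|,\\s*[xX]\\s*,|^x,", first)
  df <- utils::read.csv(path, header = has_header,
                        sep = if (grepl(",", first)) "," else "")
  as_points(if (has_header) df else stats::setNames(df[, 1:3],
                                                    c("x", "y", "z")))
}

write_xyz <- function(pts, path) {
  pts <- as_points(pts)
  utils::write.csv(data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a landmark file
#'
#' JSON (keys MFC, LFC, RA, S_point each `[x, y, z]` mm, plus `side`) or CSV
#' (columns name, x, y, z and a side row or column).
#'
#' @param path JSON or CSV landmark file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    j <- jsonlite::fromJSON(path)
    return(landmark_set(j$MFC, j$LFC, j$RA, j$S_point, side = j$side))
  }
  df <- utils::read.csv(path)
  row_of <- function(nm) {
    r <- df[df$name == nm, c("x", "y", "z")]
    if (nrow(r) != 1L) stop("landmark '", nm, "' missing in ", path)
    as.numeric(r)
  }
  side <- if ("side" %in% names(df)) as.character(df$side[1L]) else "right"
  landmark_set(row_of("MFC"), row_of("LFC"), row_of("RA"),
               row_of("S_point"), side = side)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()] to write.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(MFC = landmarks$MFC, LFC = landmarks$LFC,
                            RA = landmarks$RA, S_point = landmarks$S_point,
                            side = landmarks$side),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a knee sequence from a manifest
#'
#' The manifest CSV lists one row per frame: `frame_index`, `femur_file`,
#' `patella_file`, optional `flexion_angle` (degrees); file paths are
#' resolved relative to the manifest. Attributes `subject_id` and `side`
#' come from equally named columns if present. Unsorted frames are loaded
#' sorted with a warning; duplicate indices or missing files are errors
#' naming the offending row.
#'
#' @param manifest_path CSV manifest path.
#' @return a [knee_sequence()].
#' @export
read_sequence <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  df <- utils::read.csv(manifest_path)
  need <- c("frame_index", "femur_file", "patella_file")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$frame_index)) {
    stop("duplicate frame_index in manifest: ",
         df$frame_index[duplicated(df$frame_index)][1L])
  }
  if (is.unsorted(df$frame_index)) {
    warning("manifest frames not sorted; loading in frame_index order")
    df <- df[order(df$frame_index), ]
  }
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  frames <- lapply(seq_len(nrow(df)), function(i) {
    ff <- resolve(df$femur_file[i]); pf <- resolve(df$patella_file[i])
    for (p in c(ff, pf)) {
      if (!file.exists(p)) {
        stop("manifest row ", i, ": file not found: ", p)
      }
    }
    fem <- read_mesh(ff)
    if (!inherits(fem, "surface_model")) fem <- build_surface(fem)
    frame_data(df$frame_index[i], fem, read_mesh(pf),
               flexion_angle = if ("flexion_angle" %in% names(df))
                 df$flexion_angle[i] else NULL)
  })
  knee_sequence(if ("subject_id" %in% names(df)) df$subject_id[1L] else
                  tools::file_path_sans_ext(basename(manifest_path)),
                if ("side" %in% names(df)) df$side[1L] else "right",
                frames)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits per-frame femur meshes (PLY), patellar clouds (CSV), a manifest
#' CSV, a landmarks JSON, and a truth JSON (planted point, length, noise,
#' seed) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return the manifest path, invisibly.
#' @export
simulate_dataset <- function(dir, spec = synthetic_spec(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  femur <- make_femur(spec)
  seq_ <- make_motion(spec, femur, seed = seed)
  truth <- attr(seq_, "truth")
  write_ply(femur$surface, file.path(dir, "femur.ply"))
  rows <- lapply(seq_$frames, function(fr) {
    pf <- sprintf("patella_%03d.csv", fr$frame_index)
    write_xyz(fr$patella_points, file.path(dir, pf))
    data.frame(frame_index = fr$frame_index, femur_file = "femur.ply",
               patella_file = pf, flexion_angle = fr$flexion_angle,
               subject_id = seq_$subject_id, side = seq_$side)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  write_landmarks(femur$landmarks, file.path(dir, "landmarks.json"))
  jsonlite::write_json(list(P_star = truth$P_star, L_star = truth$L_star,
                            sigma = truth$sigma, seed = seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

round_to <- function(x, step = 0.05) round(x / step) * step

#' Write fit results to an output directory
#'
#' Emits `result.json` (machine precision), a coordinate-comparison CSV and
#' a per-angle MPFL% CSV (human-readable, mm values rounded to 0.05), the
#' per-frame trajectory CSV, and the configuration used. Deterministic
#' given identical inputs.
#'
#' @param fit an [fit_ipoint()] result.
#' @param dir output directory.
#' @param config optional named list recorded verbatim alongside.
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir, config = list()) {
  stopifnot(inherits(fit, "mpfl_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summary(fit)
  jsonlite::write_json(
    list(subject_id = fit$subject_id, side = fit$side,
         I_point_local = fit$I_point, S_point_local = fit$S_point,
         I_point_scanner = fit$I_point_scanner,
         objective_mm2 = fit$result$f, length_sd_mm = fit$result$length_sd,
         mean_length_mm = fit$result$mean_length,
         iterations = fit$result$iterations,
         converged = fit$result$converged,
         seeds_evaluated = fit$result$seeds_evaluated,
         config = config),
    file.path(dir, "result.json"), auto_unbox = TRUE, digits = NA)
  coords <- data.frame(
    point = c("S", "I"),
    X = round_to(c(fit$S_point[1L], fit$I_point[1L])),
    Y = round_to(c(fit$S_point[2L], fit$I_point[2L])),
    Z = round_to(c(fit$S_point[3L], fit$I_point[3L])))
  utils::write.csv(coords, file.path(dir, "coordinates.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(angle = sm$binned$angle,
                              mpfl_pct_S = round(sm$binned$S_pct, 2),
                              mpfl_pct_I = round(sm$binned$I_pct, 2)),
                   file.path(dir, "mpfl_percent.csv"), row.names = FALSE)
  traj <- fit$trajectory
  utils::write.csv(data.frame(frame = seq_len(nrow(traj$points)),
                              angle = traj$angles,
                              Cx = traj$points[, 1L],
                              Cy = traj$points[, 2L],
                              Cz = traj$points[, 3L]),
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  invisible(dir)
}

#' Run the full pipeline on a manifest or simulation
#'
#' Reads (or simulates) a sequence, fits the I-point, and writes all
#' outputs; the programmatic core of the command-line `run-all`.
#'
#' @param manifest path to a sequence manifest CSV, or `NULL` to simulate.
#' @param landmarks path to a landmark file (required with `manifest`).
#' @param out_dir output directory.
#' @param spec [synthetic_spec()] used when simulating.
#' @param seed simulation seed.
#' @param ... passed to [fit_ipoint()].
#' @return the `mpfl_fit`, invisibly.
#' @export
run_pipeline <- function(manifest = NULL, landmarks = NULL,
                         out_dir = "mpflopt-out",
                         spec = synthetic_spec(), seed = 1L, ...) {
  if (is.null(manifest)) {
    femur <- make_femur(spec)
    seq_ <- make_motion(spec, femur, seed = seed)
    lm <- femur$landmarks
  } else {
    if (is.null(landmarks)) stop("a landmark file is required with a manifest")
    seq_ <- read_sequence(manifest)
    lm <- read_landmarks(landmarks)
  }
  fit <- fit_ipoint(seq_, lm, ...)
  write_results(fit, out_dir, config = list(seed = seed))
  invisible(fit)
}
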