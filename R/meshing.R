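#' Resample a skeleton into metaball field sources
#'
#' Places field sources along the skeleton at arc-length intervals no larger
#' than `spacing`, with linearly interpolated radii; both endpoints are
#' always included.
#'
#' @param skeleton Tibble/matrix with columns x, y, z, radius.
#' @param spacing Maximum source spacing (um); default half the minimum
#'   radius.
#' @return Tibble of sources (x, y, z, r).
#' @export
resample_skeleton <- function(skeleton, spacing = NULL) {
  sk <- as.matrix(skeleton[, c("x", "y", "z", "radius")])
  if (nrow(sk) < 2) abort("skeleton must have at least 2 points")
  if (is.null(spacing)) spacing <- min(sk[, 4]) / 2
  if (spacing <= 0) abort("spacing must be positive")
  seg <- polyline_lengths(sk[, 1:3, drop = FALSE])
  keep <- seg > 1e-12
  total <- sum(seg)
  n_int <- max(1, ceiling(total / spacing))
  s <- seq(0, total, length.out = n_int + 1)
  cum <- c(0, cumsum(seg))
  idx <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1), length(seg))
  t <- ifelse(seg[idx] > 0, (s - cum[idx]) / seg[idx], 0)
  p <- sk[idx, 1:3, drop = FALSE] * (1 - t) + sk[idx + 1, 1:3, drop = FALSE] * t
  r <- sk[idx, 4] * (1 - t) + sk[idx + 1, 4] * t
  tibble(x = p[, 1], y = p[, 2], z = p[, 3], r = r)
}

#' Metaball field value
#'
#' Sum of signed compact-support kernels `K(q) = (1 - q^2)^3` for `q < 1`,
#' `q = |x - centre| / (2 r)`. The support is twice the source radius, so a
#' single isolated positive source crosses [calibrate_isolevel()]'s
#' single-source level `(3/4)^3` exactly on the sphere of its radius.
#'
#' @param x `n x 3` matrix of evaluation points.
#' @param sources Tibble/matrix of sources (x, y, z, r).
#' @param sign Signs per source (+1 fibre being meshed, -1 previously meshed
#'   fibres); recycled.
#' @return Numeric vector of field values.
#' @export
field_value <- function(x, sources, sign = 1) {
  S <- as.matrix(sources[, c("x", "y", "z", "r")])
  sign <- rep_len(sign, nrow(S))
  field_eval_cpp(S, sign, matrix(x, ncol = 3))
}

#' Isolevel calibration for a chain of sources
#'
#' For a straight chain of equal-radius sources at spacing `spacing`, returns
#' the exact field value at lateral distance `r` from the axis, so that the
#' extracted isosurface of a straight constant-radius fibre has exactly its
#' nominal radius.
#'
#' @param r Source radius (um).
#' @param spacing Source spacing along the chain (um).
#' @return Isolevel.
#' @export
calibrate_isolevel <- function(r, spacing) {
  kmax <- ceiling(sqrt(3) * r / spacing) + 1
  k <- -kmax:kmax
  d2 <- r^2 + (k * spacing)^2
  q2 <- d2 / (4 * r^2)
  sum(pmax(0, 1 - q2)^3)
}

new_fibre_mesh <- function(vertices, faces, fibre = NA_integer_,
                           bundle = NA_integer_) {
  structure(
    list(vertices = vertices, faces = faces, fibre = fibre, bundle = bundle),
    class = "fibre_mesh"
  )
}

#' @export
print.fibre_mesh <- function(x, ...) {
  cat(sprintf("<fibre_mesh> fibre %s: %d vertices, %d faces\n",
              x$fibre, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh volume (divergence theorem)
#' @param mesh A `fibre_mesh`.
#' @return Enclosed volume (um^3), positive for outward-oriented surfaces.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  sum(
    v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  ) / 6
}

#' Watertightness / manifoldness check
#'
#' @param mesh A `fibre_mesh`.
#' @return List with `closed` (every edge shared by exactly two faces),
#'   `oriented` (each undirected edge used once in each direction) and
#'   `volume`.
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  counts <- table(key)
  dir_key <- paste(he[, 1], he[, 2])
  list(
    closed = all(counts == 2),
    oriented = !anyDuplicated(dir_key),
    volume = mesh_volume(mesh)
  )
}

#' Mesh one fibre with deformation around previous fibres
#'
#' Extracts the isosurface of the fibre's positive metaball field plus the
#' negative fields of all previously meshed fibres, on a voxel grid local to
#' the fibre. The negative potentials repel the new surface so it deforms
#' around earlier fibres instead of intersecting them.
#'
#' @param skeleton Fibre skeleton (columns x, y, z, radius).
#' @param negative_sources Optional tibble of sources (x, y, z, r) from
#'   previously meshed fibres.
#' @param grid_resolution Voxel size (um); default a quarter of the fibre's
#'   minimum radius, and required to be at most half of it.
#' @param spacing Source spacing; default half the minimum radius.
#' @param iso_scale Multiplier on the calibrated isolevel.
#' @param margin Exclusion margin (in units of the prior fibres' isolevel)
#'   by which the new surface stays clear of previously meshed surfaces;
#'   the collision-retry loop in [mesh_phantom()] widens it.
#' @param fibre,bundle Identifiers stored on the mesh.
#' @return A `fibre_mesh`.
#' @export
mesh_fibre <- function(skeleton, negative_sources = NULL,
                       grid_resolution = NULL, spacing = NULL,
                       iso_scale = 1, margin = 0.1, fibre = NA_integer_,
                       bundle = NA_integer_) {
  rads <- as.matrix(skeleton)[, 4]
  # a fibre squeezed to its radius floor would demand an unaffordable grid;
  # resolution (and source spacing) are therefore clamped from below at a
  # tenth of the fibre's mean radius, trading accuracy only at pinch points
  if (is.null(spacing)) spacing <- max(min(rads) / 2, mean(rads) / 10)
  src <- resample_skeleton(skeleton, spacing)
  min_r <- min(src$r)
  user_res <- !is.null(grid_resolution)
  if (!user_res) {
    grid_resolution <- max(min_r / 4, mean(rads) / 10)
  }
  if (user_res && grid_resolution > min_r / 2 + 1e-12) {
    abort("grid_resolution must be at most half the minimum fibre radius")
  }
  # keep the marching grid affordable: coarsen (with a warning) if the
  # fibre's padded bounding box would exceed the cell budget
  bbox <- apply(as.matrix(src[, c("x", "y", "z")]), 2, range)
  span <- (bbox[2, ] - bbox[1, ]) + 2 * (2 * max(src$r) + 2 * grid_resolution)
  n_cells <- prod(pmax(2, ceiling(span / grid_resolution)))
  if (n_cells > 4e7) {
    grid_resolution <- grid_resolution * (n_cells / 4e7)^(1 / 3)
    warn(sprintf("coarsened meshing grid to %.3g um to fit the cell budget",
                 grid_resolution))
  }
  iso <- calibrate_isolevel(stats::median(src$r), spacing) * iso_scale
  S <- as.matrix(src[, c("x", "y", "z", "r")])
  group <- rep(0L, nrow(S))
  group_iso <- iso
  if (!is.null(negative_sources) && nrow(negative_sources) > 0) {
    N <- as.matrix(negative_sources[, c("x", "y", "z", "r")])
    ng <- if ("group" %in% names(negative_sources)) {
      as.integer(negative_sources$group)
    } else {
      rep(1L, nrow(N))
    }
    niso <- if ("iso" %in% names(negative_sources)) {
      negative_sources$iso
    } else {
      # isolevel of the prior fibres estimated from their own source layout
      d <- sqrt(rowSums((N[-1, 1:3, drop = FALSE] -
                           N[-nrow(N), 1:3, drop = FALSE])^2))
      rep(calibrate_isolevel(stats::median(N[, 4]),
                             stats::median(d[d > 1e-9])), nrow(N))
    }
    S <- rbind(S, N)
    group <- c(group, ng)
    # isolevel per group id (group 0 first)
    iso_by_group <- c(`0` = iso, tapply(niso, ng, function(v) v[1]))
    group_iso <- as.numeric(iso_by_group[as.character(0:max(ng))])
    group_iso[is.na(group_iso)] <- iso
  }
  m <- march_deform_cpp(S, group, group_iso, margin = margin, grid_resolution,
                        pad = 2 * grid_resolution, refine_iters = 14L)
  if (nrow(m$vertices) == 0) {
    abort(sprintf("fibre %s was annihilated by the negative field", fibre))
  }
  mesh <- new_fibre_mesh(m$vertices, m$faces, fibre, bundle)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh$iso <- iso
  mesh
}

#' Count intersecting triangle pairs between two meshes
#'
#' @param mesh1,mesh2 `fibre_mesh` objects.
#' @param max_count Early-exit cap.
#' @return Number of intersecting triangle pairs found (capped).
#' @export
mesh_collision_count <- function(mesh1, mesh2, max_count = 1e9) {
  tri_tri_count_cpp(mesh1$vertices, mesh1$faces, mesh2$vertices, mesh2$faces,
                    as.integer(min(max_count, .Machine$integer.max)))
}

#' Mesh a whole phantom into pairwise non-intersecting surfaces
#'
#' Fibres are meshed one-by-one in growth order; each fibre sees every
#' previously meshed fibre's sources with negative sign, so its surface
#' deforms around them. After extraction each mesh is checked against the
#' previous meshes with an exact triangle-pair test; residual discretisation
#' contacts trigger a retry at a slightly raised isolevel (shrinking the new
#' fibre within grid tolerance).
#'
#' @param phantom A `phantom` with completed fibres.
#' @param grid_resolution Voxel size (um); default a quarter of the phantom's
#'   minimum realised radius.
#' @param spacing Source spacing (um); default half the minimum radius.
#' @param max_retries Isolevel retries per fibre.
#' @param verbose Print progress?
#' @return A `phantom_mesh` object: list of `fibre_mesh` plus a tibble of
#'   failures (empty when all fibres meshed).
#' @export
mesh_phantom <- function(phantom, grid_resolution = NULL, spacing = NULL,
                         max_retries = 4, verbose = FALSE) {
  comp <- phantom$fibres[phantom$fibres$status == "complete", ]
  if (nrow(comp) == 0) abort("phantom has no completed fibres")
  order_idx <- phantom$growth_order %||% comp$fibre
  order_idx <- order_idx[order_idx %in% comp$fibre]

  meshes <- list()
  neg <- NULL
  failures <- list()
  for (fi in order_idx) {
    row <- comp[comp$fibre == fi, ]
    sk <- row$skeleton[[1]]
    res <- tryCatch({
      mesh <- NULL
      for (attempt in 0:max_retries) {
        mesh <- mesh_fibre(sk, neg, grid_resolution, spacing,
                           margin = 0.1 * 1.6^attempt, fibre = fi,
                           bundle = row$bundle)
        n_hit <- 0
        for (prev in meshes) {
          n_hit <- n_hit + mesh_collision_count(prev, mesh, max_count = 1)
          if (n_hit > 0) break
        }
        if (n_hit == 0) break
      }
      if (n_hit > 0) stop("unresolved mesh intersection")
      mesh
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble(fibre = fi,
                                                 reason = conditionMessage(res))
      next
    }
    meshes[[length(meshes) + 1]] <- res
    rads <- sk$radius
    sp_f <- spacing %||% max(min(rads) / 2, mean(rads) / 10)
    src <- resample_skeleton(sk, sp_f)
    src$group <- length(meshes)  # this fibre's exclusion group id
    src$iso <- res$iso
    neg <- if (is.null(neg)) src else bind_rows(neg, src)
    if (verbose) message(sprintf("meshed fibre %d (%d faces)", fi, nrow(res$faces)))
  }
  structure(
    list(
      meshes = meshes,
      failures = if (length(failures)) bind_rows(failures) else
        tibble(fibre = integer(0), reason = character(0)),
      grid_resolution = grid_resolution,
      spacing = spacing
    ),
    class = "phantom_mesh"
  )
}

#' @export
print.phantom_mesh <- function(x, ...) {
  cat(sprintf("<phantom_mesh> %d meshes (%d failures), voxel %.3g um\n",
              length(x$meshes), nrow(x$failures), x$grid_resolution))
  invisible(x)
}

#' Exhaustive pairwise collision check
#'
#' @param phantom_mesh A `phantom_mesh` (or list of `fibre_mesh`).
#' @return Total number of intersecting triangle pairs over all mesh pairs.
#' @export
phantom_collisions <- function(phantom_mesh) {
  meshes <- if (inherits(phantom_mesh, "phantom_mesh")) phantom_mesh$meshes else phantom_mesh
  total <- 0
  if (length(meshes) < 2) return(0)
  for (i in seq_len(length(meshes) - 1)) {
    for (j in (i + 1):length(meshes)) {
      total <- total + mesh_collision_count(meshes[[i]], meshes[[j]])
    }
  }
  total
}

# ---------------- PLY I/O ----------------

#' Write meshes to binary little-endian PLY
#'
#' Writes one PLY per fibre plus an optional merged PLY and a JSON manifest
#' mapping files to fibre/bundle identifiers.
#'
#' @param meshes A `phantom_mesh`, list of `fibre_mesh`, or single mesh.
#' @param path Output directory (created if needed).
#' @param merged Also write a merged `phantom.ply`?
#' @return Character vector of files written, invisibly.
#' @export
write_ply <- function(meshes, path, merged = TRUE) {
  if (inherits(meshes, "phantom_mesh")) meshes <- meshes$meshes
  if (inherits(meshes, "fibre_mesh")) meshes <- list(meshes)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  manifest <- list()
  for (m in meshes) {
    id <- if (is.na(m$fibre)) length(files) + 1 else m$fibre
    fn <- file.path(path, sprintf("fibre_%04d.ply", as.integer(id)))
    write_ply_one(m$vertices, m$faces, fn)
    files <- c(files, fn)
    manifest[[basename(fn)]] <- list(fibre = m$fibre, bundle = m$bundle)
  }
  if (merged && length(meshes) > 1) {
    off <- 0
    V <- list()
    F <- list()
    for (m in meshes) {
      V[[length(V) + 1]] <- m$vertices
      F[[length(F) + 1]] <- m$faces + off
      off <- off + nrow(m$vertices)
    }
    fn <- file.path(path, "phantom.ply")
    write_ply_one(do.call(rbind, V), do.call(rbind, F), fn)
    files <- c(files, fn)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

write_ply_one <- function(V, F, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "ply",
    "format binary_little_endian 1.0",
    sprintf("element vertex %d", nrow(V)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(F)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  writeLines(header, con, sep = "\n")
  writeBin(as.numeric(t(V)), con, size = 4, endian = "little")
  face_block <- t(cbind(3L, F - 1L))
  for (i in seq_len(nrow(F))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a PLY mesh (binary little-endian or ASCII)
#'
#' @param path PLY file path.
#' @return A `fibre_mesh`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, 1)
    header <- c(header, ln)
    if (identical(ln, "end_header")) break
    if (length(header) > 200) abort("invalid PLY header")
  }
  if (header[1] != "ply") abort("not a PLY file")
  fmt <- header[grepl("^format", header)][1]
  nv <- as.integer(sub("element vertex ", "", header[grepl("^element vertex", header)][1]))
  nf <- as.integer(sub("element face ", "", header[grepl("^element face", header)][1]))
  if (grepl("ascii", fmt)) {
    txt <- readLines(con)
    Vl <- do.call(rbind, lapply(txt[seq_len(nv)], function(s) {
      as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])
    }))
    Fl <- do.call(rbind, lapply(txt[nv + seq_len(nf)], function(s) {
      as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4])
    }))
    return(new_fibre_mesh(Vl, Fl + 1L))
  }
  V <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4, endian = "little"),
              ncol = 3, byrow = TRUE)
  F <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    k <- as.integer(readBin(con, "raw", 1))
    F[i, ] <- readBin(con, "integer", n = k, size = 4, endian = "little")[1:3]
  }
  new_fibre_mesh(V, F + 1L)
}
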