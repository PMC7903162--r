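# ---------------- triangulated sphere ----------------

#' Icosphere (subdivided icosahedron)
#'
#' The icosahedron is centrally symmetric, and midpoint subdivision preserves
#' that symmetry, so faces come in exact antipodal pairs -- the property the
#' orientation histogram relies on.
#'
#' @param level Subdivision level; level 3 gives 1280 faces.
#' @return List with `vertices` (unit rows) and `faces` (1-based).
#' @export
icosphere <- function(level = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (l in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(V)
    Vl <- list(V)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1
      Vl[[length(Vl) + 1]] <<- p
      mid_cache[[key]] <- nv
      nv
    }
    newF <- matrix(0L, 4 * nrow(F), 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c_, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, c(list(Vl[[1]]), lapply(Vl[-1], rbind)))
    F <- newF
  }
  list(vertices = V, faces = F)
}

# solid angle of a spherical triangle (Van Oosterom & Strackee)
spherical_triangle_solid_angle <- function(a, b, c_) {
  num <- a[1] * (b[2] * c_[3] - b[3] * c_[2]) -
    a[2] * (b[1] * c_[3] - b[3] * c_[1]) +
    a[3] * (b[1] * c_[2] - b[2] * c_[1])
  den <- 1 + sum(a * b) + sum(b * c_) + sum(a * c_)
  2 * abs(atan2(num, den))
}

# ---------------- orientation distribution ----------------

#' Orientation histogram on a triangulated sphere
#'
#' Bins segment directions onto the faces of an icosphere; every direction
#' is projected forwards and backwards (each count is mirrored onto the
#' exact antipodal face), so the histogram is antipodally symmetric by
#' construction. Face densities are normalised per steradian so that the
#' histogram integrates to 1 over the sphere.
#'
#' @param directions `n x 3` matrix of segment directions (any norm).
#' @param weights Optional per-segment weights (e.g. segment lengths);
#'   default unweighted counting.
#' @param level Icosphere subdivision level (default 3, 1280 faces).
#' @return An `orientation_histogram`: tibble with face index, centroid,
#'   count, solid angle and density (sr^-1).
#' @export
orientation_histogram <- function(directions, weights = NULL, level = 3) {
  directions <- matrix(directions, ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  keep <- nrm > 1e-12
  directions <- directions[keep, , drop = FALSE] / nrm[keep]
  if (nrow(directions) == 0) abort("no non-zero directions")
  w <- if (is.null(weights)) rep(1, nrow(directions)) else weights[keep]
  sph <- icosphere(level)
  V <- sph$vertices
  F <- sph$faces
  nf <- nrow(F)
  cent <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  cent <- cent / sqrt(rowSums(cent^2))
  # exact antipodal face pairing through centroid matching
  anti <- vapply(seq_len(nf), function(f) {
    which.max(-cent %*% cent[f, ])
  }, integer(1))
  fi <- bin_directions_cpp(directions, V[F[, 1], , drop = FALSE],
                           V[F[, 2], , drop = FALSE], V[F[, 3], , drop = FALSE])
  counts <- numeric(nf)
  cadd <- rowsum(c(w, w), c(fi, anti[fi]))
  counts[as.integer(rownames(cadd))] <- cadd[, 1]
  omega <- vapply(seq_len(nf), function(f) {
    spherical_triangle_solid_angle(V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
  }, numeric(1))
  dens <- counts / (sum(counts) * omega)
  out <- tibble(
    face = seq_len(nf),
    nx = cent[, 1], ny = cent[, 2], nz = cent[, 3],
    count = counts, solid_angle = omega, density = dens,
    antipode = as.integer(anti)
  )
  class(out) <- c("orientation_histogram", class(out))
  attr(out, "level") <- level
  attr(out, "n_segments") <- nrow(directions)
  out
}

#' Angle-from-axis statistics of segment directions
#'
#' Folds every direction into `[0, 90]` degrees from the reference axis
#' (axial data) and returns the mean and standard deviation.
#'
#' @param directions `n x 3` matrix of directions.
#' @param axis Reference axis (default z).
#' @return List with `mu_theta`, `sigma_theta` (degrees) and `n`.
#' @export
orientation_stats <- function(directions, axis = c(0, 0, 1)) {
  directions <- matrix(directions, ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  keep <- nrm > 1e-12
  d <- directions[keep, , drop = FALSE] / nrm[keep]
  if (nrow(d) < 1) abort("need at least one non-zero direction")
  axis <- unitize(axis)
  ct <- pmin(1, abs(drop(d %*% axis)))
  theta <- acos(ct) * 180 / pi
  list(mu_theta = mean(theta), sigma_theta = stats::sd(theta), n = length(theta))
}

# segment directions (and lengths) of a centre line or skeleton
segment_directions <- function(pts) {
  pts <- as.matrix(pts)
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  keep <- len > 1e-12
  list(directions = d[keep, , drop = FALSE] / len[keep], lengths = len[keep])
}

#' Segment directions of all completed fibres in a phantom
#'
#' With `smooth_window` set, each skeleton is resampled at a fine fixed
#' spacing and boxcar-smoothed over that arc-length window before taking
#' segment directions. This approximates the mesh centre-line measurement
#' (the metaball surface smooths the discrete skeleton at the radius
#' scale) without meshing; a window of about three mean radii reproduces
#' mesh-derived angle statistics closely.
#'
#' @param phantom A `phantom`.
#' @param smooth_window Arc-length smoothing window (um); `NULL` for raw
#'   skeleton segments.
#' @return List with `directions` (matrix) and `lengths`.
#' @export
phantom_segment_directions <- function(phantom, smooth_window = NULL) {
  sks <- phantom_skeletons(phantom)
  parts <- lapply(sks, function(s) {
    if (is.null(smooth_window)) return(segment_directions(s[, 1:3]))
    sm <- smooth_polyline(s, smooth_window)
    if (is.null(sm)) return(NULL)
    segment_directions(sm)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  list(
    directions = do.call(rbind, lapply(parts, `[[`, "directions")),
    lengths = unlist(lapply(parts, `[[`, "lengths"))
  )
}

# resample a skeleton at fine spacing and boxcar-smooth positions over an
# arc-length window; returns a point matrix (or NULL when too short)
smooth_polyline <- function(sk, window, spacing = 0.1) {
  sk <- as.matrix(sk)
  colnames(sk)[1:4] <- c("x", "y", "z", "radius")
  src <- resample_skeleton(sk, spacing = spacing)
  P <- as.matrix(src[, c("x", "y", "z")])
  k <- max(1, round(window / spacing))
  if (k %% 2 == 0) k <- k + 1
  if (nrow(P) <= k + 2) return(NULL)
  Ps <- apply(P, 2, function(v) stats::filter(v, rep(1 / k, k), sides = 2))
  Ps <- Ps[!is.na(Ps[, 1]), , drop = FALSE]
  if (nrow(Ps) < 3) return(NULL)
  Ps
}

# ---------------- centre lines and diameter profiles ----------------

#' Extract a fibre centre line from its mesh
#'
#' Rotates the mesh so its end-to-end vector aligns with z, takes `n_slices`
#' equidistant cross-sections, connects their area-weighted centroids, and
#' rotates back. Empty slices (possible for severely bent fibres) are
#' interpolated from their neighbours with a warning.
#'
#' @param mesh A `fibre_mesh`.
#' @param n_slices Number of slices (default 100).
#' @param ends Optional 2 x 3 matrix of fibre end points; default the two
#'   most distant mesh vertices (double-sweep heuristic).
#' @return A `centre_line` tibble (x, y, z) with the slice spacing and
#'   source fibre recorded as attributes.
#' @export
extract_centreline <- function(mesh, n_slices = 100, ends = NULL) {
  if (n_slices < 2) abort("need at least 2 slices")
  V <- mesh$vertices
  if (is.null(ends)) {
    ctr <- colMeans(V)
    i1 <- which.max(rowSums(sweep(V, 2, ctr)^2))
    i2 <- which.max(rowSums(sweep(V, 2, V[i1, ])^2))
    ends <- rbind(V[i2, ], V[i1, ])
  }
  axis <- unitize(ends[2, ] - ends[1, ])
  R <- rotation_between(axis, c(0, 0, 1))
  Vr <- V %*% t(R)
  mr <- new_fibre_mesh(Vr, mesh$faces)
  zr <- range(Vr[, 3])
  zs <- seq(zr[1], zr[2], length.out = n_slices + 2)[-c(1, n_slices + 2)]
  cents <- matrix(NA_real_, n_slices, 3)
  for (k in seq_len(n_slices)) {
    loops <- slice_mesh_cpp(Vr, mesh$faces, c(0, 0, zs[k]), c(0, 0, 1))
    if (length(loops) == 0) next
    atot <- 0
    cacc <- c(0, 0)
    for (L in loops) {
      a <- shoelace_area(L[, 1], L[, 2])
      cc <- polygon_centroid_2d(L[, 1], L[, 2])
      atot <- atot + a
      cacc <- cacc + a * cc
    }
    if (atot > 0) cents[k, ] <- c(cacc / atot, zs[k])
  }
  missing <- which(is.na(cents[, 1]))
  if (length(missing)) {
    warn(sprintf("%d empty cross-sections interpolated", length(missing)))
    okk <- which(!is.na(cents[, 1]))
    if (length(okk) < 2) abort("too few non-empty cross-sections")
    for (j in 1:2) {
      cents[missing, j] <- stats::approx(zs[okk], cents[okk, j], xout = zs[missing],
                                         rule = 2)$y
    }
    cents[missing, 3] <- zs[missing]
  }
  out_pts <- cents %*% R  # rotate back (R orthogonal)
  cl <- tibble(x = out_pts[, 1], y = out_pts[, 2], z = out_pts[, 3])
  class(cl) <- c("centre_line", class(cl))
  attr(cl, "fibre") <- mesh$fibre
  attr(cl, "axis") <- axis
  cl
}

#' Equivalent-diameter profile along a fibre
#'
#' Cuts the mesh with a plane perpendicular to each centre-line segment
#' through the segment midpoint; the cross-section area `A` gives the
#' circle-equivalent diameter `d = 2 sqrt(A / pi)`.
#'
#' @param mesh A `fibre_mesh`.
#' @param centreline A `centre_line` from [extract_centreline()] (computed if
#'   missing).
#' @return Tibble (segment, area, diameter) with the per-fibre coefficient
#'   of variation in attribute `"cv"`.
#' @export
diameter_profile <- function(mesh, centreline = NULL) {
  if (is.null(centreline)) centreline <- extract_centreline(mesh)
  pts <- as.matrix(centreline[, c("x", "y", "z")])
  seg <- segment_directions(pts)
  mids <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
  mids <- mids[polyline_lengths(pts) > 1e-12, , drop = FALSE]
  n <- nrow(seg$directions)
  area <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    loops <- slice_mesh_cpp(mesh$vertices, mesh$faces, mids[k, ], seg$directions[k, ])
    if (length(loops) == 0) next
    # keep the loop whose centroid is closest to the centre-line midpoint
    best <- NULL
    bd <- Inf
    B <- perp_basis(seg$directions[k, ])
    for (L in loops) {
      uv <- sweep(L, 2, mids[k, ]) %*% B
      cc2 <- polygon_centroid_2d(uv[, 1], uv[, 2])
      d <- sqrt(sum(cc2^2))
      if (d < bd) {
        bd <- d
        best <- shoelace_area(uv[, 1], uv[, 2])
      }
    }
    area[k] <- best
  }
  if (anyNA(area)) {
    warn(sprintf("%d slice planes missed the mesh", sum(is.na(area))))
  }
  d <- 2 * sqrt(area / pi)
  out <- tibble(segment = seq_len(n), area = area, diameter = d)
  attr(out, "cv") <- stats::sd(d, na.rm = TRUE) / mean(d, na.rm = TRUE)
  attr(out, "fibre") <- mesh$fibre
  out
}

# ---------------- density ----------------

#' Fibre volume fraction from meshes
#'
#' Voxelises the union of all meshes over a box region of interest; a voxel
#' counts as occupied when its centre lies inside any mesh.
#'
#' @param meshes A `phantom_mesh` or list of `fibre_mesh`.
#' @param roi List with `lo` and `hi` (3-vectors, um).
#' @param voxel Voxel edge (um).
#' @return Fibre volume fraction in `[0, 1]`.
#' @export
measure_density <- function(meshes, roi, voxel = 0.1) {
  if (inherits(meshes, "phantom_mesh")) meshes <- meshes$meshes
  if (inherits(meshes, "fibre_mesh")) meshes <- list(meshes)
  if (length(meshes) == 0) return(0)
  all_r <- NULL
  n <- pmax(1L, as.integer(floor((roi$hi - roi$lo) / voxel)))
  occ <- rep(FALSE, prod(n))
  for (m in meshes) {
    occ <- occ | mesh_occupancy_cpp(m$vertices, m$faces, roi$lo, voxel,
                                    n[1], n[2], n[3])
  }
  mean(occ)
}

#' Fibre volume fraction from skeletons (capsule model)
#'
#' Fast density estimate from the capsule-chain representation, used by the
#' experiment harnesses where meshing every phantom would dominate runtime.
#'
#' @param phantom A `phantom`.
#' @param roi Region of interest (`lo`/`hi`); default the central box with
#'   `shrink` of the region's linear size.
#' @param voxel Voxel edge (um).
#' @param shrink Linear shrink factor for the default central ROI.
#' @return Fibre volume fraction in `[0, 1]`.
#' @export
capsule_density <- function(phantom, roi = NULL, voxel = 0.1, shrink = 0.75) {
  sks <- phantom_skeletons(phantom)
  if (length(sks) == 0) return(0)
  L <- phantom$config$region_size
  if (is.null(roi)) {
    c0 <- L / 2
    half <- L * shrink / 2
    roi <- list(lo = c0 - half, hi = c0 + half)
  }
  res <- capsules_density_grid(unname(sks), roi$lo, roi$hi, voxel)
  res[1]
}

# ---------------- virtual histology ----------------

#' Virtual histology slice
#'
#' Intersects every mesh with a cutting plane and rasterises the resulting
#' per-axon polygons into a labelled image (background 0, one label per
#' fibre).
#'
#' @param meshes A `phantom_mesh` or list of `fibre_mesh`.
#' @param point A point on the cutting plane.
#' @param normal Plane normal.
#' @param resolution In-plane pixel size (um); default 0.005 (5 nm).
#' @param extent Optional half-extent (um) of the imaged square; default
#'   covers all intersections.
#' @return A `histology_slice`: list with `image` (integer matrix, rows = y),
#'   `polygons` (tibble of 2D loops per label), `pixel_size`, `origin`,
#'   `point`, `normal`.
#' @export
virtual_histology_slice <- function(meshes, point, normal,
                                    resolution = 0.005, extent = NULL) {
  if (inherits(meshes, "phantom_mesh")) meshes <- meshes$meshes
  normal <- unitize(normal)
  B <- perp_basis(normal)
  polys <- list()
  labels <- integer(0)
  rows <- list()
  for (mi in seq_along(meshes)) {
    m <- meshes[[mi]]
    loops <- slice_mesh_cpp(m$vertices, m$faces, point, normal)
    lab <- if (!is.na(m$fibre)) as.integer(m$fibre) else mi
    for (L in loops) {
      uv <- sweep(L, 2, point) %*% B
      polys[[length(polys) + 1]] <- uv
      labels <- c(labels, lab)
      rows[[length(rows) + 1]] <- tibble(
        label = lab, loop = length(polys),
        u = uv[, 1], v = uv[, 2]
      )
    }
  }
  if (length(polys) == 0) {
    warn("cutting plane does not intersect any mesh")
    return(structure(list(
      image = matrix(0L, 0, 0), polygons = tibble(),
      pixel_size = resolution, origin = c(0, 0),
      point = point, normal = normal
    ), class = "histology_slice"))
  }
  allu <- unlist(lapply(polys, function(p) p[, 1]))
  allv <- unlist(lapply(polys, function(p) p[, 2]))
  if (is.null(extent)) {
    x0 <- min(allu) - 2 * resolution
    y0 <- min(allv) - 2 * resolution
    x1 <- max(allu) + 2 * resolution
    y1 <- max(allv) + 2 * resolution
  } else {
    x0 <- -extent; y0 <- -extent; x1 <- extent; y1 <- extent
  }
  nx <- max(1L, as.integer(ceiling((x1 - x0) / resolution)))
  ny <- max(1L, as.integer(ceiling((y1 - y0) / resolution)))
  if (as.double(nx) * ny > 4e8) abort("histology image too large; lower the resolution")
  img <- raster_polygons_cpp(polys, labels, x0, y0, resolution, nx, ny)
  structure(list(
    image = img, polygons = bind_rows(rows),
    pixel_size = resolution, origin = c(x0, y0),
    point = point, normal = normal
  ), class = "histology_slice")
}

#' @export
print.histology_slice <- function(x, ...) {
  cat(sprintf("<histology_slice> %d x %d px at %.3g um, %d axon loops\n",
              ncol(x$image), nrow(x$image), x$pixel_size,
              length(unique(x$polygons$loop))))
  invisible(x)
}

# minimum enclosing circle (Welzl, on convex hull points)
min_enclosing_circle <- function(pts) {
  hull <- grDevices::chull(pts)
  P <- pts[hull, , drop = FALSE]
  circ2 <- function(a, b) {
    c((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c_) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c_[1]; cy <- c_[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(c(0, 0, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circle, p) {
    sqrt(sum((p - circle[1:2])^2)) <= circle[3] + 1e-9
  }
  n <- nrow(P)
  if (n == 1) return(c(P[1, ], 0))
  circle <- circ2(P[1, ], P[2, ])
  for (i in seq_len(n)) {
    if (inside(circle, P[i, ])) next
    circle <- c(P[i, ], 0)
    for (j in seq_len(i - 1)) {
      if (inside(circle, P[j, ])) next
      circle <- circ2(P[i, ], P[j, ])
      for (k in seq_len(j - 1)) {
        if (inside(circle, P[k, ])) next
        circle <- circ3(P[i, ], P[j, ], P[k, ])
      }
    }
  }
  circle
}

# separable boxcar smoothing of a 0/1 mask; removes the staircase bias of
# marching-squares boundaries (pixel-edge perimeters overestimate smooth
# outlines by up to ~5%, which circularity squares)
smooth_mask <- function(m, k = 3) {
  kern <- rep(1 / k, k)
  sm <- apply(m, 2, function(v) stats::filter(v, kern, sides = 2))
  sm[is.na(sm)] <- 0
  sm <- t(apply(sm, 1, function(v) stats::filter(v, kern, sides = 2)))
  sm[is.na(sm)] <- 0
  sm
}

# sub-pixel boundary of one label via marching-squares contouring
label_contour <- function(img, label, origin, px) {
  idx <- which(img == label, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 3L)
  r1 <- min(nrow(img), max(idx[, 1]) + 3L)
  c0 <- max(1L, min(idx[, 2]) - 3L)
  c1 <- min(ncol(img), max(idx[, 2]) + 3L)
  sub <- smooth_mask((img[r0:r1, c0:c1] == label) * 1)
  # contourLines treats x as rows; here rows index v (y) and cols index u (x)
  ys <- origin[2] + (seq(r0, r1) - 0.5) * px
  xs <- origin[1] + (seq(c0, c1) - 0.5) * px
  cl <- grDevices::contourLines(ys, xs, sub, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  areas <- vapply(cl, function(cc) shoelace_area(cc$y, cc$x), numeric(1))
  main <- cl[[which.max(areas)]]
  cbind(x = main$y, y = main$x)  # back to (u, v) order
}

#' Slice-wise shape metrics
#'
#' Per-axon morphometrics of a labelled virtual-histology image:
#' circularity `4 pi A / P^2`, convexity `A / A_hull`, eccentricity of the
#' moment-equivalent ellipse, and `A / (pi r_max^2)` with `r_max` the
#' minimum-enclosing-circle radius. Area and perimeter come from a sub-pixel
#' traced boundary polygon, which removes most of the pixel-edge bias that
#' plagues circularity estimates. Axons touching the image edge are excluded
#' (their truncation would skew every metric).
#'
#' @param slice A `histology_slice`, or a labelled integer matrix.
#' @param pixel_size Pixel size (um) when a bare matrix is given.
#' @param keep_edge Keep edge-touching axons (flagged) instead of dropping
#'   them?
#' @param min_pixels Regions smaller than this are excluded.
#' @return Tibble of per-axon metrics.
#' @export
slice_morphometrics <- function(slice, pixel_size = NULL, keep_edge = FALSE,
                                min_pixels = 5) {
  if (inherits(slice, "histology_slice")) {
    img <- slice$image
    px <- slice$pixel_size
    origin <- slice$origin
  } else {
    img <- slice
    px <- pixel_size %||% 1
    origin <- c(0, 0)
  }
  labs <- setdiff(sort(unique(as.vector(img))), 0L)
  if (length(labs) == 0) abort("labelled image contains no axons")
  out <- list()
  for (lab in labs) {
    mask_idx <- which(img == lab, arr.ind = TRUE)
    npx <- nrow(mask_idx)
    touches <- any(mask_idx[, 1] %in% c(1L, nrow(img))) ||
      any(mask_idx[, 2] %in% c(1L, ncol(img)))
    if (npx < min_pixels) {
      warn(sprintf("label %d has fewer than %d pixels; excluded", lab, min_pixels))
      next
    }
    contour <- label_contour(img, lab, origin, px)
    if (is.null(contour) || nrow(contour) < 4) next
    A <- shoelace_area(contour[, 1], contour[, 2])
    Pm <- sum(sqrt(rowSums((contour - rbind(contour[-1, , drop = FALSE],
                                            contour[1, , drop = FALSE]))^2)))
    hull <- grDevices::chull(contour)
    A_hull <- shoelace_area(contour[hull, 1], contour[hull, 2])
    # eccentricity from central second moments of the pixel region
    xs <- origin[1] + (mask_idx[, 2] - 0.5) * px
    ys <- origin[2] + (mask_idx[, 1] - 0.5) * px
    mxx <- stats::var(xs) + px^2 / 12
    myy <- stats::var(ys) + px^2 / 12
    mxy <- stats::cov(xs, ys)
    tr <- mxx + myy
    det_ <- mxx * myy - mxy^2
    l1 <- tr / 2 + sqrt(pmax(0, tr^2 / 4 - det_))
    l2 <- tr / 2 - sqrt(pmax(0, tr^2 / 4 - det_))
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    mec <- min_enclosing_circle(contour)
    out[[length(out) + 1]] <- tibble(
      label = lab,
      area = A,
      perimeter = Pm,
      circularity = 4 * pi * A / Pm^2,
      convexity = A / A_hull,
      eccentricity = ecc,
      area_ratio = unname(A / (pi * mec[3]^2)),
      touches_edge = touches
    )
  }
  res <- bind_rows(out)
  if (!keep_edge) res <- res[!res$touches_edge, , drop = FALSE]
  res
}
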