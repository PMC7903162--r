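# face geometry helpers: map 2D face coordinates into 3D and back
face_axes <- function(face) {
  # returns list(normal_axis, inward sign, in-plane axes)
  ax <- match(substr(face, 1, 1), c("x", "y", "z"))
  sign <- if (substr(face, 2, 2) == "-") 1 else -1
  inplane <- setdiff(1:3, ax)
  list(axis = ax, inward = sign, u = inplane[1], v = inplane[2])
}

face_point_3d <- function(face, uv, region_size) {
  fa <- face_axes(face)
  uv <- matrix(uv, ncol = 2)
  p <- matrix(0, nrow(uv), 3)
  p[, fa$axis] <- if (fa$inward > 0) 0 else region_size[fa$axis]
  p[, fa$u] <- uv[, 1]
  p[, fa$v] <- uv[, 2]
  p
}

# first exit of ray start + s * dir from the box [0, L]
ray_box_exit <- function(start, dir, L) {
  s_exit <- Inf
  for (k in 1:3) {
    if (abs(dir[k]) < 1e-12) next
    for (bound in c(0, L[k])) {
      s <- (bound - start[k]) / dir[k]
      if (s > 1e-9) s_exit <- min(s_exit, s)
    }
  }
  if (!is.finite(s_exit)) return(NULL)
  start + s_exit * dir
}

#' Generate fibre seeds from a growth configuration
#'
#' For each bundle, circles with the configured radius distribution are
#' packed on the bundle's entry face up to its target density; each packed
#' circle becomes a fibre start point with target diameter equal to the
#' packed circle's diameter. A direction drawn from the bundle's orientation
#' distribution projects each start point onto the region boundary to give
#' the fibre's target point.
#'
#' @param config A [growth_config()].
#' @return A tibble with one row per fibre seed: start and target
#'   coordinates, target diameter `d0`, and `bundle`.
#' @export
make_fibre_seeds <- function(config) {
  region <- config$region_size
  seeds <- list()
  for (b in config$bundles) {
    fa <- face_axes(b$entry_face)
    face_size <- region[c(fa$u, fa$v)]
    rho <- b$density %||% config$target_density
    disp <- b$dispersion %||% list(
      model = config$dispersion_model,
      kappa = config$watson_kappa,
      esag_mu = config$esag_mu,
      esag_gamma = config$esag_gamma
    )
    radii <- with_stage_seed(config$master_seed, 11 + 7 * b$bundle_index, {
      n_guess <- ceiling(2 * rho * prod(face_size) / (pi * config$radius_mean^2))
      sample_radii(config$radius_mean, config$radius_std, max(n_guess, 8))
    })
    pk <- with_stage_seed(config$master_seed, 12 + 7 * b$bundle_index, {
      pack_circles_2d(radii, face_size, rho)
    })
    n <- nrow(pk)
    starts <- face_point_3d(b$entry_face, cbind(pk$x, pk$y), region)
    axis <- b$mean_direction
    targets <- matrix(NA_real_, n, 3)
    with_stage_seed(config$master_seed, 13 + 7 * b$bundle_index, {
      for (i in seq_len(n)) {
        for (try in 1:100) {
          dir <- switch(disp$model,
            parallel = axis,
            watson = drop(sample_watson(disp$kappa, axis, 1)),
            esag = drop(sample_esag(disp$esag_mu, disp$esag_gamma, 1))
          )
          # orient into the region through the entry face
          nrm_comp <- dir[fa$axis] * fa$inward
          if (disp$model != "parallel" && nrm_comp < 0) dir <- -dir
          if (abs(dir[fa$axis]) < 1e-6) next  # parallel to the face: resample
          tp <- ray_box_exit(starts[i, ], dir, region)
          if (!is.null(tp)) {
            targets[i, ] <- tp
            break
          }
        }
      }
    })
    ok <- !is.na(targets[, 1])
    seeds[[length(seeds) + 1]] <- tibble(
      start_x = starts[ok, 1], start_y = starts[ok, 2], start_z = starts[ok, 3],
      target_x = targets[ok, 1], target_y = targets[ok, 2], target_z = targets[ok, 3],
      d0 = 2 * pk$r[ok],
      bundle = b$bundle_index
    )
  }
  out <- bind_rows(seeds)
  attr(out, "config") <- config
  out
}

#' Generate the pseudorandom growth-node cloud
#'
#' Scatters `n` points uniformly in the growth region padded on every side,
#' so that fibres near the boundary still have candidate nodes.
#'
#' @param region List with `lo` and `hi` (3-vectors, um) or a
#'   [growth_config()].
#' @param n Number of nodes (at least 4, up to 1e7).
#' @param seed Optional integer seed.
#' @param padding Padding (um) added on every side.
#' @return `n x 3` matrix of node positions.
#' @export
generate_growth_nodes <- function(region, n, seed = NULL, padding = 0) {
  if (inherits(region, "growth_config")) {
    padding <- region$node_padding
    region <- region_box(region)
  }
  if (n < 4) abort("need at least 4 nodes to triangulate")
  if (!is.null(seed)) set.seed(seed)
  lo <- region$lo - padding
  hi <- region$hi + padding
  cbind(
    runif(n, lo[1], hi[1]),
    runif(n, lo[2], hi[2]),
    runif(n, lo[3], hi[3])
  )
}

#' Export fibre seeds as CSV
#'
#' @param seeds Tibble from [make_fibre_seeds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seeds_csv <- function(seeds, path) {
  utils::write.csv(as.data.frame(seeds), path, row.names = FALSE)
  invisible(path)
}
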