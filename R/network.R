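#' Build the Delaunay growth network
#'
#' Connects the growth nodes by the edges of their 3D Delaunay
#' tetrahedralisation. Each node carries the maximum sustainable fibre
#' diameter `dc` (infinite until some fibre comes within the tracking
#' cutoff), the index `bc` of the bundle that set it, and an occupancy flag.
#'
#' @param points `n x 3` matrix of node positions (n >= 4, non-degenerate).
#' @param region Optional list with `lo`/`hi` bounds (defaults to the point
#'   bounding box).
#' @param track_radius Clearance tracking cutoff (um).
#' @param grid_cell Spatial-hash cell size (um) for clearance queries.
#' @return A `growth_network` object.
#' @export
build_network <- function(points, region = NULL, track_radius = 6,
                          grid_cell = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 4) abort("need at least 4 points to triangulate")
  if (qr(sweep(points[-1, , drop = FALSE], 2, points[1, ]))$rank < 3 &&
      nrow(points) <= 50) {
    abort("points are coplanar; cannot build a 3D triangulation")
  }
  if (is.null(region)) {
    region <- list(lo = apply(points, 2, min), hi = apply(points, 2, max))
  }
  if (is.null(grid_cell)) {
    span <- max(region$hi - region$lo)
    grid_cell <- max(span / 24, 0.5)
  }
  ptr <- ge_new(points, region$lo - 1e-6, region$hi + 1e-6, track_radius, grid_cell)
  net <- structure(
    list(
      ptr = ptr,
      n_initial = nrow(points),
      region = region,
      track_radius = track_radius
    ),
    class = "growth_network"
  )
  lens <- ge_edge_lengths_sample(ptr, 3000L)
  net$edge_q90 <- unname(quantile(lens, 0.9))
  net$mean_edge <- mean(lens)
  net
}

#' @export
print.growth_network <- function(x, ...) {
  cat(sprintf(
    "<growth_network> %d nodes (%d initial), q90 edge %.3g um\n",
    ge_n_nodes(x$ptr), x$n_initial, x$edge_q90
  ))
  invisible(x)
}

#' Number of nodes in a growth network
#' @param network A `growth_network`.
#' @return Integer node count.
#' @export
network_size <- function(network) ge_n_nodes(network$ptr)

#' Delaunay neighbours of a node
#' @param network A `growth_network`.
#' @param i Node index (1-based).
#' @return Integer vector of neighbouring node indices.
#' @export
network_neighbours <- function(network, i) ge_neighbours(network$ptr, i)

#' Per-node growth state
#' @param network A `growth_network`.
#' @param idx Node indices (default all).
#' @return Tibble with `node`, `dc`, `bc` (0 = none), `occupied`.
#' @export
network_state <- function(network, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(network_size(network))
  st <- ge_state(network$ptr, as.integer(idx))
  tibble(node = as.integer(idx), dc = st$dc, bc = st$bc, occupied = st$occupied)
}

#' Node positions
#' @param network A `growth_network`.
#' @param idx Node indices (default all).
#' @return Matrix of positions.
#' @export
network_positions <- function(network, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(network_size(network))
  ge_positions(network$ptr, as.integer(idx))
}

#' Delaunay edge list
#' @param network A `growth_network`.
#' @return Two-column integer matrix of node index pairs.
#' @export
network_edges <- function(network) ge_edges(network$ptr)

#' Update the network with a grown fibre
#'
#' For every node within the tracking cutoff of the fibre's capsule chain
#' (spheres swept along the skeleton with linearly interpolated radii), the
#' sustainable diameter is min-updated to twice the node's clearance from the
#' fibre surface; nodes inside the fibre become occupied.
#'
#' @param network A `growth_network` (updated in place; also returned).
#' @param skeleton Matrix or tibble with columns x, y, z, radius.
#' @param bundle Bundle index of the fibre.
#' @return The network, invisibly.
#' @export
update_network <- function(network, skeleton, bundle) {
  sk <- as.matrix(skeleton[, c("x", "y", "z", "radius")])
  if (nrow(sk) < 2) abort("fibre skeleton needs at least 2 points")
  ge_update_fibre(network$ptr, sk, as.integer(bundle))
  invisible(network)
}

#' Insert dynamic nodes around a fibre path
#'
#' Adds `n_added` nodes in a shell around the fibre (radial offset 1.05 to 2
#' local radii), densifying the network where fibres already run so later
#' fibres can grow along or around them. The triangulation is extended
#' incrementally and the new nodes' clearance state is computed against all
#' fibres stored so far.
#'
#' @param network A `growth_network`.
#' @param skeleton Fibre skeleton (columns x, y, z, radius).
#' @param n_added Number of nodes to add.
#' @param padded_region Optional list `lo`/`hi`; candidate nodes outside it
#'   are dropped.
#' @return Integer vector of new node indices, invisibly.
#' @export
add_dynamic_nodes <- function(network, skeleton, n_added, padded_region = NULL) {
  if (n_added <= 0) return(invisible(integer(0)))
  sk <- as.matrix(skeleton[, c("x", "y", "z", "radius")])
  seg_len <- polyline_lengths(sk[, 1:3, drop = FALSE])
  total <- sum(seg_len)
  if (total <= 0) return(invisible(integer(0)))
  s <- runif(n_added, 0, total)
  cum <- c(0, cumsum(seg_len))
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1), length(seg_len))
  t <- (s - cum[seg]) / seg_len[seg]
  p <- sk[seg, 1:3, drop = FALSE] * (1 - t) + sk[seg + 1, 1:3, drop = FALSE] * t
  r <- sk[seg, 4] * (1 - t) + sk[seg + 1, 4] * t
  tangent <- sk[seg + 1, 1:3, drop = FALSE] - sk[seg, 1:3, drop = FALSE]
  tangent <- tangent / pmax(sqrt(rowSums(tangent^2)), 1e-12)
  # random unit vectors in the plane normal to the local tangent
  raw <- matrix(rnorm(3 * n_added), n_added, 3)
  raw <- raw - tangent * rowSums(raw * tangent)
  nn <- pmax(sqrt(rowSums(raw^2)), 1e-12)
  raw <- raw / nn
  mag <- runif(n_added, 1.05, 2) * r
  cand <- p + raw * mag
  if (!is.null(padded_region)) {
    keep <- cand[, 1] >= padded_region$lo[1] & cand[, 1] <= padded_region$hi[1] &
      cand[, 2] >= padded_region$lo[2] & cand[, 2] <= padded_region$hi[2] &
      cand[, 3] >= padded_region$lo[3] & cand[, 3] <= padded_region$hi[3]
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(invisible(integer(0)))
  invisible(ge_add_nodes(network$ptr, cand))
}

#' Export a network snapshot as CSV
#' @param network A `growth_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path) {
  pos <- network_positions(network)
  st <- network_state(network)
  df <- data.frame(
    node = st$node, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    dc = st$dc, bc = st$bc, occupied = st$occupied
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @method tidy growth_network
tidy.growth_network <- function(x, ...) {
  pos <- network_positions(x)
  st <- network_state(x)
  tibble(
    node = st$node, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    dc = st$dc, bc = st$bc, occupied = st$occupied
  )
}
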