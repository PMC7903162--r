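#' Sign of the point-pair interaction
#'
#' `sgn(r_i + r_j - distance)`: repulsive (+1) when two skeleton points from
#' different fibres are closer than the sum of their radii, attractive (-1)
#' when further apart, 0 when exactly touching.
#'
#' @param ri,rj Target radii of the two points (um).
#' @param distance Distance between the points (um).
#' @return -1, 0 or +1 (vectorised).
#' @export
interaction_sign <- function(ri, rj, distance) {
  if (any(ri <= 0) || any(rj <= 0)) abort("radii must be positive")
  if (any(distance < 0)) abort("distance must be non-negative")
  sign(ri + rj - distance)
}

#' Update vector for one skeleton point
#'
#' `u_i = sum_j D(i,j) (p_i - p_j)` over the point's nearest neighbours from
#' other fibres, rescaled to norm `0.2 r_i` whenever it exceeds that cap.
#' Coincident neighbour points contribute a small random jitter instead of
#' an undefined direction.
#'
#' @param p_i Position of the point (3-vector).
#' @param r_i Its target radius.
#' @param p_j `m x 3` matrix of neighbour positions.
#' @param r_j Neighbour radii.
#' @param step_frac Cap on the step as a fraction of `r_i`.
#' @return 3-vector update.
#' @export
update_vector <- function(p_i, r_i, p_j, r_j, step_frac = 0.2) {
  p_j <- matrix(p_j, ncol = 3)
  if (nrow(p_j) == 0) abort("neighbour set must be non-empty")
  diff <- matrix(p_i, nrow(p_j), 3, byrow = TRUE) - p_j
  d <- sqrt(rowSums(diff^2))
  D <- interaction_sign(r_i, r_j, d)
  u <- colSums(diff * D)
  coincident <- d < 1e-12
  if (any(coincident)) {
    jit <- rnorm(3)
    u <- u + 1e-3 * r_i * jit / max(vec3_norm(jit), 1e-12)
  }
  un <- vec3_norm(u)
  cap <- step_frac * r_i
  if (un > cap && un > 0) u <- u * cap / un
  u
}

#' Global position relaxation of a phantom
#'
#' Synchronous sweeps move every interior skeleton point along its update
#' vector (fibre endpoints stay fixed, radii are untouched) until the
#' total-overlap metric `sum max(0, r_i + r_j - |p_i - p_j|)` over current
#' neighbour pairs stops improving or the sweep budget is exhausted. The
#' best configuration seen is kept, so the final overlap never exceeds the
#' initial one.
#'
#' @param phantom A `phantom` with at least 2 completed fibres (fewer is a
#'   no-op).
#' @param n Number of nearest other-fibre neighbours per point.
#' @param max_iters Sweep budget.
#' @param tolerance Relative overlap-improvement stopping tolerance.
#' @return The phantom with relaxed skeleton positions; the per-sweep
#'   overlap trace is attached as attribute `"optimisation"`.
#' @export
global_optimise <- function(phantom, n = 10, max_iters = 200,
                            tolerance = 1e-4) {
  comp_idx <- which(phantom$fibres$status == "complete")
  if (length(comp_idx) < 2) return(phantom)
  sks <- phantom$fibres$skeleton[comp_idx]
  m <- vapply(sks, nrow, integer(1))
  P <- do.call(rbind, lapply(sks, function(s) cbind(s$x, s$y, s$z)))
  r <- unlist(lapply(sks, function(s) s$radius))
  fid <- rep(seq_along(sks), m)
  movable <- unlist(lapply(m, function(k) {
    mv <- rep(TRUE, k)
    mv[c(1, k)] <- FALSE
    mv
  }))
  res <- global_optimise_cpp(P, r, fid, movable, as.integer(n),
                             as.integer(max_iters), tolerance, 0.2)
  off <- c(0, cumsum(m))
  for (s in seq_along(sks)) {
    rows <- (off[s] + 1):off[s + 1]
    sk <- sks[[s]]
    sk$x <- res$positions[rows, 1]
    sk$y <- res$positions[rows, 2]
    sk$z <- res$positions[rows, 3]
    phantom$fibres$skeleton[[comp_idx[s]]] <- sk
  }
  attr(phantom, "optimisation") <- list(
    trace = res$trace,
    initial_overlap = res$trace[1],
    final_overlap = res$overlap
  )
  phantom
}

#' Total-overlap metric of a phantom
#'
#' @param phantom A `phantom`.
#' @param n Neighbours per point (as in [global_optimise()]).
#' @return Total overlap (um).
#' @export
phantom_overlap <- function(phantom, n = 10) {
  comp_idx <- which(phantom$fibres$status == "complete")
  if (length(comp_idx) < 2) return(0)
  sks <- phantom$fibres$skeleton[comp_idx]
  m <- vapply(sks, nrow, integer(1))
  P <- do.call(rbind, lapply(sks, function(s) cbind(s$x, s$y, s$z)))
  r <- unlist(lapply(sks, function(s) s$radius))
  fid <- rep(seq_along(sks), m)
  overlap_metric_cpp(P, r, fid, as.integer(n))
}
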