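#' Pack circles on a rectangular face
#'
#' Packs circles with the supplied radii into a rectangle up to a target area
#' density: circles are placed at random, then relaxed by grid-accelerated
#' pairwise repulsion while their radii inflate gradually to full size
#' (Lubachevsky-Stillinger style). If the full set cannot be made
#' overlap-free within the sweep budget, the most-squeezed circles are
#' removed one at a time until the packing is valid, so the achieved density
#' may fall short of an infeasible target (reported with a warning).
#'
#' @param radii Candidate circle radii (um); circles are taken in order until
#'   their cumulative area reaches the target.
#' @param face_size Length-2 rectangle dimensions (um).
#' @param rho_target Target area fraction in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param n_scales Inflation steps from half to full radius.
#' @param sweeps_per_scale Relaxation sweeps per inflation step.
#' @param final_sweeps Relaxation budget at full radius.
#' @return A tibble with columns `x`, `y`, `r`, plus attributes
#'   `achieved_density` and `target_density`.
#' @export
pack_circles_2d <- function(radii, face_size, rho_target, seed = NULL,
                            n_scales = 120, sweeps_per_scale = 60,
                            final_sweeps = 4000) {
  if (any(radii <= 0)) abort("all radii must be positive")
  if (rho_target <= 0 || rho_target > 1) abort("rho_target must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  W <- face_size[1]
  H <- face_size[2]
  area <- W * H

  cum <- cumsum(pi * radii^2) / area
  n <- which(cum >= rho_target)[1]
  if (is.na(n)) n <- length(radii)
  r <- radii[seq_len(n)]
  fit <- 2 * r <= min(W, H)
  if (!all(fit)) {
    warn("some circles are larger than the face; dropping them")
    r <- r[fit]
  }
  if (length(r) == 0) abort("no circle fits the face")

  x <- runif(length(r), r, W - r)
  y <- runif(length(r), r, H - r)
  res <- pack_relax_cpp(x, y, r, W, H, n_scales, sweeps_per_scale,
                        final_sweeps, 0.6)
  x <- res$x
  y <- res$y
  while (res$overlaps > 0 && length(r) > 1) {
    # drop the most-squeezed circle and relax again at full radius
    d <- as.matrix(stats::dist(cbind(x, y)))
    press <- rowSums(pmax(outer(r, r, "+") - d, 0)) - 2 * r
    worst <- which.max(press)
    x <- x[-worst]
    y <- y[-worst]
    r <- r[-worst]
    res <- pack_relax_cpp(x, y, r, W, H, 1, 1, 2000, 0.6)
    x <- res$x
    y <- res$y
  }
  achieved <- sum(pi * r^2) / area
  if (achieved < rho_target - 1e-9) {
    warn(sprintf("packing stalled at %.1f%% of the face (target %.1f%%)",
                 100 * achieved, 100 * rho_target))
  }
  out <- tibble(x = x, y = y, r = r)
  attr(out, "achieved_density") <- achieved
  attr(out, "target_density") <- rho_target
  out
}
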