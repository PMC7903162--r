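#' Direction (chemoattraction) cost of a candidate step
#'
#' `lt = 1/2 * (|s - c| / (1 + |s - c|)) * (1 - cos(theta))`, where `theta`
#' is the angle between the step `c - s` and the target direction `t - s`.
#' The saturating step-length factor and the angular factor keep
#' `0 <= lt < 1`: a step on the ray towards the target costs 0, and a long
#' step straight away from the target approaches 1.
#'
#' @param s Current position (3-vector or n x 3 matrix).
#' @param c_ Candidate position(s), same shape as `s` or n x 3.
#' @param t_ Target point (3-vector).
#' @return Numeric vector of direction costs.
#' @export
cost_direction <- function(s, c_, t_) {
  c_ <- matrix(c_, ncol = 3)
  s <- matrix(s, ncol = 3, nrow = nrow(c_), byrow = length(s) == 3)
  step <- c_ - s
  tv <- matrix(t_, ncol = 3, nrow = nrow(c_), byrow = TRUE) - s
  ls <- sqrt(rowSums(step^2))
  lt_ <- sqrt(rowSums(tv^2))
  if (any(ls < 1e-12)) abort("zero-length step in direction cost")
  if (any(lt_ < 1e-12)) abort("candidate coincides with the target origin")
  cosang <- rowSums(step * tv) / (ls * lt_)
  cosang <- pmin(pmax(cosang, -1), 1)
  0.5 * (ls / (1 + ls)) * (1 - cosang)
}

#' Diameter (shrinkage) cost of a candidate node
#'
#' `ld = max(0, (d0 - dc) / d0)`: zero when the node can sustain the fibre's
#' target diameter, rising to 1 when the node is fully blocked.
#'
#' @param d0 Target fibre diameter (um), positive.
#' @param dc Maximum sustainable diameter at the node (um, may be `Inf`).
#' @return Numeric vector of diameter costs.
#' @export
cost_diameter <- function(d0, dc) {
  if (any(d0 <= 0)) abort("d0 must be positive")
  pmax(0, (d0 - pmin(dc, d0)) / d0)
}

#' Bundle-conditional diameter cost (fasciculation)
#'
#' When the nearest bundle at the candidate node is the fibre's own bundle,
#' the cost becomes `|(d0 - dc) / d0|`, penalising moving away from the
#' bundle as well as shrinkage, which draws same-bundle fibres together.
#' Nodes with no nearby fibre (`bc = 0` / `dc = Inf`) fall back to the plain
#' shrinkage cost.
#'
#' @param d0 Target diameter (um).
#' @param dc Sustainable diameter at the node (um).
#' @param bc Bundle index nearest to the node (0 for none).
#' @param bf Bundle index of the growing fibre.
#' @return Numeric vector of diameter costs.
#' @export
cost_diameter_fasciculation <- function(d0, dc, bc, bf) {
  if (any(d0 <= 0)) abort("d0 must be positive")
  same <- !is.na(bc) & bc == bf & is.finite(dc)
  out <- cost_diameter(d0, dc)
  out[same] <- abs((d0 - dc[same]) / d0)
  out
}

#' Total step cost
#'
#' `l = lt + f * ld` with weight `f` (default 0.2, weighting growth towards
#' the target more strongly than diameter preservation).
#'
#' @param lt Direction cost(s).
#' @param ld Diameter cost(s).
#' @param f Non-negative weight.
#' @return Numeric vector of total costs.
#' @export
total_cost <- function(lt, ld, f = 0.2) {
  if (f < 0) abort("cost weight must be non-negative")
  lt + f * ld
}
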