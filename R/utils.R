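# internal geometry / rng helpers

vec3_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vec3_norm(v)
  if (n < 1e-12) abort("cannot normalise a zero vector")
  v / n
}

# rotation matrix taking unit vector `from` onto unit vector `to` (Rodrigues)
rotation_between <- function(from, to) {
  from <- unitize(from)
  to <- unitize(to)
  v <- c(
    from[2] * to[3] - from[3] * to[2],
    from[3] * to[1] - from[1] * to[3],
    from[1] * to[2] - from[2] * to[1]
  )
  c_ <- sum(from * to)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitize(perp - sum(perp * from) * from)
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# orthonormal basis (b1, b2) spanning the plane perpendicular to unit axis
perp_basis <- function(axis) {
  axis <- unitize(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unitize(ref - sum(ref * axis) * axis)
  b2 <- c(
    axis[2] * b1[3] - axis[3] * b1[2],
    axis[3] * b1[1] - axis[1] * b1[3],
    axis[1] * b1[2] - axis[2] * b1[1]
  )
  cbind(b1, b2)
}

# deterministic per-stage sub-seed below 2^31
derive_seed <- function(master_seed, stage) {
  as.integer((as.double(master_seed) * 7919 + 104729 * stage) %% 2147483629)
}

with_stage_seed <- function(master_seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(derive_seed(master_seed, stage))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# arc lengths of a polyline (m x 3)
polyline_lengths <- function(pts) {
  if (nrow(pts) < 2) return(numeric(0))
  sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid_2d <- function(x, y) {
  n <- length(x)
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}
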