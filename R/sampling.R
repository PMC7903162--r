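#' Sample fibre radii
#'
#' Radii are drawn from a gamma distribution parameterised by its mean and
#' standard deviation (shape `mu^2/sigma^2`, scale `sigma^2/mu`), the usual
#' choice for axon-radius phantoms; `sigma = 0` degenerates to a constant.
#'
#' @param mu Mean radius (um), positive.
#' @param sigma Radius standard deviation (um), non-negative.
#' @param n Number of radii.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive radii.
#' @export
sample_radii <- function(mu, sigma, n, seed = NULL) {
  if (mu <= 0) abort("radius mean must be positive")
  if (sigma < 0) abort("radius standard deviation must be non-negative")
  if (n < 1) abort("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(rep(mu, n))
  shape <- (mu / sigma)^2
  r <- rgamma(n, shape = shape, scale = sigma^2 / mu)
  # guard the extreme lower tail; zero radii cannot be grown or meshed
  pmax(r, mu * 1e-3)
}

#' Sample axial directions from the Watson distribution
#'
#' Axial (antipodally symmetric) samples about `mean_axis` with concentration
#' `kappa`, via vectorised rejection sampling of `t = cos(theta)` against the
#' envelope `exp(kappa (t^2 - 1))`. Samples are returned as unit vectors in
#' the hemisphere of `mean_axis`.
#'
#' @param kappa Concentration parameter, positive (bipolar regime).
#' @param mean_axis Mean axis (any non-zero 3-vector; normalised internally).
#' @param n Number of directions.
#' @param seed Optional integer seed.
#' @return `n x 3` matrix of unit row vectors.
#' @export
sample_watson <- function(kappa, mean_axis = c(0, 0, 1), n = 1, seed = NULL) {
  if (kappa <= 0) abort("kappa must be positive")
  if (!is.null(seed)) set.seed(seed)
  mean_axis <- unitize(mean_axis)
  t_acc <- numeric(0)
  while (length(t_acc) < n) {
    m <- max(2L * (n - length(t_acc)), 256L)
    t <- runif(m, -1, 1)
    u <- runif(m)
    keep <- log(u) < kappa * (t^2 - 1)
    t_acc <- c(t_acc, t[keep])
  }
  t <- t_acc[seq_len(n)]
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - t^2))
  d <- cbind(s * cos(phi), s * sin(phi), t)
  R <- rotation_between(c(0, 0, 1), mean_axis)
  d <- d %*% t(R)
  # fold to the hemisphere of the mean axis (axial data)
  flip <- drop(d %*% mean_axis) < 0
  d[flip, ] <- -d[flip, , drop = FALSE]
  d
}

#' Sample directions from the elliptically symmetric angular Gaussian
#'
#' Directions are obtained by normalising draws from a trivariate normal with
#' mean `mu` and a unit-determinant covariance that acts as the identity
#' along `mu`; `gamma = c(0, 0)` gives the isotropic angular Gaussian, and
#' the norm of `mu` acts as a concentration. In the plane perpendicular to
#' `mu` the covariance block is `[[r + g1, g2], [g2, r - g1]]` with
#' `r = sqrt(1 + g1^2 + g2^2)`, so its determinant is exactly 1.
#'
#' @param mu Mean vector (non-zero); larger norm concentrates the samples.
#' @param gamma Length-2 anisotropy parameter.
#' @param n Number of directions.
#' @param seed Optional integer seed.
#' @return `n x 3` matrix of unit row vectors.
#' @export
sample_esag <- function(mu, gamma = c(0, 0), n = 1, seed = NULL) {
  if (vec3_norm(mu) <= 0) abort("mu must be non-zero")
  if (!is.null(seed)) set.seed(seed)
  axis <- unitize(mu)
  B <- perp_basis(axis)
  g1 <- gamma[1]
  g2 <- gamma[2]
  r <- sqrt(1 + g1^2 + g2^2)
  Vb <- matrix(c(r + g1, g2, g2, r - g1), 2, 2)
  L <- chol(Vb)  # upper triangular, t(L) %*% L = Vb
  z <- matrix(rnorm(2 * n), n, 2) %*% L
  x <- matrix(rep(mu, each = n), n, 3) +
    z[, 1] %o% B[, 1] + z[, 2] %o% B[, 2] + rnorm(n) %o% axis
  x / sqrt(rowSums(x^2))
}
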