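# shared fixtures built in code; kept tiny so the suite stays fast

# numerical oracle for Watson angle-from-axis moments (degrees)
watson_moments_oracle <- function(kappa) {
  f <- function(th) exp(kappa * cos(th)^2) * sin(th)
  Z <- stats::integrate(f, 0, pi / 2)$value
  m1 <- stats::integrate(function(th) th * f(th), 0, pi / 2)$value / Z
  m2 <- stats::integrate(function(th) th^2 * f(th), 0, pi / 2)$value / Z
  c(mu = m1 * 180 / pi, sd = sqrt(m2 - m1^2) * 180 / pi)
}

# straight-fibre skeleton along z
straight_skeleton <- function(length = 10, radius = 0.5, n = 11,
                              x = 0, y = 0) {
  tibble::tibble(
    x = x, y = y, z = seq(0, length, length.out = n), radius = radius
  )
}

# small deterministic phantom grown once per session (used by several tests)
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- suppressWarnings(growth_config(
        region_size = 5, n_nodes = 2e4, target_density = 0.4,
        dispersion_model = "parallel", n_added = 500, master_seed = 42
      ))
      cache <<- suppressWarnings(grow_all(cfg, mechanisms = "all"))
    }
    cache
  }
})

# brute-force pairwise circle overlap count
circle_overlaps <- function(pk) {
  d <- as.matrix(stats::dist(cbind(pk$x, pk$y)))
  tg <- outer(pk$r, pk$r, "+")
  sum(d < tg - 1e-9 & upper.tri(d))
}
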