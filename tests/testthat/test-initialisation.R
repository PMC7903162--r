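test_that("radius sampling matches the requested gamma moments", {
  expect_equal(sample_radii(1, 0, 5), rep(1, 5))
  r <- sample_radii(0.5, 0.2, 1e4, seed = 1)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - 0.5) / 0.5, 0.02)
  expect_lt(abs(sd(r) - 0.2) / 0.2, 0.05)
  expect_error(sample_radii(-1, 0.1, 10), "positive")
  expect_error(sample_radii(1, 0.1, 0), "at least 1")
  # inside the tested practical range: no warning from the config layer
  expect_no_warning(growth_config(radius_mean = 2, radius_std = 0.5))
})

test_that("config warns outside practical limits and errors on invalid input", {
  expect_warning(growth_config(radius_mean = 3), "practical range")
  expect_warning(growth_config(cost_weight = 0.9), "practical range")
  expect_error(growth_config(target_density = 1.5), "0, 1")
  expect_error(growth_config(dispersion_model = "watson", watson_kappa = -1),
               "positive")
  cfg <- growth_config()
  expect_equal(cfg$cost_weight, 0.2)
  expect_equal(cfg$collapse_initial, 2)
  expect_equal(cfg$collapse_increment, 5)
  expect_equal(cfg$collapse_max_attempts, 5L)
  expect_equal(cfg$n_added, 2500L)
})

test_that("config round-trips through YAML", {
  cfg <- growth_config(region_size = c(5, 6, 7), master_seed = 9,
                       dispersion_model = "watson", watson_kappa = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_growth_config(cfg, path)
  cfg2 <- read_growth_config(path)
  expect_equal(cfg2$region_size, c(5, 6, 7))
  expect_equal(cfg2$watson_kappa, 12)
  expect_equal(cfg2$master_seed, 9L)
  cfg3 <- read_growth_config(path, watson_kappa = 30)
  expect_equal(cfg3$watson_kappa, 30)
})

test_that("circle packing is overlap-free and reaches high densities", {
  # single disc: density is the analytic area ratio (the 5% target is not
  # reachable with one circle, which warns)
  expect_warning(pk1 <- pack_circles_2d(1, c(10, 10), 0.05, seed = 1),
                 "stalled")
  expect_equal(attr(pk1, "achieved_density"), pi / 100, tolerance = 1e-12)
  # polydisperse pack at 75%: zero overlaps by the exact pairwise oracle
  r <- sample_radii(0.5, 0.1, 400, seed = 2)
  pk <- suppressWarnings(pack_circles_2d(r, c(20, 20), 0.75, seed = 3))
  expect_equal(circle_overlaps(pk), 0)
  expect_gte(attr(pk, "achieved_density"), 0.70)
  expect_true(all(pk$x >= pk$r - 1e-9 & pk$x <= 20 - pk$r + 1e-9))
  expect_true(all(pk$y >= pk$r - 1e-9 & pk$y <= 20 - pk$r + 1e-9))
})

test_that("Watson sampler reproduces numerical-oracle angle statistics", {
  for (kappa in c(8, 20, 100)) {
    d <- sample_watson(kappa, c(0, 0, 1), 1e4, seed = round(kappa))
    expect_equal(sqrt(rowSums(d^2)), rep(1, nrow(d)), tolerance = 1e-9)
    expect_true(all(d[, 3] >= 0))  # folded to the mean-axis hemisphere
    st <- orientation_stats(d)
    orc <- watson_moments_oracle(kappa)
    se_mu <- orc["sd"] / sqrt(1e4)
    expect_lt(abs(st$mu_theta - orc["mu"]), 4 * se_mu)
    expect_lt(abs(st$sigma_theta - orc["sd"]), 4 * orc["sd"] / sqrt(2e4))
  }
  # concentration limit
  d <- sample_watson(1e6, c(0, 0, 1), 2000, seed = 5)
  expect_lt(orientation_stats(d)$mu_theta, 0.2)
  # mean axis rotation
  ax <- c(1, 1, 1) / sqrt(3)
  d <- sample_watson(50, ax, 5000, seed = 6)
  expect_lt(orientation_stats(d, ax)$mu_theta, 15)
  expect_error(sample_watson(-1, c(0, 0, 1), 10), "positive")
})

test_that("ESAG sampler is consistent and concentrates with |mu|", {
  # gamma = 0 reduces to the isotropic angular Gaussian
  d0 <- sample_esag(c(0, 0, 4), c(0, 0), 4000, seed = 1)
  # isotropic: azimuthal angle uniform
  phi <- atan2(d0[, 2], d0[, 1])
  expect_gt(stats::ks.test(phi, "punif", -pi, pi)$p.value, 1e-3)
  # mean resultant direction within 2 degrees of mu
  mr <- colMeans(sample_esag(c(0, 0, 10), c(0, 0), 1e4, seed = 2))
  ang <- acos(sum(unitize(mr) * c(0, 0, 1))) * 180 / pi
  expect_lt(ang, 2)
  # monotone concentration in |mu|
  th10 <- orientation_stats(sample_esag(c(0, 0, 10), c(0, 0), 5000, seed = 3))$mu_theta
  th2 <- orientation_stats(sample_esag(c(0, 0, 2), c(0, 0), 5000, seed = 3))$mu_theta
  expect_lt(th10, th2)
  # anisotropy: gamma widens one principal axis over the other
  da <- sample_esag(c(0, 0, 4), c(2, 0), 5000, seed = 4)
  expect_gt(sd(da[, 1]) / sd(da[, 2]), 1.2)
  expect_error(sample_esag(c(0, 0, 0), c(0, 0), 5), "non-zero")
})

test_that("fibre seeds start and end on the region boundary", {
  cfg <- growth_config(region_size = 10, target_density = 0.3,
                       dispersion_model = "watson", watson_kappa = 20,
                       master_seed = 3)
  seeds <- suppressWarnings(make_fibre_seeds(cfg))
  expect_gt(nrow(seeds), 3)
  expect_true(all(seeds$start_z == 0))
  onb <- function(p) {
    apply(p, 1, function(q) min(abs(c(q, q - 10))) < 1e-6)
  }
  expect_true(all(onb(cbind(seeds$target_x, seeds$target_y, seeds$target_z))))
  expect_true(all(seeds$d0 > 0))
  # parallel bundle along z from (5,5,0) in a 10-cube exits at z = 10
  tp <- ray_box_exit(c(5, 5, 0), c(0, 0, 1), c(10, 10, 10))
  expect_equal(tp, c(5, 5, 10))
})

test_that("two perpendicular bundles carry distinct indices and directions", {
  cfg <- growth_config(
    region_size = 6, target_density = 0.2, dispersion_model = "parallel",
    bundles = list(bundle_spec(1L, c(0, 0, 1)), bundle_spec(2L, c(1, 0, 0))),
    master_seed = 4
  )
  seeds <- suppressWarnings(make_fibre_seeds(cfg))
  expect_setequal(unique(seeds$bundle), c(1L, 2L))
  b1 <- seeds[seeds$bundle == 1, ]
  b2 <- seeds[seeds$bundle == 2, ]
  expect_true(all(b1$start_z == 0))
  expect_true(all(b2$start_x == 0))
})

test_that("growth nodes are uniform in the padded region and reproducible", {
  reg <- list(lo = c(0, 0, 0), hi = c(1, 1, 1))
  p1 <- generate_growth_nodes(reg, 1000, seed = 7, padding = 0.1)
  p2 <- generate_growth_nodes(reg, 1000, seed = 7, padding = 0.1)
  expect_identical(p1, p2)
  expect_true(all(p1 >= -0.1 - 1e-12 & p1 <= 1.1 + 1e-12))
  # octant occupancy consistent with uniformity
  oct <- (p1[, 1] > 0.5) + 2 * (p1[, 2] > 0.5) + 4 * (p1[, 3] > 0.5)
  expect_gt(stats::chisq.test(table(oct))$p.value, 1e-3)
  expect_error(generate_growth_nodes(reg, 3), "at least 4")
})
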