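test_that("orientation histogram is antipodal, normalised and uniform-capable", {
  set.seed(1)
  d <- matrix(rnorm(3 * 2e4), ncol = 3)
  h <- orientation_histogram(d, level = 2)
  # integrates to 1 over the sphere
  expect_equal(sum(h$density * h$solid_angle), 1, tolerance = 1e-9)
  # exact antipodal symmetry
  expect_equal(h$density, h$density[h$antipode])
  # uniform directions: per-face density near 1/(4 pi)
  expect_equal(mean(h$density), 1 / (4 * pi), tolerance = 0.02)
  expect_lt(max(abs(h$density - 1 / (4 * pi))) / (1 / (4 * pi)), 0.5)
  # all mass at the poles for z-aligned segments
  hz <- orientation_histogram(matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE),
                              level = 2)
  expect_true(all(abs(hz$nz[hz$count > 0]) > 0.9))
  # histogram of -v equals histogram of v exactly
  hneg <- orientation_histogram(-d, level = 2)
  expect_equal(h$count, hneg$count)
})

test_that("orientation stats fold angles into [0, 90] degrees", {
  expect_equal(orientation_stats(rbind(c(0, 0, 1), c(0, 0, -1)))$mu_theta, 0)
  eq <- orientation_stats(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(eq$mu_theta, 90)
  d <- sample_watson(8, c(0, 0, 1), 1e4, seed = 3)
  st <- orientation_stats(d)
  orc <- watson_moments_oracle(8)
  expect_equal(st$mu_theta, unname(orc["mu"]), tolerance = 0.02)
  expect_equal(st$sigma_theta, unname(orc["sd"]), tolerance = 0.05)
})

test_that("centre line of a straight cylinder is its axis (also when tilted)", {
  sk <- straight_skeleton(10, 1, n = 11)
  mesh <- mesh_fibre(sk)
  cl <- extract_centreline(mesh, n_slices = 40)
  expect_equal(nrow(cl), 40)
  expect_lt(max(abs(cl$x)), 0.05)
  expect_lt(max(abs(cl$y)), 0.05)
  # tilted 30 degrees about y: centre line recovers the tilted axis
  R <- rotation_between(c(0, 0, 1), c(sin(pi / 6), 0, cos(pi / 6)))
  mesh_t <- new_fibre_mesh(mesh$vertices %*% t(R), mesh$faces)
  cl_t <- extract_centreline(mesh_t, n_slices = 40)
  segs <- segment_directions(as.matrix(cl_t[, c("x", "y", "z")]))
  mean_dir <- unitize(colMeans(segs$directions))
  ang <- acos(abs(sum(mean_dir * c(sin(pi / 6), 0, cos(pi / 6))))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("diameter profiles recover nominal and elliptic diameters", {
  sk <- straight_skeleton(10, 1, n = 11)
  mesh <- mesh_fibre(sk)
  cl <- extract_centreline(mesh, n_slices = 30)
  prof <- diameter_profile(mesh, cl)
  inner <- prof$diameter[5:(nrow(prof) - 5)]  # away from the capsule caps
  expect_equal(mean(inner), 2, tolerance = 0.02)
  expect_lt(sd(inner) / mean(inner), 0.05)
  # analytic elliptical section: semi-axes 2 and 0.5 -> d = 2 sqrt(ab) = 2
  expect_equal(2 * sqrt((pi * 2 * 0.5) / pi), 2)
  # beaded tube: alternating radius 0.5 / 1.0 -> CV > 0, mean in (1, 2)
  skb <- tibble::tibble(
    x = 0, y = 0, z = seq(0, 10, 0.5),
    radius = rep(c(0.5, 1), length.out = 21)
  )
  meshb <- mesh_fibre(skb, grid_resolution = 0.12)
  clb <- extract_centreline(meshb, n_slices = 40)
  profb <- diameter_profile(meshb, clb)
  expect_gt(attr(profb, "cv"), 0.05)
  db <- mean(profb$diameter, na.rm = TRUE)
  expect_gt(db, 1)
  expect_lt(db, 2)
})

test_that("mesh density converges to the analytic cylinder fraction", {
  sk <- straight_skeleton(6, 1, n = 7, x = 3, y = 3)
  mesh <- mesh_fibre(sk)
  roi <- list(lo = c(0, 0, 1), hi = c(6, 6, 5))
  fvf <- measure_density(list(mesh), roi, voxel = 0.1)
  expect_lt(abs(fvf - pi / 36), 0.02 * pi / 36 + 0.003)
  # halving the voxel changes the estimate by < 1%
  fvf2 <- measure_density(list(mesh), roi, voxel = 0.05)
  expect_lt(abs(fvf2 - fvf) / fvf, 0.01)
  expect_equal(measure_density(list(), roi), 0)
})

test_that("virtual histology renders discs and oblique ellipses", {
  sk <- straight_skeleton(6, 1, n = 7)
  mesh <- mesh_fibre(sk)
  sl <- virtual_histology_slice(list(mesh), point = c(0, 0, 3),
                                normal = c(0, 0, 1), resolution = 0.02)
  expect_s3_class(sl, "histology_slice")
  expect_gt(sum(sl$image > 0), 0)
  # disc area from pixels matches pi r^2
  a_px <- sum(sl$image != 0) * sl$pixel_size^2
  expect_equal(a_px, pi, tolerance = 0.02)
  # oblique cut at 30 degrees: ellipse with axis ratio 1/cos(30)
  sl2 <- virtual_histology_slice(list(mesh), point = c(0, 0, 3),
                                 normal = c(sin(pi / 6), 0, cos(pi / 6)),
                                 resolution = 0.02)
  poly <- sl2$polygons
  expect_gt(nrow(poly), 0)
  ranges <- c(diff(range(poly$u)), diff(range(poly$v)))
  expect_equal(max(ranges) / min(ranges), 1 / cos(pi / 6), tolerance = 0.03)
})

test_that("slice metrics hit the closed-form circle and square limits", {
  px <- 1 / 400
  # rasterised disc of radius 0.3 centred in a 1x1 image
  n <- 400
  xy <- (seq_len(n) - 0.5) * px
  disc <- outer(xy, xy, function(x, y) (x - 0.5)^2 + (y - 0.5)^2 < 0.09) * 1L
  md <- slice_morphometrics(disc, pixel_size = px)
  expect_equal(md$circularity, 1, tolerance = 0.02)
  expect_equal(md$convexity, 1, tolerance = 0.02)
  expect_lt(md$eccentricity, 0.1)
  expect_equal(md$area_ratio, 1, tolerance = 0.03)
  # rasterised square: circularity -> pi/4
  sq <- matrix(0L, n, n)
  sq[100:300, 100:300] <- 1L
  ms <- slice_morphometrics(sq, pixel_size = px)
  expect_equal(ms$circularity, pi / 4, tolerance = 0.02)
  # 3:1 ellipse: eccentricity -> sqrt(1 - 1/9)
  ell <- outer(xy, xy, function(x, y) {
    ((x - 0.5) / 0.45)^2 + ((y - 0.5) / 0.15)^2 < 1
  }) * 1L
  me <- slice_morphometrics(ell, pixel_size = px)
  expect_equal(me$eccentricity, sqrt(1 - 1 / 9), tolerance = 0.02)
  # edge-touching axons are excluded
  edge <- matrix(0L, 50, 50)
  edge[1:10, 20:30] <- 1L
  edge[25:35, 20:30] <- 2L
  m2 <- slice_morphometrics(edge, pixel_size = 0.01)
  expect_equal(m2$label, 2L)
})
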