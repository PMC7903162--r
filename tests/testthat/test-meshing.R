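test_that("skeleton resampling respects spacing and endpoints", {
  sk <- straight_skeleton(10, 0.5, n = 3)
  src <- resample_skeleton(sk, spacing = 0.5)
  expect_gte(nrow(src), 21)
  expect_equal(src$z[1], 0)
  expect_equal(src$z[nrow(src)], 10)
  gaps <- diff(src$z)
  expect_true(all(gaps <= 0.5 + 1e-9))
  expect_equal(sd(gaps), 0, tolerance = 1e-9)
  expect_equal(unique(round(src$r, 12)), 0.5)
  # varying radii interpolate linearly
  sk2 <- tibble::tibble(x = 0, y = 0, z = c(0, 10), radius = c(0.5, 1))
  src2 <- resample_skeleton(sk2, 0.5)
  expect_equal(src2$r, 0.5 + src2$z / 20, tolerance = 1e-9)
  expect_error(resample_skeleton(sk[1, ]), "at least 2")
})

test_that("field kernel has compact support and calibrated isolevel", {
  src <- tibble::tibble(x = 0, y = 0, z = 0, r = 1)
  # outside the support (2r): exactly zero
  expect_equal(field_value(c(0, 0, 2.01), src), 0)
  # at the nominal radius the field equals the single-source isolevel
  expect_equal(field_value(c(1, 0, 0), src), (3 / 4)^3, tolerance = 1e-12)
  # coincident +/- sources cancel everywhere
  both <- tibble::tibble(x = c(0, 0), y = 0, z = 0, r = 1)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(field_value(pts, both, sign = c(1, -1)), rep(0, 10))
})

test_that("an isolated source meshes to a sphere of its radius", {
  src <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1)
  # via mesh_fibre machinery on a degenerate two-point skeleton
  m <- march_sources_cpp(matrix(c(0, 0, 0, 1), 1), 1, (3 / 4)^3, 0.1, 0.2, 14L)
  rad <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(rad - 1)), 2e-3)
  mesh <- new_fibre_mesh(m$vertices, m$faces)
  wt <- mesh_is_watertight(mesh)
  expect_true(wt$closed)
  expect_true(wt$oriented)
  expect_equal(abs(wt$volume), 4 * pi / 3, tolerance = 0.01)
})

# grid-resolution band used by the capsule-deviation check
mesh_volume_resolution_band <- function(sk) {
  min(as.matrix(sk)[, 4]) / 4 + 1e-6
}

test_that("a straight fibre meshes to a tube of its nominal diameter", {
  sk <- straight_skeleton(10, 1, n = 11)
  mesh <- mesh_fibre(sk)
  wt <- mesh_is_watertight(mesh)
  expect_true(wt$closed)
  expect_gt(wt$volume, 0)
  # cross-section equivalent diameter within 2% of 2.0
  loops <- slice_mesh_cpp(mesh$vertices, mesh$faces, c(0, 0, 5), c(0, 0, 1))
  expect_length(loops, 1)
  A <- shoelace_area(loops[[1]][, 1], loops[[1]][, 2])
  expect_equal(2 * sqrt(A / pi), 2.0, tolerance = 0.02)
  # away from the end caps the surface stays within a grid-resolution band
  # of the analytic capsule (the metaball tips round off short of the caps)
  body <- mesh$vertices[, 3] > 1 & mesh$vertices[, 3] < 9
  dist_surf <- capsule_min_distance(mesh$vertices[body, , drop = FALSE],
                                    as.matrix(sk))
  expect_lt(max(abs(dist_surf)), mesh_volume_resolution_band(sk))
})

test_that("negative potentials deform later fibres without intersection", {
  sk1 <- straight_skeleton(8, 1, n = 9, x = 0)
  sk2 <- straight_skeleton(8, 1, n = 9, x = 1.5)  # 1.5 radii apart: overlap
  m1 <- mesh_fibre(sk1, fibre = 1L)
  neg <- resample_skeleton(sk1, 0.5)
  m2 <- mesh_fibre(sk2, negative_sources = neg, fibre = 2L)
  expect_equal(mesh_collision_count(m1, m2), 0)
  # the deformed mesh loses volume relative to its undeformed capsule
  m2_free <- mesh_fibre(sk2, fibre = 2L)
  expect_lt(mesh_volume(m2), mesh_volume(m2_free))
  expect_true(mesh_is_watertight(m2)$closed)
})

test_that("phantom meshing yields pairwise non-intersecting watertight meshes", {
  ph <- tiny_phantom()
  pm <- mesh_phantom(ph)
  expect_equal(nrow(pm$failures), 0)
  expect_length(pm$meshes, sum(ph$fibres$status == "complete"))
  for (m in pm$meshes) {
    wt <- mesh_is_watertight(m)
    expect_true(wt$closed)
    expect_true(wt$oriented)
    expect_gt(wt$volume, 0)
  }
  expect_equal(phantom_collisions(pm), 0)
})

test_that("PLY round-trips vertices to float precision", {
  sk <- straight_skeleton(4, 0.5, n = 5)
  mesh <- mesh_fibre(sk, fibre = 3L, bundle = 1L)
  dir <- withr::local_tempdir()
  files <- write_ply(mesh, dir, merged = FALSE)
  expect_true(file.exists(files[1]))
  # header declares counts matching the body, and magic is valid
  header <- readLines(files[1], n = 3, warn = FALSE)
  expect_equal(header[1], "ply")
  expect_equal(header[2], "format binary_little_endian 1.0")
  back <- read_ply(files[1])
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))
  expect_equal(back$faces, mesh$faces)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
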