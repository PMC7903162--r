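test_that("interaction sign separates repulsion, contact and attraction", {
  expect_equal(interaction_sign(1, 1, 1.5), 1)
  expect_equal(interaction_sign(1, 1, 2), 0)
  expect_equal(interaction_sign(1, 0.5, 3), -1)
  expect_error(interaction_sign(-1, 1, 1), "positive")
})

test_that("update vector points away from an overlapping neighbour and is capped", {
  # single overlapping neighbour displaced along -x: update along +x
  u <- update_vector(c(0, 0, 0), 1, matrix(c(-1, 0, 0), 1), 1)
  expect_gt(u[1], 0)
  expect_equal(u[2:3], c(0, 0))
  # all neighbours exactly touching: zero update
  u0 <- update_vector(c(0, 0, 0), 1, rbind(c(2, 0, 0), c(0, 2, 0)), c(1, 1))
  expect_equal(u0, c(0, 0, 0))
  # cap: raw norm r_i rescales to exactly 0.2 r_i
  u2 <- update_vector(c(0, 0, 0), 1, matrix(c(-1, 0, 0), 1), 0.5)
  expect_equal(sqrt(sum(u2^2)), 0.2, tolerance = 1e-12)
  # coincident neighbour: finite jitter, not NaN
  set.seed(1)
  u3 <- update_vector(c(0, 0, 0), 1, matrix(0, 1, 3), 1)
  expect_true(all(is.finite(u3)))
})

test_that("relaxing two overlapping parallel fibres reduces total overlap", {
  z <- seq(0, 10, 0.5)
  mk <- function(x0) tibble::tibble(x = x0, y = 0, z = z, radius = 1,
                                    node = NA_integer_)
  fibres <- list(mk(0), mk(1.6))  # 20% overlap of the touching distance
  ph <- structure(list(
    fibres = tibble::tibble(
      fibre = 1:2, bundle = 1L, status = "complete", d0 = 2,
      collapses = 0L, n_points = lengths(lapply(fibres, nrow)),
      skeleton = fibres
    ),
    config = suppressWarnings(growth_config(region_size = 12)),
    mechanisms = character(0)
  ), class = "phantom")
  before <- phantom_overlap(ph)
  expect_gt(before, 0)
  set.seed(2)
  ph2 <- global_optimise(ph)
  opt <- attr(ph2, "optimisation")
  expect_lt(opt$final_overlap, before)
  expect_lte(opt$final_overlap, opt$initial_overlap)
  # endpoints fixed; counts, ordering and radii unchanged
  for (k in 1:2) {
    sk0 <- ph$fibres$skeleton[[k]]
    sk1 <- ph2$fibres$skeleton[[k]]
    expect_equal(nrow(sk1), nrow(sk0))
    expect_equal(sk1$radius, sk0$radius)
    expect_equal(unlist(sk1[1, c("x", "y", "z")]), unlist(sk0[1, c("x", "y", "z")]))
    expect_equal(unlist(sk1[nrow(sk1), c("x", "y", "z")]),
                 unlist(sk0[nrow(sk0), c("x", "y", "z")]))
  }
  # no point moved by more than the per-sweep cap times the sweep count
  n_sweeps <- length(opt$trace)
  for (k in 1:2) {
    d <- sqrt(rowSums((as.matrix(ph2$fibres$skeleton[[k]][, c("x", "y", "z")]) -
                         as.matrix(ph$fibres$skeleton[[k]][, c("x", "y", "z")]))^2))
    expect_true(all(d <= 0.2 * 1 * n_sweeps + 1e-9))
  }
})

test_that("an overlap-free well-separated phantom stays overlap-free", {
  z <- seq(0, 6, 0.5)
  mk <- function(x0) tibble::tibble(x = x0, y = 0, z = z, radius = 0.5,
                                    node = NA_integer_)
  ph <- structure(list(
    fibres = tibble::tibble(
      fibre = 1:2, bundle = 1L, status = "complete", d0 = 1,
      collapses = 0L, n_points = 13L,
      skeleton = list(mk(0), mk(5))
    ),
    config = suppressWarnings(growth_config(region_size = 8)),
    mechanisms = character(0)
  ), class = "phantom")
  expect_equal(phantom_overlap(ph), 0)
  ph2 <- global_optimise(ph)
  expect_equal(attr(ph2, "optimisation")$final_overlap, 0)
})
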