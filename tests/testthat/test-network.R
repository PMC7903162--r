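test_that("a single tetrahedron triangulates to 6 edges", {
  p4 <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  net <- build_network(p4)
  expect_equal(network_size(net), 4)
  expect_equal(nrow(network_edges(net)), 6)
  st <- network_state(net)
  expect_true(all(is.infinite(st$dc)))
  expect_true(all(st$bc == 0))
  expect_false(any(st$occupied))
})

test_that("Delaunay edges satisfy the empty-circumsphere oracle", {
  set.seed(1)
  P <- matrix(runif(150), ncol = 3)
  net <- build_network(P)
  tets <- ge_tets(net$ptr)$tets
  circum <- function(A, B, C, D) {
    M <- rbind(B - A, C - A, D - A)
    b <- 0.5 * c(sum(B^2) - sum(A^2), sum(C^2) - sum(A^2), sum(D^2) - sum(A^2))
    ctr <- solve(M, b)
    list(c = ctr, r = sqrt(sum((A - ctr)^2)))
  }
  bad <- 0
  for (i in seq_len(nrow(tets))) {
    cs <- circum(P[tets[i, 1], ], P[tets[i, 2], ], P[tets[i, 3], ],
                 P[tets[i, 4], ])
    d <- sqrt(colSums((t(P) - cs$c)^2))
    if (any(d < cs$r - 1e-8)) bad <- bad + 1
  }
  expect_equal(bad, 0)
  # adjacency symmetry
  for (i in sample(50, 10)) {
    for (j in network_neighbours(net, i)) {
      expect_true(i %in% network_neighbours(net, j))
    }
  }
})

test_that("network update stores clearance as a sustainable diameter", {
  # node at distance 3 from the axis of a straight radius-1 fibre: dc = 4
  P <- rbind(c(3, 0, 5), c(8, 8, 8), c(-2, -3, 1), c(5, -4, 9))
  net <- build_network(P, region = list(lo = rep(-5, 3), hi = rep(12, 3)),
                       track_radius = 10)
  update_network(net, straight_skeleton(10, 1), bundle = 2)
  st <- network_state(net, 1)
  expect_equal(st$dc, 4, tolerance = 1e-12)
  expect_equal(st$bc, 2L)
  # min rule: a closer second fibre lowers dc, a farther one cannot raise it
  update_network(net, straight_skeleton(10, 1, x = 1.5), bundle = 3)
  expect_equal(network_state(net, 1)$dc, 2 * (1.5 - 1), tolerance = 1e-12)
  update_network(net, straight_skeleton(10, 0.5, x = -4), bundle = 4)
  expect_equal(network_state(net, 1)$dc, 1, tolerance = 1e-12)
  expect_equal(network_state(net, 1)$bc, 3L)
})

test_that("nodes inside a fibre become occupied and inaccessible", {
  set.seed(2)
  P <- rbind(c(0, 0, 5), matrix(runif(90, -4, 4), ncol = 3))
  net <- build_network(P, region = list(lo = rep(-5, 3), hi = rep(6, 3)))
  update_network(net, straight_skeleton(10, 1), bundle = 1)
  st <- network_state(net, 1)
  expect_true(st$occupied)
  expect_equal(st$dc, 0)
  # dc is non-increasing over repeated (idempotent) application
  before <- network_state(net)$dc
  update_network(net, straight_skeleton(10, 1), bundle = 1)
  expect_true(all(network_state(net)$dc <= before + 1e-12))
  # no accessible node lies strictly inside the capsule (exact oracle)
  stall <- network_state(net)
  pos <- network_positions(net)
  inside <- capsule_min_distance(pos, as.matrix(straight_skeleton(10, 1))) < -1e-9
  expect_true(all(stall$occupied[inside]))
})

test_that("dynamic nodes densify the shell around a fibre", {
  set.seed(3)
  P <- matrix(runif(300, 0, 10), ncol = 3)
  net <- build_network(P, region = list(lo = rep(0, 3), hi = rep(10, 3)))
  sk <- straight_skeleton(10, 0.5, x = 5, y = 5)
  update_network(net, sk, bundle = 1)
  n0 <- network_size(net)
  pos0 <- network_positions(net)
  d0 <- capsule_min_distance(pos0, as.matrix(sk))
  near0 <- sum(d0 < 2)
  idx <- add_dynamic_nodes(net, sk, 400,
                           padded_region = list(lo = rep(-1, 3), hi = rep(11, 3)))
  expect_equal(network_size(net), n0 + length(idx))
  expect_gt(length(idx), 300)  # a few may fall outside the padded region
  # every added node is outside the fibre and within 2 local radii
  padd <- network_positions(net, idx)
  dd <- capsule_min_distance(padd, as.matrix(sk))
  expect_true(all(dd > 0))
  expect_true(all(dd < 2 * 0.5 + 1e-9))
  # shell density strictly increases near the path
  d1 <- capsule_min_distance(network_positions(net), as.matrix(sk))
  expect_gt(sum(d1 < 2), near0)
  # no-op on zero
  expect_length(add_dynamic_nodes(net, sk, 0), 0)
})
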