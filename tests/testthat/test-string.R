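test_that("string initialization produces equally spaced images", {
  p <- initialize_string(c(0, 0), c(1, 1), M = 10)
  expect_equal(nrow(p$images), 11)
  expect_equal(p$alpha, seq(0, 1, length.out = 11))
  seg <- sqrt(rowSums(diff(p$images)^2))
  expect_lt(diff(range(seg)), 1e-12)
  # all images colinear
  dirs <- diff(p$images)
  expect_lt(max(abs(dirs[, 1] - dirs[, 2])), 1e-12)
  # a waypoint on the segment reduces through_point to linear
  p2 <- initialize_string(c(0, 0), c(1, 1), M = 10, mode = "through_point",
                          waypoint = c(0.5, 0.5))
  expect_equal(p2$images, p$images, tolerance = 1e-12)
  expect_error(initialize_string(c(0, 0), c(0, 0), M = 10), "coincident")
})

test_that("reparameterization is exact on a straight line and keeps endpoints", {
  p <- initialize_string(c(0, 0), c(2, 1), M = 12)
  img <- p$images
  img[4, ] <- img[4, ]  # already equal arc length
  expect_lt(max(abs(fesfold:::.reparameterize(img) - img)), 1e-8)
  # a perturbed path keeps its endpoints; iterated reparameterization
  # equalizes the chord spacing (one pass cuts corners of a kinked path)
  img[5, ] <- img[5, ] + c(0.1, -0.2)
  rp <- fesfold:::.reparameterize(img)
  expect_equal(rp[1, ], img[1, ])
  expect_equal(rp[13, ], img[13, ])
  for (i in 1:20) rp <- fesfold:::.reparameterize(rp)
  seg <- sqrt(rowSums(diff(rp)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)
})

test_that("Voronoi-restricted sampling never leaves its cell", {
  mb <- make_surface("muller_brown")
  images <- initialize_string(c(-0.558, 1.442), c(0.623, 0.028), M = 12)$images
  set.seed(4)
  res <- fesfold:::voronoi_sample_cpp(mb$spec, images, 5L, images[6, ],
                                      2000L, 5e-5, 1, 1 / kB, 1L)
  expect_gt(res$acceptance, 0)
  d2 <- fesfold:::.cross_dist2(res$samples, images)
  expect_true(all(max.col(-d2, ties.method = "first") == 6L))
})

test_that("a single-basin string collapses to the minimum with a flat profile", {
  qb <- make_surface("quad_bowl_nd", list(dim = 2, kappa = 2))
  p0 <- initialize_string(c(-0.3, 0), c(0.3, 0), M = 10)
  ps <- fts_relax(qb, p0, n_cell_samples = 400, dt = 2e-3, T = 300,
                  max_iter = 80, tol = 1e-3, seed = 6,
                  endpoint_mode = "relaxed")
  spread <- 3 * sqrt(kB * 300 / 2)
  expect_true(all(sqrt(rowSums(ps$images^2)) < spread))
  pf <- path_free_energy(qb, ps)
  expect_equal(pf$A[1], 0)
  expect_lt(diff(range(pf$A)), 3 * kB * 300)
  # determinism
  ps2 <- fts_relax(qb, p0, n_cell_samples = 400, dt = 2e-3, T = 300,
                   max_iter = 80, tol = 1e-3, seed = 6,
                   endpoint_mode = "relaxed")
  expect_identical(ps$images, ps2$images)
})

test_that("the 6-D two-basin string reports the designed basin free energy gap", {
  s6 <- make_surface("sym6d_wells")
  ctr <- s6$params$centers
  p0 <- initialize_string(ctr["open", ], ctr["folded", ], M = 24)
  ps <- fts_relax(s6, p0, n_cell_samples = 300, dt = 0.005, T = 300,
                  max_iter = 40, tol = 0.02, seed = 2)
  pf <- path_free_energy(s6, ps)
  expect_equal(pf$A[1], 0)
  expect_equal(tail(pf$A, 1), -2, tolerance = 0.5)
  # interior images climb over a barrier between the basins
  expect_gt(max(pf$A), 1)
})

test_that("path clustering separates engineered channels and handles edge cases", {
  ch <- make_surface("channels_2d")
  Tch <- 0.15 / kB
  relax <- function(wp, seed) {
    p0 <- initialize_string(c(-1, 0), c(1, 0), M = 16, mode = "through_point",
                            waypoint = wp)
    fts_relax(ch, p0, n_cell_samples = 300, dt = 2e-3, T = Tch,
              max_iter = 80, tol = 5e-3, seed = seed)
  }
  upper <- relax(c(0, 1), 5); lower <- relax(c(0, -1), 6)
  upper2 <- relax(c(0, 0.8), 7)
  expect_gt(mean(upper$images[, 2]), 0.3)
  expect_lt(mean(lower$images[, 2]), -0.3)
  g <- cluster_paths(list(upper, lower, upper2), distance_threshold = 0.5)
  expect_equal(g, list(c(1L, 3L), 2L), ignore_attr = TRUE)
  expect_equal(cluster_paths(list(upper, upper), 0.5), list(c(1L, 2L)),
               ignore_attr = TRUE)
  expect_equal(length(cluster_paths(list(upper, lower), Inf)), 1L)
  expect_equal(length(cluster_paths(list(upper, lower), 1e-12)), 2L)
  short <- initialize_string(c(-1, 0), c(1, 0), M = 8)
  expect_error(cluster_paths(list(upper, short), 0.5), "differing image counts")
})
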