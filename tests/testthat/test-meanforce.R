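test_that("K-means center selection is deterministic and recovers blob means", {
  set.seed(1)
  blob1 <- matrix(rnorm(400, mean = 0, sd = 0.5), ncol = 2)
  blob2 <- matrix(rnorm(400, mean = 5, sd = 0.5), ncol = 2)
  X <- rbind(blob1, blob2)
  cs <- select_centers(X, 2, seed = 3)
  got <- cs$centers[order(cs$centers[, 1]), ]
  se <- 0.5 / sqrt(200)
  expect_lt(max(abs(got[1, ] - colMeans(blob1))), 3 * se)
  expect_lt(max(abs(got[2, ] - colMeans(blob2))), 3 * se)
  cs2 <- select_centers(X, 2, seed = 3)
  expect_identical(cs$centers, cs2$centers)
  # k = number of distinct samples returns the samples as a set
  Xs <- matrix(runif(20), ncol = 2)
  all10 <- select_centers(Xs, 10, seed = 1)
  expect_equal(all10$centers[order(all10$centers[, 1]), ],
               Xs[order(Xs[, 1]), ], ignore_attr = TRUE)
  expect_error(select_centers(Xs, 11, seed = 1), "exceeds distinct samples")
})

test_that("restrained mean force matches the 1-D restrained-Gaussian closed form", {
  # U = kappa/2 x^2 with restraint k at x_o: F = k kappa (mu - x_o) / (k + kappa)
  qb <- make_surface("quad_bowl_nd", list(dim = 1, kappa = 1))
  rec <- estimate_mean_force(qb, d_o = 1, k = 100, T = 300, n_steps = 4e5,
                             dt = 5e-4, seed = 6)
  expect_lt(abs(rec$F.1 - (-100 / 101)), 4 * rec$se.1 + 0.02)
  expect_equal(rec$F.1, -0.9901, tolerance = 0.25)
  rec0 <- estimate_mean_force(qb, d_o = 0, k = 100, T = 300, n_steps = 4e5,
                              dt = 5e-4, seed = 7)
  expect_lt(abs(rec0$F.1), 4 * rec0$se.1)
  expect_error(estimate_mean_force(qb, 0, k = -1), "k > 0")
})

test_that("estimator bias decays as the restrained-Gaussian factor k/(k+kappa)", {
  kappa <- 10
  qb <- make_surface("quad_bowl_nd", list(dim = 1, kappa = kappa))
  x_o <- 2
  ks <- c(50, 200, 800)
  F_inf <- -kappa * x_o
  Fhat <- numeric(length(ks)); SE <- numeric(length(ks))
  for (i in seq_along(ks)) {
    rec <- estimate_mean_force(qb, d_o = x_o, k = ks[i], T = 300,
                               n_steps = 2e6, dt = 0.05 / ks[i],
                               save_stride = 10L, seed = 30 + i)
    Fhat[i] <- rec$F.1; SE[i] <- rec$se.1
    closed <- -ks[i] * kappa * x_o / (ks[i] + kappa)
    expect_lt(abs(Fhat[i] - closed), 4 * SE[i] + 0.02)
  }
  bias <- abs(Fhat - F_inf)
  slope <- coef(lm(log(bias) ~ log(ks + kappa)))[2]
  expect_gt(slope, -1.25)
  expect_lt(slope, -0.75)
  # bias shrinks monotonically toward the true gradient
  expect_true(all(diff(bias) < 0))
})

test_that("batch mean forces match the 6-D closed form and are reproducible", {
  kappa <- 0.5; k <- 50
  ctrv <- c(3, 4, 5, 6, 4, 3)
  qb <- make_surface("quad_bowl_nd", list(dim = 6, kappa = kappa, center = ctrv))
  set.seed(8)
  centers <- matrix(runif(20 * 6, 1, 8), 20)
  recs <- batch_mean_forces(qb, centers, k = k, T = 300, n_steps = 4e4,
                            dt = 1e-3, seed = 9)
  m <- fesfold:::.records_matrices(recs)
  closed <- -sweep(m$centers, 2, ctrv) * kappa * k / (k + kappa)
  se <- as.matrix(recs[, grep("^se\\.", names(recs))])
  expect_true(all(abs(m$forces - closed) < 4 * se + 0.05))
  recs2 <- batch_mean_forces(qb, centers, k = k, T = 300, n_steps = 4e4,
                             dt = 1e-3, seed = 9)
  expect_identical(recs, recs2)
  empty <- batch_mean_forces(qb, centers[0, , drop = FALSE], k = k)
  expect_equal(nrow(empty), 0)
})

test_that("mean-force records round-trip through the CSV interchange format", {
  qb <- make_surface("quad_bowl_nd", list(dim = 2, kappa = 1))
  rec <- estimate_mean_force(qb, c(0.5, -0.5), k = 20, n_steps = 1e4, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_mean_forces(rec, f)
  back <- read_mean_forces(f)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
  expect_error(read_mean_forces(write_hills(data.frame(a = 1), tempfile())),
               "not a mean-force CSV")
})
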