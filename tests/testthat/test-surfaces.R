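test_that("every catalog surface passes a finite-difference gradient check", {
  specs <- list(make_surface("double_well_1d"),
                make_surface("muller_brown"),
                make_surface("quad_bowl_nd", list(dim = 4, kappa = c(1, 2, 3, 4),
                                                  center = c(0, 1, -1, 2))),
                make_surface("sym6d_wells"),
                make_surface("channels_2d"))
  set.seed(7)
  h <- 1e-5
  for (surf in specs) {
    # interior points away from the boundary
    X <- sapply(seq_len(surf$dim), function(j) {
      span <- surf$upper[j] - surf$lower[j]
      runif(100, surf$lower[j] + 0.1 * span, surf$upper[j] - 0.1 * span)
    })
    X <- matrix(X, ncol = surf$dim)
    eg <- fesfold:::.energy_batch(surf, X, grad = TRUE)
    for (j in seq_len(surf$dim)) {
      Xp <- X; Xp[, j] <- Xp[, j] + h
      Xm <- X; Xm[, j] <- Xm[, j] - h
      fd <- (fesfold:::.energy_batch(surf, Xp)$energy -
             fesfold:::.energy_batch(surf, Xm)$energy) / (2 * h)
      scale <- pmax(abs(eg$grad[, j]), 1)
      expect_lt(max(abs(fd - eg$grad[, j]) / scale), 1e-5)
    }
  }
})

test_that("surface landmarks match their construction", {
  dw <- make_surface("double_well_1d", list(h = 7))
  expect_equal(eval_surface(dw, 1)$energy, 0)
  expect_equal(eval_surface(dw, -1)$energy, 0)
  expect_equal(eval_surface(dw, 0), list(energy = 7, gradient = 0))
  qb <- make_surface("quad_bowl_nd", list(dim = 3, kappa = 2, center = c(1, 2, 3)))
  expect_equal(eval_surface(qb, c(1, 2, 3)),
               list(energy = 0, gradient = c(0, 0, 0)))
  expect_error(eval_surface(dw, 10), "domain")
  expect_error(make_surface("no_such_surface"), "unknown surface")
  # Muller-Brown deepest minimum located by independent numerical minimization
  mb <- make_surface("muller_brown")
  o <- optim(c(-0.5, 1.5),
             function(p) fesfold:::.energy_batch(mb, matrix(p, 1))$energy)
  expect_equal(o$par, c(-0.558, 1.442), tolerance = 2e-3)
})

test_that("sym6d_wells is reversal-symmetric with the designed basin gap", {
  s6 <- make_surface("sym6d_wells")
  set.seed(11)
  D <- matrix(runif(1000 * 6, 2, 38), ncol = 6)
  e1 <- fesfold:::.energy_batch(s6, D)$energy
  e2 <- fesfold:::.energy_batch(s6, D[, c(6, 5, 3, 4, 2, 1)])$energy
  expect_lt(max(abs(e1 - e2)), 1e-10)
  ctr <- s6$params$centers
  gap <- diff(fesfold:::.energy_batch(s6, ctr)$energy)
  expect_equal(gap, 2, tolerance = 1e-6)
  # basin centers recovered by local minimization from perturbed starts
  set.seed(12)
  for (b in 1:2) {
    start <- ctr[b, ] + runif(6, -1.5, 1.5)
    o <- optim(start, function(p) fesfold:::.energy_batch(s6, matrix(p, 1))$energy,
               method = "BFGS")
    expect_equal(o$par, ctr[b, ], tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("exact marginals reproduce separable closed forms", {
  qb <- make_surface("quad_bowl_nd", list(dim = 2, kappa = c(1.3, 0.7)))
  grid <- seq(-2, 2, length.out = 41)
  pr <- marginal_1d_exact(qb, 1, grid, T = 300)
  ref <- 0.5 * 1.3 * grid^2
  expect_lt(max(abs(pr$A - (ref - min(ref)))), 1e-3)
  # doubling T leaves a separable component's marginal unchanged up to shift
  pr2 <- marginal_1d_exact(qb, 1, grid, T = 600)
  expect_lt(max(abs(pr$A - pr2$A)), 1e-3)
})

test_that("Monte-Carlo marginal of the 6-D mixture matches its analytic marginal", {
  s6 <- make_surface("sym6d_wells")
  grid <- seq(3, 35, length.out = 33)
  pr <- marginal_1d_exact(s6, 2, grid, T = 300, n_mc = 2e5, seed = 9)
  # analytic marginal of an equal-width Gaussian mixture factorizes
  w <- s6$params$weights; ctr <- s6$params$centers[, 2]; s <- s6$params$width
  an <- -kB * 300 * log(w[1] * exp(-(grid - ctr[1])^2 / (2 * s^2)) +
                        w[2] * exp(-(grid - ctr[2])^2 / (2 * s^2)))
  an <- an - min(an)
  expect_lt(max(abs(pr$A - an)), 0.2)
  expect_true(all(pr$se > 0))
  # marginalization commutes with the reversal symmetry (d13 vs d24)
  pr24 <- marginal_1d_exact(s6, 5, grid, T = 300, n_mc = 2e5, seed = 10)
  expect_lt(max(abs(pr$A - pr24$A)), 0.2)
})

test_that("Langevin sampling reproduces the Gaussian stationary law and is reproducible", {
  qb <- make_surface("quad_bowl_nd", list(dim = 1, kappa = 1))
  tr <- langevin_sample(qb, T = 300, n_steps = 1e6, dt = 0.01, seed = 4,
                        save_stride = 5)
  expect_equal(var(tr$samples[, 1]), kB * 300, tolerance = 0.05)
  expect_equal(mean(tr$samples[, 1]), 0, tolerance = 0.02)
  tr2 <- langevin_sample(qb, T = 300, n_steps = 1e4, dt = 0.01, seed = 8)
  tr3 <- langevin_sample(qb, T = 300, n_steps = 1e4, dt = 0.01, seed = 8)
  expect_identical(tr2$samples, tr3$samples)
  expect_error(langevin_sample(qb, T = 300, n_steps = 1e3, dt = 1e3, seed = 1),
               "instability")
})

test_that("a deep double well shows no unbiased barrier crossings", {
  dw <- make_surface("double_well_1d", list(h = 10))
  crossings <- vapply(1:20, function(s) {
    tr <- langevin_sample(dw, T = 300, n_steps = 1e5, dt = 5e-4, x0 = -1,
                          seed = s, save_stride = 5)
    count_well_transitions(tr$samples[, 1])
  }, integer(1))
  expect_gte(sum(crossings == 0L), 19L)
})
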