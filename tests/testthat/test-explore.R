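test_that("the hill bias is additive and zero without hills", {
  expect_equal(bias_potential(NULL, c(0, 0)), 0)
  hills <- data.frame(step = c(10, 20), center.1 = c(1, 1), center.2 = c(2, 2),
                      height = c(0.5, 0.5), width.1 = c(0.3, 0.3),
                      width.2 = c(0.3, 0.3))
  expect_equal(bias_potential(hills, c(1, 2)), 1)          # 2 x height at center
  expect_equal(bias_potential(hills[1, ], c(1, 2)), 0.5)
  far <- bias_potential(hills, c(10, 10))
  expect_lt(far, 1e-10)
  expect_gte(far, 0)
})

test_that("TAMD bookkeeping: hill count and tether equilibrium", {
  qb <- make_surface("quad_bowl_nd", list(dim = 2, kappa = 1))
  ex <- run_tamd_metad(qb, 1L,
                       params = list(n_steps = 2e4, dt = 0.005, deposit_stride = 500,
                                     hill_height = 0.2, hill_width = 0.5,
                                     Tbar = 300, kappa_ext = 5),
                       x0 = c(0, 0), seed = 3)
  expect_equal(nrow(ex$hills), floor(2e4 / 500))
  # with zero hills and Tbar = T the tether displacement averages to zero
  ex0 <- run_tamd_metad(qb, 1L,
                        params = list(n_steps = 1e5, dt = 0.005, hill_height = 0,
                                      Tbar = 300, kappa_ext = 5, save_stride = 5),
                        x0 = c(0, 0), seed = 4)
  gap <- ex0$trajectory$samples[, 1] - ex0$z[, 1]
  expect_lt(abs(mean(gap)), 0.05)
  # and the bias stays identically zero
  expect_equal(sum(ex0$hills$height), 0)
})

test_that("biasing produces barrier crossings and broader coverage than plain dynamics", {
  dw <- make_surface("double_well_1d", list(h = 10))
  biased <- run_tamd_metad(dw, 1L,
                           params = list(n_steps = 1e5, dt = 5e-4, kappa_ext = 50,
                                         Tbar = 3000, hill_height = 0.5,
                                         hill_width = 0.3, deposit_stride = 500,
                                         friction_z = 1, save_stride = 5),
                           x0 = -1, seed = 21)
  expect_gte(count_well_transitions(biased$trajectory$samples[, 1]), 5L)
  unbiased <- langevin_sample(dw, T = 300, n_steps = 1e5, dt = 5e-4, x0 = -1,
                              seed = 21, save_stride = 5)
  cov_b <- coverage_report(biased$trajectory, 1, 40, -1.6, 1.6)
  cov_u <- coverage_report(unbiased, 1, 40, -1.6, 1.6)
  expect_gt(cov_b, cov_u)
})

test_that("coverage_report counts occupied bins", {
  const <- matrix(1, 50, 2)
  expect_equal(coverage_report(const, 1:2, 10, c(0, 0), c(2, 2)), 1 / 100)
  expect_equal(coverage_report(const, 1:2, 1, c(0, 0), c(2, 2)), 1)
  expect_error(coverage_report(const, 1:2, 10, c(0, 0), c(0, 2)), "zero-volume")
  expect_error(coverage_report(matrix(numeric(0), 0, 2), 1:2, 10, 0, 1), "empty")
})

test_that("hills round-trip through CSV", {
  qb <- make_surface("quad_bowl_nd", list(dim = 2, kappa = 1))
  ex <- run_tamd_metad(qb, 1:2,
                       params = list(n_steps = 5e3, dt = 0.005,
                                     deposit_stride = 250),
                       seed = 5)
  f <- tempfile(fileext = ".csv")
  write_hills(ex$hills, f)
  expect_equal(read_hills(f), ex$hills, tolerance = 1e-12)
})
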