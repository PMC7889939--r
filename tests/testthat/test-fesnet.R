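test_that("the analytic force-matching gradient matches finite differences", {
  model <- fes_build(layers = c(5, 4), features = "symmetric", seed = 7)
  set.seed(3)
  D <- matrix(runif(8 * 6, 5, 30), 8)
  Fm <- matrix(rnorm(8 * 6), 8)
  S <- symmetric_features(D)
  mu <- colMeans(S); sdv <- apply(S, 2, sd)
  Z <- sweep(sweep(S, 2, mu), 2, sdv, "/")
  wd <- 1e-3
  par <- model$par
  g <- fesfold:::.fes_loss_grad(par, D, Z, Fm, "symmetric", sdv, wd)
  total <- function(p)
    fesfold:::.fes_loss_grad(p, D, Z, Fm, "symmetric", sdv, wd)$loss +
      wd * (sum(unlist(lapply(p$W, function(w) sum(w^2)))) + sum(p$w_out^2))
  h <- 1e-6
  numgrad <- function(mutate) {
    p1 <- mutate(par, h); p2 <- mutate(par, -h)
    (total(p1) - total(p2)) / (2 * h)
  }
  checks <- list(
    list(an = g$gW[[1]][1, 2],
         f = function(p, d) { p$W[[1]][1, 2] <- p$W[[1]][1, 2] + d; p }),
    list(an = g$gW[[2]][3, 1],
         f = function(p, d) { p$W[[2]][3, 1] <- p$W[[2]][3, 1] + d; p }),
    list(an = g$gb[[1]][4],
         f = function(p, d) { p$b[[1]][4] <- p$b[[1]][4] + d; p }),
    list(an = g$gb[[2]][2],
         f = function(p, d) { p$b[[2]][2] <- p$b[[2]][2] + d; p }),
    list(an = g$g_wout[3],
         f = function(p, d) { p$w_out[3] <- p$w_out[3] + d; p }))
  for (ck in checks) {
    nu <- numgrad(ck$f)
    expect_lt(abs(ck$an - nu) / max(abs(nu), 1e-6), 1e-4)
  }
})

test_that("model construction is deterministic and symmetric by construction", {
  m1 <- fes_build(seed = 9); m2 <- fes_build(seed = 9)
  expect_identical(m1$par, m2$par)
  set.seed(5)
  D <- matrix(runif(1000 * 6, 1, 40), ncol = 6)
  e <- fesfold:::.fes_energy_grad(m1, D)$energy
  erev <- fesfold:::.fes_energy_grad(m1, D[, c(6, 5, 3, 4, 2, 1)])$energy
  expect_true(all(is.finite(e)))
  expect_identical(e, erev)
  expect_error(fes_build(layers = c(16, 0)), "positive width")
  expect_error(fes_build(features = "symmetric", dim = 4), "6-D")
})

test_that("a noiseless quadratic surface is learned nearly exactly", {
  fx <- quad6_records(500)
  fit <- fesnet(fx$records, epochs = 1500, seed = 1)
  expect_gte(fit$report$cor_pooled, 0.99)
  # gauge freedom: an independent fit differs by about a constant
  fit2 <- fesnet(fx$records, epochs = 1500, seed = 77)
  set.seed(10)
  probe <- fit$centers[sample.int(nrow(fit$centers), 200), ]
  dif <- predict(fit, probe)$energy - predict(fit2, probe)$energy
  expect_lt(sd(dif), 0.2)
  # determinism of the full fit
  fit3 <- fesnet(fx$records, epochs = 1500, seed = 1)
  expect_identical(fit$par, fit3$par)
})

test_that("all-zero forces train to a flat surface", {
  set.seed(6)
  ctr <- matrix(runif(100 * 6, 5, 30), 100)
  rec <- fesfold:::.mf_records(ctr, matrix(0, 100, 6), matrix(0, 100, 6),
                               k = Inf, T = 300, n_samples = 1L, seed = 6)
  fit <- fesnet(rec, epochs = 500, seed = 2)
  g <- fesfold:::.fes_energy_grad(fit, ctr)$grad
  expect_lte(sqrt(mean(g^2)), 1e-2)
  e <- predict(fit, ctr)$energy
  expect_lt(diff(range(e)), 0.1)
})

test_that("predicted forces are the exact negative gradient of predicted energy", {
  fx <- quad6_records(120)
  fit <- fesnet(fx$records, epochs = 300, seed = 3)
  set.seed(4)
  h <- 1e-4
  for (i in 1:10) {
    x <- runif(6, 2, 7)
    p <- predict(fit, x)
    fd <- vapply(1:6, function(j) {
      xp <- x; xm <- x; xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (predict(fit, xp)$energy - predict(fit, xm)$energy) / (2 * h)
    }, numeric(1))
    scale <- pmax(abs(p$force), 1e-3)
    expect_lt(max(abs(fd + drop(p$force)) / scale), 1e-4)
  }
})

test_that("the trusted domain contains the training centers and excludes far points", {
  fx <- quad6_records(120)
  fit <- fesnet(fx$records, epochs = 100, seed = 3)
  expect_true(all(fes_trusted(fit, fit$centers)))
  expect_false(fes_trusted(fit, rep(1000, 6)))
  p <- predict(fit, rep(1000, 6))
  expect_false(p$trusted)
  expect_true(is.finite(p$energy))
})

test_that("JSON serialization round-trips and matches the compiled evaluator", {
  fx <- quad6_records(120)
  fit <- fesnet(fx$records, epochs = 200, seed = 5)
  f <- tempfile(fileext = ".json")
  save_fesnet(fit, f)
  back <- load_fesnet(f)
  set.seed(11)
  D <- matrix(runif(50 * 6, 1, 9), 50)
  p1 <- predict(fit, D); p2 <- predict(back, D)
  expect_equal(p1$energy, p2$energy, tolerance = 1e-12)
  expect_equal(p1$force, p2$force, tolerance = 1e-12)
  expect_equal(p1$trusted, p2$trusted)
  cpp <- fesfold:::eval_batch_cpp(fesfold:::as_surface_spec(fit), D, TRUE)
  expect_equal(cpp$energy, p1$energy, tolerance = 1e-10)
  expect_equal(cpp$grad, -p1$force, tolerance = 1e-10)
})
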