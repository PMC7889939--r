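# Shared fixtures.  The full synthetic benchmark (exploration -> centers ->
# forces -> training -> marginal validation) is expensive, so it is run once
# per session and memoized for all test files that need it.

.bench_cache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (is.null(.bench_cache$bench)) {
    .bench_cache$bench <- benchmark_pipeline(seed = 42)
    .bench_cache$marginal <- benchmark_marginal(.bench_cache$bench, seed = 42)
  }
  list(bench = .bench_cache$bench, marginal = .bench_cache$marginal)
}

# a small bead model: four one-bead nucleosomes on the x axis plus optional
# flexible beads
colinear_model <- function(flexible = FALSE) {
  pos <- cbind(0:3, 0, 0)
  ids <- 1:4
  grp <- rep("core", 4)
  if (flexible) {
    pos <- rbind(pos, cbind(100 + 0:3, 50, 0))
    ids <- c(ids, 1:4)
    grp <- c(grp, rep("flexible", 4))
  }
  bead_model(pos, ids, grp)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# noiseless restrained-Gaussian records on a reversal-symmetric 6-D
# quadratic bowl (exactly learnable by the network)
quad6_records <- function(n = 500, seed = 5) {
  surf <- make_surface("quad_bowl_nd",
                       list(dim = 6, kappa = 0.5, center = c(3, 4, 5, 6, 4, 3)))
  set.seed(seed)
  ctr <- matrix(runif(n * 6, 1, 8), n)
  list(surface = surf,
       records = noisy_reference_forces(surf, ctr, noise_frac = 0, seed = seed))
}
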