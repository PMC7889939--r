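# Center selection by K-means and mean-force estimation from restrained
# sampling.  The mean force at a center d_o is the average restraint force
# F(d_o) = < k (d - d_o) > over the ensemble of the restrained system
# U + (k/2) |d - d_o|^2; it converges to -grad A(d_o) as k grows, with the
# restrained-Gaussian bias factor k/(k + kappa) on quadratic surfaces.

#' Select force-evaluation centers by K-means
#'
#' K-means clustering with k-means++ initialization (deterministic under the
#' given seed, Lloyd iterations, assignment ties broken by the lowest center
#' index).  Centers selected from broad biased sampling concentrate where
#' the system actually visits, so no histogram overlap between centers is
#' needed downstream.
#'
#' @param samples matrix of samples (rows) in collective-variable space.
#' @param n_centers number of centers (at most the number of distinct samples).
#' @param seed RNG seed.
#' @param iter_max maximum Lloyd iterations.
#' @return Object of class `center_set`: list with `centers` (matrix),
#'   `k`, `seed`.
#' @export
select_centers <- function(samples, n_centers, seed = 1, iter_max = 30L) {
  X <- as.matrix(samples)
  n_centers <- as.integer(n_centers)
  n_distinct <- nrow(unique(X))
  if (n_centers > n_distinct)
    .stopf("select_centers: n_centers (%d) exceeds distinct samples (%d)",
           n_centers, n_distinct)
  set.seed(seed)
  init <- .kmeanspp_init(X, n_centers)
  if (n_centers == n_distinct) {
    centers <- unique(X)
  } else {
    km <- suppressWarnings(
      kmeans(X, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    centers <- km$centers
  }
  dimnames(centers) <- NULL
  structure(list(centers = centers, k = n_centers, seed = seed),
            class = "center_set")
}

# k-means++ seeding: each new center sampled with probability proportional
# to the squared distance from the nearest already-chosen center
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[idx[1L], ])^2)
  for (i in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    idx[i + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[i + 1L], ])^2))
  }
  X[idx, , drop = FALSE]
}

#' @export
print.center_set <- function(x, ...) {
  cat(sprintf("center_set: %d centers in %d-D (seed %d)\n",
              nrow(x$centers), ncol(x$centers), x$seed))
  invisible(x)
}

#' Estimate the mean force at one center by restrained sampling
#'
#' Runs overdamped Langevin sampling on `U + (k/2) |d - d_o|^2` and returns
#' `F = mean(k (d - d_o))` over post-burn-in samples, the restrained-ensemble
#' estimator of the negative free energy gradient at `d_o`.  Standard errors
#' come from batch means (20 consecutive batches).
#'
#' @param surface a [make_surface()] object.
#' @param d_o restraint center.
#' @param k scalar spring constant (kcal/mol/nm^2) applied isotropically, or
#'   a per-component vector.
#' @param T temperature (K).
#' @param n_steps,dt,friction,save_stride Langevin settings.
#' @param burn_in fraction of saved samples discarded (default 0.2).
#' @param seed RNG seed.
#' @param n_batches batches for the standard error (default 20).
#' @return One-row data frame of class `mean_force_records` with columns
#'   `d.1...` (center), `F.1...` (force), `se.1...`, `k`, `T`,
#'   `n_samples`, `seed`.
#' @export
estimate_mean_force <- function(surface, d_o, k, T = 300, n_steps = 5e4,
                                dt = NULL, friction = 1, save_stride = 5L,
                                burn_in = 0.2, seed = 1, n_batches = 20L) {
  stopifnot(all(k > 0), burn_in >= 0, burn_in < 1)
  kvec <- if (length(k) == 1L) rep(k, length(d_o)) else k
  if (is.null(dt)) dt <- min(0.1 / max(kvec), 0.01)
  traj <- langevin_sample(surface, T = T, n_steps = n_steps, dt = dt,
                          friction = friction, x0 = d_o, seed = seed,
                          save_stride = save_stride,
                          restraint = list(k = kvec, center = d_o))
  S <- traj$samples
  keep <- S[-seq_len(floor(burn_in * nrow(S))), , drop = FALSE]
  Fmat <- sweep(keep, 2L, as.numeric(d_o)) * rep(kvec, each = nrow(keep))
  Fbar <- colMeans(Fmat)
  nb <- min(n_batches, nrow(keep))
  bid <- cut(seq_len(nrow(keep)), nb, labels = FALSE)
  bm <- apply(Fmat, 2L, function(col) tapply(col, bid, mean))
  se <- apply(bm, 2L, sd) / sqrt(nb)
  .mf_records(matrix(d_o, 1L), matrix(Fbar, 1L), matrix(se, 1L),
              k = mean(kvec), T = T, n_samples = nrow(keep), seed = seed)
}

.mf_records <- function(centers, forces, se, k, T, n_samples, seed) {
  d <- ncol(centers)
  df <- data.frame(centers, forces, se,
                   k = k, T = T, n_samples = n_samples, seed = seed)
  names(df) <- c(paste0("d.", seq_len(d)), paste0("F.", seq_len(d)),
                 paste0("se.", seq_len(d)), "k", "T", "n_samples", "seed")
  class(df) <- c("mean_force_records", "data.frame")
  df
}

#' Mean forces at a batch of centers
#'
#' Maps [estimate_mean_force()] over the rows of a center set with
#' deterministic per-center seeds; per-center failures are isolated and
#' reported, and the run fails only if more than 10 percent of centers fail.
#'
#' @param surface a [make_surface()] object.
#' @param centers a `center_set` or a matrix of centers.
#' @param k,T,n_steps,dt,friction,save_stride,burn_in see
#'   [estimate_mean_force()].
#' @param seed base seed; center `i` uses `seed + i`.
#' @return `mean_force_records` data frame, one row per successful center.
#' @export
batch_mean_forces <- function(surface, centers, k, T = 300, n_steps = 5e4,
                              dt = NULL, friction = 1, save_stride = 5L,
                              burn_in = 0.2, seed = 1) {
  C <- if (inherits(centers, "center_set")) centers$centers else as.matrix(centers)
  if (nrow(C) == 0L)
    return(.mf_records(matrix(numeric(0), 0, surface$dim),
                       matrix(numeric(0), 0, surface$dim),
                       matrix(numeric(0), 0, surface$dim),
                       k = numeric(0), T = numeric(0), n_samples = integer(0),
                       seed = integer(0)))
  rows <- vector("list", nrow(C))
  failed <- 0L
  for (i in seq_len(nrow(C))) {
    rows[[i]] <- tryCatch(
      estimate_mean_force(surface, C[i, ], k = k, T = T, n_steps = n_steps,
                          dt = dt, friction = friction,
                          save_stride = save_stride, burn_in = burn_in,
                          seed = seed + i),
      error = function(e) {
        warning(sprintf("center %d failed: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(rows[[i]])) failed <- failed + 1L
  }
  if (failed > 0.1 * nrow(C))
    .stopf("batch_mean_forces: %d of %d centers failed", failed, nrow(C))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  class(out) <- c("mean_force_records", "data.frame")
  out
}

#' Reference mean forces from the analytic gradient, with noise
#'
#' For benchmark surfaces the exact mean force at a center is the negative
#' analytic gradient.  This helper evaluates it at every center and adds
#' i.i.d. Gaussian noise with standard deviation `noise_frac` times the
#' root-mean-square force, emulating the statistical uncertainty of
#' simulation-estimated mean forces.
#'
#' @param surface a [make_surface()] object.
#' @param centers a `center_set` or matrix of centers.
#' @param noise_frac noise SD as a fraction of the pooled force RMS
#'   (default 0.05).
#' @param T temperature recorded in the records (K).
#' @param seed RNG seed for the noise.
#' @return `mean_force_records` data frame.
#' @export
noisy_reference_forces <- function(surface, centers, noise_frac = 0.05,
                                   T = 300, seed = 1) {
  C <- if (inherits(centers, "center_set")) centers$centers else as.matrix(centers)
  G <- .energy_batch(surface, C, grad = TRUE)$grad
  Fmat <- -G
  sdn <- noise_frac * .rms(Fmat)
  set.seed(seed)
  Fn <- Fmat + matrix(rnorm(length(Fmat), sd = sdn), nrow(Fmat))
  .mf_records(C, Fn, matrix(sdn, nrow(C), ncol(C)),
              k = Inf, T = T, n_samples = 1L, seed = seed)
}

#' Read / write mean-force records as CSV
#'
#' The CSV interchange format (`d.*`, `F.*`, `se.*`, `k`, `T`, `n_samples`,
#' `seed`) is the boundary at which externally computed mean forces (for
#' example from molecular dynamics engines) can be substituted.
#'
#' @param records a `mean_force_records` data frame.
#' @param path file path.
#' @return `path` (write) or the records (read).
#' @export
write_mean_forces <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mean_forces
#' @export
read_mean_forces <- function(path) {
  df <- read.csv(path)
  if (!all(c("k", "T", "n_samples") %in% names(df)) ||
      !length(grep("^d\\.", names(df))) || !length(grep("^F\\.", names(df))))
    .stopf("read_mean_forces: %s is not a mean-force CSV", path)
  class(df) <- c("mean_force_records", "data.frame")
  df
}

# split a records frame into centers / forces matrices
.records_matrices <- function(records) {
  dcol <- grep("^d\\.", names(records))
  fcol <- grep("^F\\.", names(records))
  list(centers = as.matrix(records[, dcol, drop = FALSE]),
       forces = as.matrix(records[, fcol, drop = FALSE]))
}
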