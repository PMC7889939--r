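# Umbrella sampling along one collective variable plus the weighted
# histogram analysis method (WHAM) to recombine the windows into an
# unbiased 1-D free energy profile -- the independent cross-check for
# marginals of the learned surface.

#' Umbrella sampling along one coordinate
#'
#' One restrained Langevin run per window on
#' `U + (spring/2) (x_cv - center)^2`, with deterministic per-window,
#' per-replica seeds derived from the base seed.  Rugged orthogonal degrees
#' of freedom can trap neighboring windows in different basins; pooling
#' several independent replicas per window (default 3) mitigates this.
#'
#' @param surface a [make_surface()] object.
#' @param cv_dim index of the restrained coordinate.
#' @param window_centers sorted vector of window centers.
#' @param spring window spring constant (kcal/mol/nm^2).
#' @param T temperature (K).
#' @param n_steps,dt,friction,save_stride,burn_in Langevin settings per
#'   replica.
#' @param n_seeds replicas pooled per window (default 3).
#' @param seed base seed.
#' @return List of `umbrella_window` objects: `center`, `spring`, `samples`
#'   (pooled scalar CV series), `seed`.
#' @export
run_umbrella <- function(surface, cv_dim, window_centers, spring, T = 300,
                         n_steps = 4e4, dt = NULL, friction = 1,
                         save_stride = 5L, burn_in = 0.2, n_seeds = 3L,
                         seed = 1) {
  stopifnot(spring > 0, !is.unsorted(window_centers))
  cv_dim <- as.integer(cv_dim)
  dim <- surface$dim
  if (is.null(dt)) dt <- min(0.1 / spring, 0.01)
  kvec <- rep(0, dim); kvec[cv_dim] <- spring
  out <- vector("list", length(window_centers))
  for (i in seq_along(window_centers)) {
    x0 <- (surface$lower + surface$upper) / 2
    x0[cv_dim] <- window_centers[i]
    ctr <- rep(0, dim); ctr[cv_dim] <- window_centers[i]
    pooled <- numeric(0)
    for (s in seq_len(n_seeds)) {
      traj <- langevin_sample(surface, T = T, n_steps = n_steps, dt = dt,
                              friction = friction, x0 = x0,
                              seed = seed + 1000L * i + s,
                              save_stride = save_stride,
                              restraint = list(k = kvec, center = ctr))
      cvs <- traj$samples[, cv_dim]
      pooled <- c(pooled, cvs[-seq_len(floor(burn_in * length(cvs)))])
    }
    if (length(pooled) < 100L)
      .stopf("run_umbrella: window %d kept only %d samples (need 100)",
             i, length(pooled))
    out[[i]] <- structure(list(center = window_centers[i], spring = spring,
                               samples = pooled, seed = seed, T = T),
                          class = "umbrella_window")
  }
  out
}

#' Solve the WHAM equations
#'
#' Standard self-consistent iteration over the window free energies f_i:
#' \deqn{P(x) \propto \frac{\sum_i n_i(x)}{\sum_j N_j \exp[(f_j - w_j(x))/k_B T]},
#'       \quad f_i = -k_B T \ln \sum_x P(x) e^{-w_i(x)/k_B T}}
#' with `w_i(x) = (spring_i/2)(x - center_i)^2`, iterated until
#' `max |delta f_i| < tol`.  Empty histogram bins carry zero counts and are
#' reported as missing rather than regularized.  The profile is
#' `-kB T log P`, minimum-shifted.
#'
#' @param windows list of `umbrella_window` objects.
#' @param n_bins number of fixed-width bins over the union of window sample
#'   ranges (default 100); alternatively pass explicit `breaks`.
#' @param T temperature (K).
#' @param tol convergence tolerance on the window offsets (kcal/mol,
#'   default 1e-6).
#' @param max_iter iteration cap.
#' @param breaks optional explicit bin breaks.
#' @return Object of class `wham_result`: `grid` (bin midpoints), `A`
#'   (kcal/mol, min-shifted, `NA` for empty bins), `f` (window offsets),
#'   `iterations`, `converged`, `overlap_ok`.
#' @export
wham_solve <- function(windows, n_bins = 100L, T = 300, tol = 1e-6,
                       max_iter = 10000L, breaks = NULL) {
  stopifnot(length(windows) >= 1L)
  kT <- kB * T
  allx <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(breaks)) breaks <- seq(min(allx), max(allx), length.out = n_bins + 1L)
  mid <- (head(breaks, -1L) + tail(breaks, -1L)) / 2
  nw <- length(windows)
  counts <- vapply(windows, function(w) {
    h <- hist(w$samples, breaks = breaks, plot = FALSE,
              include.lowest = TRUE, right = TRUE)
    h$counts
  }, numeric(length(mid)))              # bins x windows
  Ntot <- colSums(counts)
  bias <- vapply(windows, function(w) w$spring / 2 * (mid - w$center)^2,
                 numeric(length(mid)))  # bins x windows
  # adjacent-window histogram overlap check
  overlap_ok <- TRUE
  if (nw > 1L) for (i in seq_len(nw - 1L))
    if (!any(counts[, i] > 0 & counts[, i + 1L] > 0)) overlap_ok <- FALSE
  if (!overlap_ok)
    warning("wham_solve: adjacent windows share no occupied bins; profile unreliable",
            call. = FALSE)
  nsum <- rowSums(counts)
  f <- rep(0, nw)
  expb <- exp(-bias / kT)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    denom <- drop(expb %*% (Ntot * exp(f / kT))) # bins
    P <- nsum / pmax(denom, .Machine$double.xmin)
    fnew <- -kT * log(pmax(colSums(P * expb), .Machine$double.xmin))
    fnew <- fnew - fnew[1L]
    if (max(abs(fnew - f)) < tol) { f <- fnew; converged <- TRUE; break }
    f <- fnew
  }
  P <- nsum / pmax(drop(expb %*% (Ntot * exp(f / kT))), .Machine$double.xmin)
  A <- ifelse(nsum > 0, -kT * log(P), NA)
  A <- A - min(A, na.rm = TRUE)
  structure(list(grid = mid, A = A, f = f, iterations = it,
                 converged = converged, overlap_ok = overlap_ok, T = T),
            class = "wham_result")
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("wham_result: %d bins, %d window offsets, %s after %d iterations\n",
              length(x$grid), length(x$f),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Convert a WHAM result to a profile data frame
#'
#' @param result a `wham_result`.
#' @return An `fe_profile` data frame (`x`, `A`, `se`, `n_eff`) usable with
#'   [compare_profiles()].
#' @export
wham_profile <- function(result) {
  stopifnot(inherits(result, "wham_result"))
  .fe_profile(result$grid, result$A, rep(NA_real_, length(result$grid)))
}
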