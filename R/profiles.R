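# Marginal 1-D / 2-D free energy profiles of a learned or analytic surface,
# profile comparison, and contour export.
#
# For a learned surface the integration runs only over the trusted domain
# (points within the cutoff of a training center): outside it the network is
# unconstrained by data and its values are meaningless.  For analytic
# surfaces the integration box is the surface domain.

#' Marginal free energy profile
#'
#' For each grid value of the kept coordinate(s) the remaining dimensions
#' are integrated by Monte-Carlo:
#' `A(x) = -kB T log < exp(-A(full point)/kB T) * trusted(full point) >`
#' with uniform proposals over the integration box, points shared across the
#' grid (common random numbers), the minimum shifted to 0, and a delta-method
#' standard error per cell.  Grid cells whose trusted volume is (near) empty
#' are returned as missing (`NA`), not as errors.
#'
#' @param object a trained [fesnet()] model or a [make_surface()] surface.
#' @param dims one or two coordinate indices to keep.
#' @param grid numeric vector of grid values (1-D), or a list of two vectors
#'   (2-D).
#' @param T temperature (K).
#' @param n_mc Monte-Carlo points per grid cell.
#' @param seed RNG seed.
#' @param min_points cells with fewer trusted points are marked missing.
#' @return 1-D: `fe_profile` data frame (`x`, `A`, `se`, `n_eff`).
#'   2-D: object of class `fe_profile2d` with fields `x`, `y`, `A`, `se`
#'   (matrices).
#' @export
marginal_profile <- function(object, dims, grid, T = 300, n_mc = 2e4, seed = 1,
                             min_points = 20L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) %in% 1:2)
  is_model <- inherits(object, "fesnet")
  ndim <- if (is_model) object$dim else object$dim
  others <- setdiff(seq_len(ndim), dims)
  kT <- kB * T
  if (is_model) {
    lo <- apply(object$centers, 2L, min) - object$cutoff
    hi <- apply(object$centers, 2L, max) + object$cutoff
  } else {
    lo <- object$lower; hi <- object$upper
  }
  set.seed(seed)
  if (length(others)) {
    U <- vapply(others, function(j) runif(n_mc, lo[j], hi[j]), numeric(n_mc))
  } else U <- matrix(numeric(0), n_mc, 0L)
  gridlist <- if (is.list(grid)) grid else list(grid)
  stopifnot(length(gridlist) == length(dims))
  cells <- as.matrix(expand.grid(gridlist))
  ncell <- nrow(cells)
  A <- numeric(ncell); SE <- numeric(ncell); NEFF <- numeric(ncell)
  X <- matrix(NA_real_, n_mc, ndim)
  X[, others] <- U
  Aref <- NULL
  for (g in seq_len(ncell)) {
    for (j in seq_along(dims)) X[, dims[j]] <- cells[g, j]
    mask <- if (is_model) fes_trusted(object, X) else
      !(colSums(t(X) < lo) > 0 | colSums(t(X) > hi) > 0)
    nin <- sum(mask)
    if (nin < min_points) { A[g] <- NA; SE[g] <- NA; NEFF[g] <- nin; next }
    e <- .energy_batch(object, X[mask, , drop = FALSE])$energy
    if (is.null(Aref)) Aref <- min(e)
    f <- numeric(n_mc)
    f[mask] <- exp(-(e - Aref) / kT)
    m <- mean(f)
    A[g] <- -kT * log(m)
    SE[g] <- kT * sd(f) / sqrt(n_mc) / m
    NEFF[g] <- nin
  }
  A <- A - min(A, na.rm = TRUE)
  if (length(dims) == 1L) return(.fe_profile(cells[, 1L], A, SE, NEFF))
  nx <- length(gridlist[[1L]]); ny <- length(gridlist[[2L]])
  structure(list(x = gridlist[[1L]], y = gridlist[[2L]],
                 A = matrix(A, nx, ny), se = matrix(SE, nx, ny),
                 dims = dims, T = T),
            class = "fe_profile2d")
}

#' Compare two 1-D free energy profiles
#'
#' Profiles are matched on their common grid points (missing cells
#' excluded); the additive offset `mean(p - q)` is removed (free energies
#' are gauge quantities) and deviations are reported about it.
#'
#' @param p,q `fe_profile` data frames (columns `x`, `A`).
#' @return List with `offset`, `max_abs_dev`, `mean_abs_dev`, `n_common`.
#' @export
compare_profiles <- function(p, q) {
  ip <- match(round(q$x, 9), round(p$x, 9))
  common <- which(!is.na(ip))
  keep <- common[!is.na(q$A[common]) & !is.na(p$A[ip[common]])]
  if (length(keep) < 5L)
    .stopf("compare_profiles: overlapping support has only %d points (need 5)",
           length(keep))
  dif <- p$A[ip[keep]] - q$A[keep]
  off <- mean(dif)
  list(offset = off, max_abs_dev = max(abs(dif - off)),
       mean_abs_dev = mean(abs(dif - off)), n_common = length(keep))
}

#' Export a 2-D profile as gridded CSV and a contour figure
#'
#' @param profile a `fe_profile2d` from [marginal_profile()].
#' @param csv_path output CSV path (long format: x, y, A, se).
#' @param plot_path optional PNG path for a contour figure.
#' @param levels_interval contour interval in kcal/mol (default 1).
#' @return The long-format data frame, invisibly.
#' @export
contour_export <- function(profile, csv_path, plot_path = NULL,
                           levels_interval = 1) {
  stopifnot(inherits(profile, "fe_profile2d"))
  if (all(is.na(profile$A))) .stopf("contour_export: all cells are missing")
  df <- data.frame(x = rep(profile$x, times = length(profile$y)),
                   y = rep(profile$y, each = length(profile$x)),
                   A = as.vector(profile$A), se = as.vector(profile$se))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    rng <- range(profile$A, na.rm = TRUE)
    lev <- seq(floor(rng[1L]), ceiling(rng[2L]), by = levels_interval)
    png(plot_path, width = 900, height = 800, res = 130)
    contour(profile$x, profile$y, profile$A, levels = lev,
            xlab = paste0("dim ", profile$dims[1L]),
            ylab = paste0("dim ", profile$dims[2L]),
            main = "free energy (kcal/mol)")
    dev.off()
  }
  invisible(df)
}

#' Read a gridded profile CSV back into a 2-D profile
#'
#' @param csv_path path written by [contour_export()].
#' @return A `fe_profile2d`.
#' @export
read_profile2d <- function(csv_path) {
  df <- read.csv(csv_path)
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  A <- matrix(NA_real_, length(x), length(y))
  SE <- A
  ix <- match(df$x, x); iy <- match(df$y, y)
  A[cbind(ix, iy)] <- df$A
  SE[cbind(ix, iy)] <- df$se
  structure(list(x = x, y = y, A = A, se = SE, dims = NA, T = NA),
            class = "fe_profile2d")
}
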