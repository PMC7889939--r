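# Analytic benchmark potentials with exact gradients, an overdamped Langevin
# sampler, and exact/quadrature marginal profiles.  These surfaces stand in
# for the molecular system: samplers act directly in collective-variable
# space, so collective variables are coordinate projections.

#' Catalog of analytic benchmark surfaces
#'
#' Available surfaces:
#' \describe{
#'   \item{`double_well_1d`}{`A(x) = h (x^2 - 1)^2`, default `h = 5` kcal/mol:
#'     minima at -1 and +1, barrier `h` at 0.}
#'   \item{`muller_brown`}{the standard 4-term Gaussian Muller-Brown potential
#'     (its own energy/length units); deepest minimum near (-0.558, 1.442),
#'     second minimum near (0.623, 0.028), intermediate minimum near
#'     (-0.050, 0.467).}
#'   \item{`quad_bowl_nd`}{`A = 1/2 sum_i kappa_i (x_i - c_i)^2`; overrides:
#'     `dim`, `kappa` (scalar or per-dimension), `center`.}
#'   \item{`sym6d_wells`}{a reversal-symmetric 6-D two-basin Gaussian-mixture
#'     free energy in inter-nucleosome distance space:
#'     `A(d) = -kB T0 log(w_f G(d; c_f, s) + w_o G(d; c_o, s))` with a compact
#'     "folded" basin at `c_f = (9, 6, 12, 9, 6, 9)` nm and an extended
#'     "open" basin at `c_o = (15, 25, 32, 15, 25, 15)` nm, isotropic width
#'     `s = 3` nm, `T0 = 300` K, and weights fixed so the folded basin is
#'     2 kcal/mol deeper.  These constants are package benchmark choices.}
#'   \item{`channels_2d`}{two symmetric transition channels along the unit
#'     circle between minima at (-1, 0) and (1, 0):
#'     `A = h1 (x^2-1)^2 + h2 (x^2+y^2-1)^2` (defaults `h1 = 1`, `h2 = 5`);
#'     the direct route through the origin costs `h1 + h2`, each channel
#'     only `h1`.}
#' }
#'
#' @param name surface name (see above).
#' @param overrides named list of parameter overrides.
#' @return An object of class `toy_surface` with fields `name`, `dim`,
#'   `params`, `lower`/`upper` domain bounds, and `symmetric` (whether the
#'   energy is invariant under [reverse_order()]).
#' @export
make_surface <- function(name, overrides = list()) {
  stopifnot(is.list(overrides))
  p <- overrides
  surf <- switch(name,
    double_well_1d = {
      h <- p$h %||% 5
      list(dim = 1L, params = list(h = h),
           lower = -2.5, upper = 2.5, symmetric = FALSE,
           spec = list(type_id = 1L, dim = 1L, h = h))
    },
    muller_brown = {
      list(dim = 2L, params = list(),
           lower = c(-1.8, -0.5), upper = c(1.2, 2.3), symmetric = FALSE,
           spec = list(type_id = 2L, dim = 2L))
    },
    quad_bowl_nd = {
      dim <- as.integer(p$dim %||% 2L)
      kappa <- p$kappa %||% 1
      if (length(kappa) == 1L) kappa <- rep(kappa, dim)
      center <- p$center %||% rep(0, dim)
      stopifnot(length(kappa) == dim, length(center) == dim, all(kappa > 0))
      list(dim = dim, params = list(kappa = kappa, center = center),
           lower = center - 10, upper = center + 10, symmetric = FALSE,
           spec = list(type_id = 3L, dim = dim, kappa = kappa, center = center))
    },
    sym6d_wells = {
      T0 <- p$T0 %||% 300
      s <- p$width %||% 3
      c_f <- p$c_f %||% c(9, 6, 12, 9, 6, 9)
      c_o <- p$c_o %||% c(15, 25, 32, 15, 25, 15)
      gap <- p$depth_gap %||% 2
      kT <- kB * T0
      w <- c(exp(gap / kT), 1)          # folded deeper by `gap` kcal/mol
      centers <- rbind(folded = c_f, open = c_o)
      lo <- pmax(0.5, apply(centers, 2L, min) - 4 * s)
      hi <- apply(centers, 2L, max) + 4 * s
      list(dim = 6L,
           params = list(centers = centers, weights = w, width = s, T0 = T0,
                         depth_gap = gap),
           lower = lo, upper = hi, symmetric = TRUE,
           spec = list(type_id = 4L, dim = 6L, centers = centers, weights = w,
                       width = s, kT = kT))
    },
    channels_2d = {
      h1 <- p$h1 %||% 1; h2 <- p$h2 %||% 5
      list(dim = 2L, params = list(h1 = h1, h2 = h2),
           lower = c(-1.6, -1.6), upper = c(1.6, 1.6), symmetric = FALSE,
           spec = list(type_id = 5L, dim = 2L, h1 = h1, h2 = h2))
    },
    .stopf("make_surface: unknown surface '%s'", name)
  )
  surf$name <- name
  class(surf) <- "toy_surface"
  surf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.toy_surface <- function(x, ...) {
  cat(sprintf("toy_surface '%s': %d-D, domain [%s] x [%s]%s\n", x$name, x$dim,
              paste(signif(x$lower, 3), collapse = ", "),
              paste(signif(x$upper, 3), collapse = ", "),
              if (isTRUE(x$symmetric)) ", reversal-symmetric" else ""))
  invisible(x)
}

#' Evaluate a surface at one point
#'
#' @param surface a [make_surface()] object.
#' @param x point inside the surface domain.
#' @return List with `energy` (kcal/mol) and `gradient` (exact derivative).
#' @export
eval_surface <- function(surface, x) {
  stopifnot(inherits(surface, "toy_surface"))
  x <- as.numeric(x)
  if (length(x) != surface$dim)
    .stopf("eval_surface: expected %d coordinates, got %d", surface$dim, length(x))
  if (any(x < surface$lower) || any(x > surface$upper))
    .stopf("eval_surface: point outside the surface domain")
  out <- eval_batch_cpp(surface$spec, matrix(x, 1L), TRUE)
  list(energy = out$energy[1L], gradient = drop(out$grad))
}

# batch energy/gradient, no domain check (internal; also dispatches fesnet)
.energy_batch <- function(object, X, grad = FALSE) {
  X <- as.matrix(X)
  if (inherits(object, "toy_surface")) {
    out <- eval_batch_cpp(object$spec, X, grad)
  } else if (inherits(object, "fesnet")) {
    out <- eval_batch_cpp(as_surface_spec(object), X, grad)
  } else .stopf("unsupported surface object of class %s", class(object)[1L])
  out
}

#' Overdamped Langevin sampling of a surface
#'
#' Euler--Maruyama integration of
#' `x <- x - (dt/gamma) grad A(x) + sqrt(2 kB T dt / gamma) xi`
#' with standard-normal noise, optionally under a harmonic restraint
#' `(1/2) sum_j k_j (x_j - c_j)^2`.  Trajectories are bit-reproducible for a
#' fixed seed.
#'
#' @param surface a [make_surface()] object (or a fitted [fesnet()] model).
#' @param T temperature in K.
#' @param n_steps number of integration steps.
#' @param dt time step (units of gamma * length^2 / energy).
#' @param friction friction coefficient gamma.
#' @param x0 starting point (default: domain midpoint).
#' @param seed RNG seed.
#' @param save_stride keep every `save_stride`-th configuration.
#' @param restraint optional list with `k` (scalar or per-dimension spring,
#'   kcal/mol/nm^2) and `center`.
#' @return Object of class `trajectory`: list with `samples`
#'   (matrix, one row per saved configuration), and the run metadata.
#' @export
langevin_sample <- function(surface, T = 300, n_steps = 1e5, dt = 0.01,
                            friction = 1, x0 = NULL, seed = 1,
                            save_stride = 10L, restraint = NULL) {
  spec <- if (inherits(surface, "fesnet")) as_surface_spec(surface) else surface$spec
  dim <- spec$dim
  lower <- if (inherits(surface, "toy_surface")) surface$lower else rep(-Inf, dim)
  upper <- if (inherits(surface, "toy_surface")) surface$upper else rep(Inf, dim)
  if (any(!is.finite(lower))) { lower <- rep(-1e6, dim); upper <- rep(1e6, dim) }
  if (is.null(x0)) x0 <- (lower + upper) / 2
  stopifnot(length(x0) == dim, T > 0, dt > 0, n_steps >= save_stride)
  kres <- rep(0, dim); cres <- rep(0, dim)
  if (!is.null(restraint)) {
    k <- restraint$k
    if (length(k) == 1L) k <- rep(k, dim)
    stopifnot(length(k) == dim, all(k >= 0), length(restraint$center) == dim)
    kres <- k; cres <- as.numeric(restraint$center)
  }
  set.seed(seed)
  out <- langevin_cpp(spec, as.numeric(x0), as.integer(n_steps), dt, friction,
                      T, as.integer(save_stride), kres, cres, lower, upper)
  structure(list(samples = out$samples, final = drop(out$final), T = T,
                 dt = dt, friction = friction, seed = seed,
                 save_stride = as.integer(save_stride), n_steps = n_steps,
                 surface = if (inherits(surface, "toy_surface")) surface$name else "fesnet",
                 restraint = restraint),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory on '%s': %d saved samples (%d steps, dt = %g, T = %g K, seed %d)\n",
              x$surface, nrow(x$samples), x$n_steps, x$dt, x$T, x$seed))
  invisible(x)
}

#' Exact 1-D marginal free energy of an analytic surface
#'
#' Computes `A1(x) = -kB T log \int exp(-A / kB T)` over the remaining
#' dimensions of the surface domain.  Up to 3 integrated dimensions this uses
#' tensor-product Gauss--Legendre quadrature; above 3 it falls back to plain
#' Monte-Carlo integration over the domain box, with points shared across
#' grid values and a per-point standard error.  The minimum is shifted to 0.
#'
#' @param surface a [make_surface()] object.
#' @param dim index of the coordinate kept.
#' @param grid vector of grid values for the kept coordinate.
#' @param T temperature (K).
#' @param n_quad Gauss--Legendre nodes per integrated dimension.
#' @param n_mc Monte-Carlo sample count for the fallback.
#' @param seed RNG seed for the Monte-Carlo fallback.
#' @return Object of class `fe_profile`: data.frame with columns `x`,
#'   `A` (kcal/mol, min-shifted) and `se`.
#' @export
marginal_1d_exact <- function(surface, dim, grid, T = 300, n_quad = 40L,
                              n_mc = 2e5, seed = 1) {
  stopifnot(inherits(surface, "toy_surface"), dim >= 1, dim <= surface$dim)
  if (any(grid < surface$lower[dim] | grid > surface$upper[dim]))
    .stopf("marginal_1d_exact: grid outside the surface domain")
  kT <- kB * T
  others <- setdiff(seq_len(surface$dim), dim)
  ng <- length(grid)
  if (length(others) == 0L) {
    A <- .energy_batch(surface, matrix(grid, ncol = 1L))$energy
    return(.fe_profile(grid, A - min(A), rep(0, ng)))
  }
  if (length(others) <= 3L) {
    nodes <- lapply(others, function(j) {
      gl <- pracma::gaussLegendre(n_quad, surface$lower[j], surface$upper[j])
      list(x = gl$x, w = gl$w)
    })
    U <- as.matrix(expand.grid(lapply(nodes, `[[`, "x")))
    w <- Reduce(function(a, b) as.vector(outer(a, b)),
                lapply(nodes, `[[`, "w"))
    # outer() nests in the same order as expand.grid (first factor fastest)
    vals <- numeric(ng); ses <- rep(0, ng)
    X <- matrix(NA_real_, nrow(U), surface$dim)
    X[, others] <- U
    Aref <- NULL
    for (g in seq_len(ng)) {
      X[, dim] <- grid[g]
      A <- .energy_batch(surface, X)$energy
      if (is.null(Aref)) Aref <- min(A)
      vals[g] <- -kT * log(sum(w * exp(-(A - Aref) / kT)))
    }
    return(.fe_profile(grid, vals - min(vals), ses))
  }
  # Monte-Carlo fallback, common random numbers across the grid
  set.seed(seed)
  U <- vapply(others, function(j)
    runif(n_mc, surface$lower[j], surface$upper[j]), numeric(n_mc))
  vals <- numeric(ng); ses <- numeric(ng)
  X <- matrix(NA_real_, n_mc, surface$dim)
  X[, others] <- U
  Aref <- NULL
  for (g in seq_len(ng)) {
    X[, dim] <- grid[g]
    A <- .energy_batch(surface, X)$energy
    if (is.null(Aref)) Aref <- min(A)
    f <- exp(-(A - Aref) / kT)
    m <- mean(f)
    vals[g] <- -kT * log(m)
    ses[g] <- kT * sd(f) / sqrt(n_mc) / m
  }
  .fe_profile(grid, vals - min(vals), ses)
}

.fe_profile <- function(x, A, se, n_eff = NA_real_) {
  structure(data.frame(x = x, A = A, se = se,
                       n_eff = if (length(n_eff) == 1L) rep(n_eff, length(x)) else n_eff),
            class = c("fe_profile", "data.frame"))
}
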