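# Enhanced conformational exploration: metadynamics hills combined with
# temperature-accelerated dynamics (TAMD) along projection collective
# variables, plus coverage diagnostics.
#
# The physical coordinates x evolve at temperature T under the surface force
# plus a harmonic tether -kappa_ext (theta(x) - z); the extended variables z
# evolve at the elevated temperature Tbar under the tether reaction force
# minus the gradient of the accumulated hill bias.  Because toy surfaces
# live directly in collective-variable space, the collective variables are
# coordinate projections selected by index.

#' Metadynamics bias potential
#'
#' Sum of repulsive Gaussian hills
#' `sum_h height_h * exp(-sum_k (z_k - c_hk)^2 / (2 w_hk^2))`.
#'
#' @param hills data frame of deposited hills as returned by
#'   [run_tamd_metad()] (columns `step`, `center.1...`, `height`,
#'   `width.1...`), or NULL/empty for no bias.
#' @param z point in collective-variable space.
#' @return Bias energy in kcal/mol (0 for no hills).
#' @export
bias_potential <- function(hills, z) {
  if (is.null(hills) || nrow(hills) == 0L) return(0)
  ncv <- length(z)
  ctr <- as.matrix(hills[, grep("^center", names(hills)), drop = FALSE])
  wid <- as.matrix(hills[, grep("^width", names(hills)), drop = FALSE])
  stopifnot(ncol(ctr) == ncv, ncol(wid) == ncv)
  e <- rowSums(sweep(ctr, 2L, as.numeric(z))^2 / (2 * wid^2))
  sum(hills$height * exp(-e))
}

#' Biased exploration with metadynamics + TAMD
#'
#' @param surface a [make_surface()] object.
#' @param cv_dims integer indices of the coordinates used as collective
#'   variables.
#' @param params named list of run parameters; unset entries take the
#'   defaults: `kappa_ext = 2` (tether spring, kcal/mol/nm^2), `T = 300`,
#'   `Tbar = 3000` (extended temperature, K), `hill_height = 0.3` kcal/mol,
#'   `hill_width` (per CV, default 1.5), `deposit_stride = 250`,
#'   `n_steps = 2e5`, `dt = 0.02`, `friction_x = 1`, `friction_z = 5`,
#'   `save_stride = 10`, `k_wall = 50` (soft walls confining z to the CV
#'   domain), `well_tempered_dT = 0` (plain hills; > 0 enables well-tempered
#'   scaling).
#' @param x0 starting point (default domain midpoint).
#' @param seed RNG seed.
#' @return List with `trajectory` (the physical samples, class `trajectory`),
#'   `z` (matrix of extended-variable samples), `hills` (data frame) and
#'   `params`.
#' @export
run_tamd_metad <- function(surface, cv_dims, params = list(), x0 = NULL, seed = 1) {
  stopifnot(inherits(surface, "toy_surface"))
  cv_dims <- as.integer(cv_dims)
  stopifnot(all(cv_dims >= 1L), all(cv_dims <= surface$dim))
  p <- params
  def <- list(kappa_ext = 2, T = 300, Tbar = 3000, hill_height = 0.3,
              hill_width = rep(1.5, length(cv_dims)), deposit_stride = 250L,
              n_steps = 2e5, dt = 0.02, friction_x = 1, friction_z = 5,
              save_stride = 10L, k_wall = 50, well_tempered_dT = 0)
  for (nm in names(def)) if (is.null(p[[nm]])) p[[nm]] <- def[[nm]]
  if (length(p$hill_width) == 1L) p$hill_width <- rep(p$hill_width, length(cv_dims))
  stopifnot(p$hill_height >= 0, all(p$hill_width > 0), p$Tbar >= p$T)
  if (is.null(x0)) x0 <- (surface$lower + surface$upper) / 2
  z0 <- x0[cv_dims]
  set.seed(seed)
  out <- tamd_metad_cpp(surface$spec, as.numeric(x0), as.numeric(z0),
                        cv_dims - 1L, p$kappa_ext, p$T, p$Tbar,
                        p$friction_x, p$friction_z,
                        p$hill_height, p$hill_width,
                        as.integer(p$deposit_stride), as.integer(p$n_steps),
                        p$dt, as.integer(p$save_stride),
                        surface$lower[cv_dims], surface$upper[cv_dims],
                        p$k_wall, p$well_tempered_dT,
                        surface$lower, surface$upper)
  ncv <- length(cv_dims)
  hills <- as.data.frame(out$hills)
  if (out$n_hills == 0L) hills <- hills[0, , drop = FALSE]
  names(hills) <- c("step", paste0("center.", seq_len(ncv)), "height",
                    paste0("width.", seq_len(ncv)))
  traj <- structure(list(samples = out$x, final = out$x[nrow(out$x), ],
                         T = p$T, dt = p$dt, friction = p$friction_x,
                         seed = seed, save_stride = as.integer(p$save_stride),
                         n_steps = p$n_steps, surface = surface$name,
                         restraint = NULL),
                    class = "trajectory")
  list(trajectory = traj, z = out$z, hills = hills, params = p,
       cv_dims = cv_dims, seed = seed)
}

#' Fraction of occupied collective-variable bins
#'
#' Histograms trajectory collective variables over a stated bounding box and
#' reports the fraction of occupied bins -- a simple coverage diagnostic for
#' judging how uniformly an exploration run has visited CV space.
#'
#' @param trajectory a `trajectory` object or a sample matrix.
#' @param cv_dims coordinate indices used as collective variables.
#' @param bins number of bins per CV (scalar or per-CV vector).
#' @param lower,upper bounds of the CV bounding box (per CV).
#' @return Fraction of occupied bins in (0, 1].
#' @export
coverage_report <- function(trajectory, cv_dims, bins, lower, upper) {
  X <- if (inherits(trajectory, "trajectory")) trajectory$samples else as.matrix(trajectory)
  if (nrow(X) == 0L) .stopf("coverage_report: empty trajectory")
  cv_dims <- as.integer(cv_dims)
  ncv <- length(cv_dims)
  if (length(bins) == 1L) bins <- rep(as.integer(bins), ncv)
  stopifnot(length(lower) == ncv, length(upper) == ncv, all(bins >= 1L))
  if (any(upper <= lower)) .stopf("coverage_report: zero-volume bounding box")
  Z <- X[, cv_dims, drop = FALSE]
  idx <- vapply(seq_len(ncv), function(k) {
    i <- floor((Z[, k] - lower[k]) / (upper[k] - lower[k]) * bins[k])
    pmin(pmax(i, 0L), bins[k] - 1L)
  }, numeric(nrow(Z)))
  idx <- matrix(idx, ncol = ncv)
  key <- as.vector(idx %*% cumprod(c(1, bins[-ncv])))
  length(unique(key)) / prod(bins)
}

#' Count well-to-well transitions of a 1-D coordinate
#'
#' Counts alternating visits between the regions `x < lower` and `x > upper`
#' (a hysteresis band suppresses counting noise around a barrier top).
#'
#' @param x numeric series.
#' @param lower,upper boundaries of the two wells (default -0.5 / 0.5).
#' @return Integer number of transitions.
#' @export
count_well_transitions <- function(x, lower = -0.5, upper = 0.5) {
  state <- ifelse(x < lower, -1L, ifelse(x > upper, 1L, 0L))
  state <- state[state != 0L]
  if (length(state) < 2L) return(0L)
  sum(diff(state) != 0L)
}

#' Pooled biased exploration over independent replicas
#'
#' Runs [run_tamd_metad()] `n_replicas` times with seeds `seed + i` and
#' pools the physical samples.  Independent replicas with separate hill
#' histories cover the accessible collective-variable space far more
#' uniformly than one long run, which is what downstream center selection
#' needs.
#'
#' @inheritParams run_tamd_metad
#' @param n_replicas number of independent runs (default 20).
#' @return List with `samples` (pooled matrix), `replicas` (list of
#'   [run_tamd_metad()] results) and `seed`.
#' @export
explore_replicas <- function(surface, cv_dims, n_replicas = 20L,
                             params = list(), x0 = NULL, seed = 1) {
  reps <- vector("list", n_replicas)
  for (i in seq_len(n_replicas))
    reps[[i]] <- run_tamd_metad(surface, cv_dims, params = params, x0 = x0,
                                seed = seed + i)
  list(samples = do.call(rbind, lapply(reps, function(r) r$trajectory$samples)),
       replicas = reps, seed = seed)
}

#' Write / read metadynamics hills as CSV
#'
#' @param hills hills data frame from [run_tamd_metad()].
#' @param path file path.
#' @return `path` (write) or the hills data frame (read).
#' @export
write_hills <- function(hills, path) {
  write.csv(hills, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) read.csv(path)
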