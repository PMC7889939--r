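# Finite-temperature string method: a discretized path (images) between two
# basins is relaxed toward the most probable transition tube.  Each
# iteration samples the surface inside every image's Voronoi cell (Langevin
# proposals leaving the cell are rejected), moves images toward their cell
# means, smooths interior images, and reparameterizes to equal arc length.

#' Initialize a string path between two endpoints
#'
#' @param endpoint_a,endpoint_b path endpoints in collective-variable space.
#' @param M number of segments; the path carries `M + 1` images.
#' @param mode `"linear"` (equal-spaced interpolation) or `"through_point"`
#'   (piecewise-linear via `waypoint`, to seed distinct transition channels).
#' @param waypoint intermediate point for `"through_point"`.
#' @return Object of class `string_path`: `images` ((M+1) x dim matrix),
#'   `alpha` (arc-length parameters 0..1), `energy`, `history`, `seed`.
#' @export
initialize_string <- function(endpoint_a, endpoint_b, M = 32L,
                              mode = c("linear", "through_point"),
                              waypoint = NULL) {
  mode <- match.arg(mode)
  a <- as.numeric(endpoint_a); b <- as.numeric(endpoint_b)
  stopifnot(length(a) == length(b), M >= 8L)
  if (sqrt(sum((a - b)^2)) < 1e-12)
    .stopf("initialize_string: coincident endpoints")
  alpha <- seq(0, 1, length.out = M + 1L)
  if (mode == "linear") {
    images <- outer(1 - alpha, a) + outer(alpha, b)
  } else {
    stopifnot(!is.null(waypoint), length(waypoint) == length(a))
    w <- as.numeric(waypoint)
    l1 <- sqrt(sum((w - a)^2)); l2 <- sqrt(sum((b - w)^2))
    s <- alpha * (l1 + l2)
    images <- t(vapply(s, function(si) {
      if (si <= l1) a + (w - a) * (if (l1 > 0) si / l1 else 0)
      else w + (b - w) * (if (l2 > 0) (si - l1) / l2 else 0)
    }, numeric(length(a))))
  }
  structure(list(images = images, alpha = alpha, energy = NULL,
                 history = numeric(0), seed = NULL, converged = FALSE),
            class = "string_path")
}

#' @export
print.string_path <- function(x, ...) {
  cat(sprintf("string_path: %d images in %d-D%s\n", nrow(x$images),
              ncol(x$images),
              if (length(x$history))
                sprintf(", %d relaxation iterations (final displacement %.3g)%s",
                        length(x$history), tail(x$history, 1L),
                        if (isTRUE(x$converged)) ", converged" else "")
              else " (not relaxed)"))
  invisible(x)
}

# reparameterize images to equal arc length (piecewise linear), endpoints kept
.reparameterize <- function(images) {
  M1 <- nrow(images)
  seg <- sqrt(rowSums(diff(images)^2))
  s <- c(0, cumsum(seg))
  if (s[M1] < 1e-300) return(images)
  starget <- seq(0, s[M1], length.out = M1)
  out <- vapply(seq_len(ncol(images)), function(j)
    approx(s, images[, j], xout = starget, ties = "ordered")$y,
    numeric(M1))
  out[1L, ] <- images[1L, ]; out[M1, ] <- images[M1, ]
  out
}

#' Relax a string with the finite-temperature string method
#'
#' Per iteration and image: (1) Langevin sampling at temperature `T`
#' restricted to the image's Voronoi cell by rejection; (2) image update
#' `image <- (1 - alpha) image + alpha * cell_mean`; (3) smoothing of
#' interior images `z_i <- z_i + lambda (z_{i+1} - 2 z_i + z_{i-1})`;
#' (4) reparameterization to equal arc length.  Endpoints stay fixed at the
#' supplied minima (default) or relax within their own cells.  Iteration
#' stops when the maximum image displacement falls below `tol` or at
#' `max_iter`.
#'
#' @param object a [make_surface()] surface or trained [fesnet()] model.
#' @param path a [initialize_string()] path.
#' @param n_cell_samples Langevin steps per cell per iteration.
#' @param dt,friction,T sampler settings.
#' @param image_step relaxation step alpha toward the cell mean (default 0.1).
#' @param smooth smoothing strength lambda (default 0.1).
#' @param max_iter,tol stopping rule (displacement in CV units).
#' @param seed RNG seed.
#' @param endpoint_mode `"fixed"` or `"relaxed"`.
#' @return The relaxed `string_path`; `$history` holds the per-iteration
#'   maximum image displacement and `$energy` the per-image surface energy.
#' @export
fts_relax <- function(object, path, n_cell_samples = 300L, dt = 1e-3,
                      friction = 1, T = 300, image_step = 0.1, smooth = 0.1,
                      max_iter = 100L, tol = 1e-3, seed = 1,
                      endpoint_mode = c("fixed", "relaxed")) {
  endpoint_mode <- match.arg(endpoint_mode)
  stopifnot(inherits(path, "string_path"), tol > 0)
  spec <- if (inherits(object, "fesnet")) as_surface_spec(object) else object$spec
  if (inherits(object, "fesnet") && !all(fes_trusted(object, path$images)))
    warning("fts_relax: some initial images lie outside the trusted domain",
            call. = FALSE)
  images <- path$images
  M1 <- nrow(images); dim <- ncol(images)
  walkers <- images                     # per-cell walker state persists
  history <- numeric(0)
  set.seed(seed)
  converged <- FALSE
  upd_range <- if (endpoint_mode == "fixed") 2L:(M1 - 1L) else seq_len(M1)
  for (it in seq_len(max_iter)) {
    means <- images
    for (m in upd_range) {
      res <- voronoi_sample_cpp(spec, images, m - 1L, walkers[m, ],
                                as.integer(n_cell_samples), dt, friction, T, 1L)
      if (nrow(res$samples) == 0L)
        .stopf("fts_relax: cell of image %d captured no samples", m)
      walkers[m, ] <- res$final
      means[m, ] <- colMeans(res$samples)
    }
    new_images <- images
    new_images[upd_range, ] <- (1 - image_step) * images[upd_range, , drop = FALSE] +
      image_step * means[upd_range, , drop = FALSE]
    if (M1 > 2L) {
      interior <- 2L:(M1 - 1L)
      lap <- new_images[interior + 1L, , drop = FALSE] -
        2 * new_images[interior, , drop = FALSE] +
        new_images[interior - 1L, , drop = FALSE]
      new_images[interior, ] <- new_images[interior, , drop = FALSE] + smooth * lap
    }
    new_images <- .reparameterize(new_images)
    disp <- max(sqrt(rowSums((new_images - images)^2)))
    history <- c(history, disp)
    images <- new_images
    if (disp < tol) { converged <- TRUE; break }
  }
  path$images <- images
  path$alpha <- seq(0, 1, length.out = M1)
  path$history <- history
  path$seed <- seed
  path$converged <- converged
  path$energy <- .energy_batch(object, images)$energy
  path
}

#' Free energy profile along a string path
#'
#' Surface energy at each image, shifted so the reactant endpoint (first
#' image) is zero, reported against the image index (the reaction
#' coordinate index).
#'
#' @param object surface or trained model the path was relaxed on.
#' @param path a relaxed `string_path`.
#' @return Data frame with `index`, `A` (kcal/mol) and, for learned models,
#'   `trusted` flags.
#' @export
path_free_energy <- function(object, path) {
  stopifnot(inherits(path, "string_path"))
  e <- .energy_batch(object, path$images)$energy
  out <- data.frame(index = seq_len(nrow(path$images)) - 1L, A = e - e[1L])
  if (inherits(object, "fesnet"))
    out$trusted <- fes_trusted(object, path$images)
  out
}

#' Group relaxed paths into distinct transition channels
#'
#' Pairwise path distance is the mean over image index of the Euclidean
#' distance between corresponding images; single-linkage clustering is cut
#' at `distance_threshold`.  Groups are ordered by their lowest member
#' index.
#'
#' @param paths list of `string_path` objects with identical image counts.
#' @param distance_threshold linkage cut (CV units).
#' @return List of integer vectors of path indices, one per channel.
#' @export
cluster_paths <- function(paths, distance_threshold) {
  stopifnot(length(paths) >= 1L)
  M <- vapply(paths, function(p) nrow(p$images), integer(1))
  if (length(unique(M)) != 1L)
    .stopf("cluster_paths: paths have differing image counts: %s",
           paste(unique(M), collapse = ","))
  np <- length(paths)
  if (np == 1L) return(list(1L))
  if (!is.finite(distance_threshold)) return(list(seq_len(np)))
  dm <- matrix(0, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np)
    dm[i, j] <- dm[j, i] <-
      mean(sqrt(rowSums((paths[[i]]$images - paths[[j]]$images)^2)))
  hc <- hclust(stats::as.dist(dm), method = "single")
  memb <- cutree(hc, h = distance_threshold)
  groups <- split(seq_len(np), memb)
  names(groups) <- NULL
  groups[order(vapply(groups, min, integer(1)))]
}

#' Multi-start string protocol
#'
#' Runs `n_starts` independent string relaxations between the same
#' endpoints, seeding distinct channels with randomly drawn waypoints
#' inside the supplied box, then groups the converged paths into channels
#' with [cluster_paths()].
#'
#' @param object surface or trained model.
#' @param endpoint_a,endpoint_b endpoints (typically basin minima).
#' @param n_starts number of independent initializations (default 8).
#' @param waypoint_box list with `lower`/`upper` bounds the random waypoints
#'   are drawn from (default: bounding box of the endpoints).
#' @param M segments per string.
#' @param distance_threshold channel-grouping threshold.
#' @param seed base seed; start `i` uses `seed + i`.
#' @param ... passed to [fts_relax()].
#' @return List with `paths` (all relaxed paths) and `groups`
#'   (channel membership from [cluster_paths()]).
#' @export
string_multistart <- function(object, endpoint_a, endpoint_b, n_starts = 8L,
                              waypoint_box = NULL, M = 32L,
                              distance_threshold = 1, seed = 1, ...) {
  if (is.null(waypoint_box))
    waypoint_box <- list(lower = pmin(endpoint_a, endpoint_b),
                         upper = pmax(endpoint_a, endpoint_b))
  paths <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    set.seed(seed + i)
    wp <- runif(length(endpoint_a), waypoint_box$lower, waypoint_box$upper)
    p0 <- initialize_string(endpoint_a, endpoint_b, M = M,
                            mode = "through_point", waypoint = wp)
    paths[[i]] <- fts_relax(object, p0, seed = seed + i, ...)
  }
  list(paths = paths, groups = cluster_paths(paths, distance_threshold))
}

#' Write a string path (images + free energy) as CSV
#'
#' @param path a `string_path`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_string_path <- function(path, file) {
  df <- as.data.frame(path$images)
  names(df) <- paste0("cv.", seq_len(ncol(path$images)))
  df <- cbind(index = seq_len(nrow(df)) - 1L, df)
  if (!is.null(path$energy)) df$A <- path$energy - path$energy[1L]
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
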