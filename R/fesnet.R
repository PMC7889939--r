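# Symmetry-respecting neural-network free energy surface trained by force
# matching.  The network maps a distance vector d through reversal-invariant
# features s(d) and a small tanh multilayer perceptron to the free energy
# A(d); training minimizes the mean squared difference between the network
# gradient and the negative of the supplied mean forces,
#   L = mean_o | grad A(d_o) + F(d_o) |^2 ,
# so the fitted surface satisfies -grad A = F up to noise.  The gradient of
# L with respect to the weights runs through the input-gradient computation
# (double backprop), implemented analytically below and verified against
# finite differences in the test suite.  Because only gradients are fitted,
# A is defined up to an additive constant; the gauge is fixed by shifting
# the minimum over training centers to zero.

# ---- feature maps -----------------------------------------------------------

.feat_apply <- function(features, D) {
  if (features == "symmetric") symmetric_features(D) else D
}

# map the gradient w.r.t. features back to d-space: g_d = J(d)^T g_s
.feat_pullback <- function(features, D, Gs) {
  if (features == "identity") return(Gs)
  Gd <- matrix(0, nrow(D), 6L)
  Gd[, 1L] <- Gs[, 1L] + D[, 6L] * Gs[, 2L]
  Gd[, 6L] <- Gs[, 1L] + D[, 1L] * Gs[, 2L]
  Gd[, 2L] <- Gs[, 3L] + D[, 5L] * Gs[, 4L]
  Gd[, 5L] <- Gs[, 3L] + D[, 2L] * Gs[, 4L]
  Gd[, 3L] <- Gs[, 5L]
  Gd[, 4L] <- Gs[, 6L]
  Gd
}

# adjoint of the pullback: v_s = J(d) v_d (used by the training gradient)
.feat_pushforward <- function(features, D, Vd) {
  if (features == "identity") return(Vd)
  Vs <- matrix(0, nrow(D), 6L)
  Vs[, 1L] <- Vd[, 1L] + Vd[, 6L]
  Vs[, 2L] <- D[, 6L] * Vd[, 1L] + D[, 1L] * Vd[, 6L]
  Vs[, 3L] <- Vd[, 2L] + Vd[, 5L]
  Vs[, 4L] <- D[, 5L] * Vd[, 2L] + D[, 2L] * Vd[, 5L]
  Vs[, 5L] <- Vd[, 3L]
  Vs[, 6L] <- Vd[, 4L]
  Vs
}

# ---- forward pass and input gradient ---------------------------------------

# par: list(W = list of weight matrices, b = list of bias vectors,
#           w_out = output weights, b_out = scalar)
.fes_forward <- function(par, Z) {
  L <- length(par$W)
  A <- vector("list", L); Dl <- vector("list", L)
  cur <- Z
  for (l in seq_len(L)) {
    H <- cur %*% par$W[[l]]
    H <- sweep(H, 2L, par$b[[l]], "+")
    A[[l]] <- tanh(H)
    Dl[[l]] <- 1 - A[[l]]^2
    cur <- A[[l]]
  }
  E <- drop(cur %*% par$w_out) + par$b_out
  list(E = E, A = A, D = Dl)
}

# energy and gradient w.r.t. the raw inputs D (n x dim)
.fes_energy_grad <- function(model, D) {
  D <- as.matrix(D)
  S <- .feat_apply(model$features, D)
  Z <- sweep(sweep(S, 2L, model$norm$mu), 2L, model$norm$sd, "/")
  fw <- .fes_forward(model$par, Z)
  L <- length(model$par$W)
  B <- fw$D[[L]] * matrix(model$par$w_out, nrow(D), length(model$par$w_out),
                          byrow = TRUE)
  if (L > 1L) for (l in (L - 1L):1L)
    B <- fw$D[[l]] * (B %*% t(model$par$W[[l + 1L]]))
  Gz <- B %*% t(model$par$W[[1L]])
  Gs <- sweep(Gz, 2L, model$norm$sd, "/")
  Gd <- .feat_pullback(model$features, D, Gs)
  list(energy = fw$E - model$offset, grad = Gd)
}

# ---- force-matching loss and analytic weight gradient (double backprop) ----

.fes_loss_grad <- function(par, D, Z, Fm, features, sdvec, weight_decay) {
  n <- nrow(Z)
  L <- length(par$W)
  fw <- .fes_forward(par, Z)
  A <- fw$A; Dl <- fw$D
  wmat <- matrix(par$w_out, n, length(par$w_out), byrow = TRUE)
  # reverse chain for the input gradient
  B <- vector("list", L)
  B[[L]] <- Dl[[L]] * wmat
  if (L > 1L) for (l in (L - 1L):1L)
    B[[l]] <- Dl[[l]] * (B[[l + 1L]] %*% t(par$W[[l + 1L]]))
  Gz <- B[[1L]] %*% t(par$W[[1L]])
  Gs <- sweep(Gz, 2L, sdvec, "/")
  Gd <- .feat_pullback(features, D, Gs)
  R <- Gd + Fm                       # grad A + F
  loss <- mean(rowSums(R^2))
  Vd <- (2 / n) * R
  U0 <- sweep(.feat_pushforward(features, D, Vd), 2L, sdvec, "/")
  # forward tangent chain
  Tl <- vector("list", L + 1L); Ql <- vector("list", L)
  Tl[[1L]] <- U0                     # T_0
  for (l in seq_len(L)) {
    Ql[[l]] <- Tl[[l]] %*% par$W[[l]]
    Tl[[l + 1L]] <- Dl[[l]] * Ql[[l]]
  }
  gW <- vector("list", L); gb <- vector("list", L)
  g_wout <- colSums(Tl[[L + 1L]])
  # adjoints: Plist[[l]] = dphi/dT_l, Rl[[l]] = dphi/dH_l
  Rl <- vector("list", L)
  Plist <- vector("list", L); Plist[[L]] <- wmat
  if (L > 1L) for (l in (L - 1L):1L)
    Plist[[l]] <- (Plist[[l + 1L]] * Dl[[l + 1L]]) %*% t(par$W[[l + 1L]])
  for (l in L:1L) {
    Rl[[l]] <- -2 * Plist[[l]] * Ql[[l]] * A[[l]] * Dl[[l]]
    if (l < L) Rl[[l]] <- Rl[[l]] + Dl[[l]] * (Rl[[l + 1L]] %*% t(par$W[[l + 1L]]))
  }
  for (l in L:1L) {
    Aprev <- if (l == 1L) Z else A[[l - 1L]]
    gW[[l]] <- t(Tl[[l]]) %*% (Plist[[l]] * Dl[[l]]) + t(Aprev) %*% Rl[[l]] +
      2 * weight_decay * par$W[[l]]
    gb[[l]] <- colSums(Rl[[l]])
  }
  g_wout <- g_wout + 2 * weight_decay * par$w_out
  list(loss = loss, gW = gW, gb = gb, g_wout = g_wout, g_bout = 0)
}

# validation force loss (no parameter gradient needed)
.fes_val_loss <- function(par, D, Z, Fm, features, sdvec) {
  L <- length(par$W)
  fw <- .fes_forward(par, Z)
  B <- fw$D[[L]] * matrix(par$w_out, nrow(Z), length(par$w_out), byrow = TRUE)
  if (L > 1L) for (l in (L - 1L):1L)
    B <- fw$D[[l]] * (B %*% t(par$W[[l + 1L]]))
  Gz <- B %*% t(par$W[[1L]])
  Gs <- sweep(Gz, 2L, sdvec, "/")
  Gd <- .feat_pullback(features, D, Gs)
  mean(rowSums((Gd + Fm)^2))
}

# ---- construction and training ---------------------------------------------

#' Build an untrained free-energy-surface network
#'
#' Default architecture: input features -> 64 -> 64 -> 1 with tanh
#' activations.  tanh (rather than a piecewise-linear activation) keeps the
#' predicted forces continuous, which the string method downstream requires.
#' With `features = "symmetric"` the input passes through
#' [symmetric_features()], making the output exactly invariant under
#' [reverse_order()] by construction.
#'
#' @param layers integer vector of hidden layer widths (default `c(64, 64)`).
#' @param features `"symmetric"` (6-D distance vectors) or `"identity"`.
#' @param dim input dimension (must be 6 for symmetric features).
#' @param seed seed for the deterministic weight initialization.
#' @return Object of class `fesnet` (untrained: no normalization, no
#'   trusted domain).
#' @export
fes_build <- function(layers = c(64L, 64L), features = c("symmetric", "identity"),
                      dim = 6L, seed = 1) {
  features <- match.arg(features)
  layers <- as.integer(layers)
  if (length(layers) < 1L || any(layers < 1L))
    .stopf("fes_build: need at least one hidden layer of positive width")
  if (features == "symmetric" && dim != 6L)
    .stopf("fes_build: symmetric features require 6-D input")
  set.seed(seed)
  sizes <- c(dim, layers)
  W <- vector("list", length(layers)); b <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(1 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  w_out <- rnorm(layers[length(layers)], sd = sqrt(1 / layers[length(layers)]))
  structure(list(par = list(W = W, b = b, w_out = w_out, b_out = 0),
                 features = features, dim = as.integer(dim), layers = layers,
                 norm = list(mu = rep(0, dim), sd = rep(1, dim)),
                 offset = 0, centers = NULL, cutoff = NA_real_,
                 report = NULL, seed = seed),
            class = "fesnet")
}

#' Train a free-energy network by force matching
#'
#' Minimizes the mean squared mismatch between the network gradient and the
#' negative mean forces over the training records with full-batch Adam and
#' L2 weight decay.  A `split_fraction` share of records is held out: it
#' drives early stopping (fixed patience on the held-out force loss) and is
#' the data on which the reported pooled Pearson correlation between
#' predicted and reference forces is computed; held-out records never enter
#' the weight updates.  Features are standardized to zero mean and unit
#' variance over the training centers.  After training the energy gauge is
#' fixed (minimum over training centers = 0) and the trusted domain is
#' recorded: a point is trusted within `cutoff` of its nearest training
#' center, where `cutoff` defaults to twice the 95th percentile of
#' nearest-neighbor distances among the centers.
#'
#' @param model an untrained [fes_build()] model.
#' @param records `mean_force_records` (at least 50 rows).
#' @param split_fraction held-out fraction in (0, 1), default 0.2.
#' @param epochs maximum training epochs (default 3000).
#' @param lr Adam learning rate (default 3e-3).
#' @param weight_decay L2 penalty coefficient (default 1e-5).
#' @param patience early-stopping patience in epochs (default 50).
#' @param seed seed for the split (and any residual randomness).
#' @param verbose print progress every 100 epochs.
#' @return The trained `fesnet` model; its `$report` holds per-epoch
#'   train/validation force losses, the stopping epoch, and held-out
#'   per-component and pooled Pearson correlations.
#' @export
train_force_matching <- function(model, records, split_fraction = 0.2,
                                 epochs = 3000L, lr = 3e-3,
                                 weight_decay = 1e-5, patience = 50L,
                                 seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "fesnet"))
  m <- .records_matrices(records)
  n <- nrow(m$centers)
  if (n < 50L) .stopf("train_force_matching: need at least 50 records, got %d", n)
  if (split_fraction <= 0 || split_fraction >= 1)
    .stopf("train_force_matching: split_fraction must be in (0,1)")
  if (ncol(m$centers) != model$dim)
    .stopf("train_force_matching: records are %d-D but the model expects %d-D",
           ncol(m$centers), model$dim)
  set.seed(seed)
  val_idx <- sample.int(n, max(1L, round(split_fraction * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Dtr <- m$centers[tr_idx, , drop = FALSE]; Ftr <- m$forces[tr_idx, , drop = FALSE]
  Dva <- m$centers[val_idx, , drop = FALSE]; Fva <- m$forces[val_idx, , drop = FALSE]
  Str <- .feat_apply(model$features, Dtr)
  mu <- colMeans(Str)
  sdv <- apply(Str, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  model$norm <- list(mu = mu, sd = sdv)
  Ztr <- sweep(sweep(Str, 2L, mu), 2L, sdv, "/")
  Sva <- .feat_apply(model$features, Dva)
  Zva <- sweep(sweep(Sva, 2L, mu), 2L, sdv, "/")

  par <- model$par
  adam <- .adam_init(par)
  best <- list(loss = Inf, par = par, epoch = 0L)
  tl <- numeric(epochs); vl <- numeric(epochs)
  stopped <- epochs
  for (ep in seq_len(epochs)) {
    g <- .fes_loss_grad(par, Dtr, Ztr, Ftr, model$features, sdv, weight_decay)
    if (!is.finite(g$loss))
      .stopf("train_force_matching: non-finite loss at epoch %d (lr = %g too large?)",
             ep, lr)
    st <- .adam_step(par, g, adam, lr)
    par <- st$par; adam <- st$state
    tl[ep] <- g$loss
    vl[ep] <- .fes_val_loss(par, Dva, Zva, Fva, model$features, sdv)
    if (vl[ep] < best$loss) best <- list(loss = vl[ep], par = par, epoch = ep)
    if (verbose && ep %% 100L == 0L)
      message(sprintf("epoch %d: train %.5g  val %.5g", ep, tl[ep], vl[ep]))
    if (ep - best$epoch >= patience) { stopped <- ep; break }
  }
  model$par <- best$par
  tl <- tl[seq_len(stopped)]; vl <- vl[seq_len(stopped)]
  # gauge and trusted domain
  allC <- m$centers
  model$offset <- 0
  e_all <- .fes_energy_grad(model, allC)$energy
  model$offset <- min(e_all)
  model$centers <- allC
  nn <- .nn_dist_among(allC)
  model$cutoff <- 2 * as.numeric(quantile(nn, 0.95))
  # held-out force correlation
  pv <- .fes_energy_grad(model, Dva)
  pred <- -pv$grad
  safe_cor <- function(a, b)
    if (sd(a) < 1e-300 || sd(b) < 1e-300) NA_real_ else cor(a, b)
  cor_comp <- vapply(seq_len(ncol(pred)),
                     function(j) safe_cor(pred[, j], Fva[, j]), numeric(1))
  model$report <- list(train_loss = tl, val_loss = vl,
                       best_epoch = best$epoch, stopped_epoch = stopped,
                       cor_pooled = safe_cor(as.vector(pred), as.vector(Fva)),
                       cor_component = cor_comp,
                       n_train = length(tr_idx), n_val = length(val_idx),
                       val_pred_force = pred, val_ref_force = Fva,
                       hyper = list(epochs = epochs, lr = lr,
                                    weight_decay = weight_decay,
                                    patience = patience,
                                    split_fraction = split_fraction,
                                    seed = seed))
  model
}

# nearest-neighbor distances among rows (excluding self)
.nn_dist_among <- function(X, chunk = 2048L) {
  X <- as.matrix(X)
  x2 <- rowSums(X^2)
  out <- numeric(nrow(X))
  for (i0 in seq(1L, nrow(X), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(X))
    d2 <- outer(x2[i0:i1], x2, "+") - 2 * tcrossprod(X[i0:i1, , drop = FALSE], X)
    d2[cbind(seq_len(i1 - i0 + 1L), i0:i1)] <- Inf
    out[i0:i1] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

.adam_init <- function(par) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(par), v = zeros(par), t = 0L, beta1 = 0.9, beta2 = 0.999,
       eps = 1e-8)
}

.adam_step <- function(par, g, state, lr) {
  grads <- list(W = g$gW, b = g$gb, w_out = g$g_wout, b_out = g$g_bout)
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  upd <- function(p, gr, m, v) {
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + state$eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(par$W)) {
    u <- upd(par$W[[l]], grads$W[[l]], state$m$W[[l]], state$v$W[[l]])
    par$W[[l]] <- u$p; state$m$W[[l]] <- u$m; state$v$W[[l]] <- u$v
    u <- upd(par$b[[l]], grads$b[[l]], state$m$b[[l]], state$v$b[[l]])
    par$b[[l]] <- u$p; state$m$b[[l]] <- u$m; state$v$b[[l]] <- u$v
  }
  u <- upd(par$w_out, grads$w_out, state$m$w_out, state$v$w_out)
  par$w_out <- u$p; state$m$w_out <- u$m; state$v$w_out <- u$v
  list(par = par, state = state)
}

#' Fit a free energy surface to mean-force records
#'
#' One-call interface: builds the network ([fes_build()]) and trains it by
#' force matching ([train_force_matching()]).
#'
#' @param records `mean_force_records` data frame (centers and forces).
#' @param layers,features passed to [fes_build()].
#' @param ... training options passed to [train_force_matching()]
#'   (`split_fraction`, `epochs`, `lr`, `weight_decay`, `patience`,
#'   `verbose`).
#' @param seed seed controlling initialization and the held-out split.
#' @return A trained `fesnet` model.
#' @examples
#' surf <- make_surface("quad_bowl_nd",
#'                      list(dim = 6, kappa = 0.5, center = c(3, 4, 5, 6, 4, 3)))
#' ctr <- matrix(runif(100 * 6, 1, 8), 100)
#' rec <- noisy_reference_forces(surf, ctr, noise_frac = 0, seed = 1)
#' fit <- fesnet(rec, epochs = 200, seed = 1)
#' summary(fit)
#' @export
fesnet <- function(records, layers = c(64L, 64L), features = "symmetric",
                   seed = 1, ...) {
  m <- .records_matrices(records)
  model <- fes_build(layers = layers, features = features,
                     dim = ncol(m$centers), seed = seed)
  train_force_matching(model, records, seed = seed, ...)
}

# ---- methods ----------------------------------------------------------------

#' Predict free energy and mean force from a fitted surface
#'
#' @param object a trained `fesnet` model.
#' @param newdata distance vector or matrix of distance vectors (rows).
#' @param ... unused.
#' @return List with `energy` (kcal/mol, gauge: minimum over training
#'   centers is 0), `force` (the mean force, `-grad A`) and `trusted`
#'   (whether each point lies inside the trusted domain; predictions outside
#'   it are extrapolations).
#' @export
predict.fesnet <- function(object, newdata, ...) {
  D <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  eg <- .fes_energy_grad(object, D)
  list(energy = eg$energy, force = -eg$grad, trusted = fes_trusted(object, D))
}

#' Trusted-domain membership
#'
#' TRUE where the Euclidean distance to the nearest training center is at
#' most the model cutoff; the learned surface is unconstrained by data
#' outside this region.
#'
#' @param model a trained `fesnet` model.
#' @param d point or matrix of points.
#' @return Logical vector.
#' @export
fes_trusted <- function(model, d) {
  if (is.null(model$centers)) .stopf("fes_trusted: model is untrained")
  D <- if (is.matrix(d)) d else matrix(d, nrow = 1L)
  .nearest_dist(D, model$centers) <= model$cutoff
}

#' @export
print.fesnet <- function(x, ...) {
  cat(sprintf("fesnet: %s features, %d -> %s -> 1 (tanh)\n", x$features,
              x$dim, paste(x$layers, collapse = " -> ")))
  if (!is.null(x$report))
    cat(sprintf("  trained on %d records (%d held out); held-out force r = %.4f\n",
                x$report$n_train + x$report$n_val, x$report$n_val,
                x$report$cor_pooled))
  else cat("  (untrained)\n")
  invisible(x)
}

#' @export
summary.fesnet <- function(object, ...) {
  print(object)
  r <- object$report
  if (!is.null(r)) {
    cat(sprintf("  best epoch %d of %d; train loss %.5g, held-out loss %.5g\n",
                r$best_epoch, r$stopped_epoch,
                r$train_loss[r$best_epoch], r$val_loss[r$best_epoch]))
    cat("  held-out per-component force correlations:\n   ",
        paste(sprintf("%.3f", r$cor_component), collapse = "  "), "\n")
    cat(sprintf("  trusted domain: %d centers, cutoff %.3g nm\n",
                nrow(object$centers), object$cutoff))
  }
  invisible(object)
}

#' @export
coef.fesnet <- function(object, ...) object$par

#' @export
residuals.fesnet <- function(object, ...) {
  r <- object$report
  if (is.null(r)) .stopf("residuals: model is untrained")
  r$val_pred_force - r$val_ref_force
}

#' @export
plot.fesnet <- function(x, ...) {
  r <- x$report
  if (is.null(r)) .stopf("plot: model is untrained")
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  ep <- seq_along(r$train_loss)
  plot(ep, r$train_loss, type = "l", log = "y", xlab = "epoch",
       ylab = "force loss", main = "training")
  lines(ep, r$val_loss, col = 2)
  abline(v = r$best_epoch, lty = 3)
  plot(as.vector(r$val_ref_force), as.vector(r$val_pred_force), pch = ".",
       xlab = "reference force (kcal/mol/nm)",
       ylab = "predicted force (kcal/mol/nm)",
       main = sprintf("held-out, r = %.3f", r$cor_pooled))
  abline(0, 1, col = 2)
  invisible(x)
}

# surface spec consumed by the compiled samplers (2-hidden-layer models)
#' @keywords internal
as_surface_spec <- function(model) {
  stopifnot(inherits(model, "fesnet"))
  if (length(model$par$W) != 2L)
    .stopf("as_surface_spec: compiled samplers support 2-hidden-layer models")
  list(type_id = 6L, dim = model$dim,
       feat = if (model$features == "symmetric") 1L else 0L,
       fmu = model$norm$mu, fsd = model$norm$sd,
       W1 = model$par$W[[1L]], b1 = model$par$b[[1L]],
       W2 = model$par$W[[2L]], b2 = model$par$b[[2L]],
       w3 = model$par$w_out, b3 = model$par$b_out, offset = model$offset)
}

# ---- serialization ----------------------------------------------------------

#' Save / load a fitted surface as JSON
#'
#' The file stores the architecture, feature map, normalization, weights,
#' gauge offset and trusted domain (training centers and cutoff) as plain
#' arrays so any runtime can reload the surface.
#'
#' @param model a trained `fesnet` model.
#' @param path file path.
#' @return `path` (save) or the reloaded model (load).
#' @export
save_fesnet <- function(model, path) {
  stopifnot(inherits(model, "fesnet"))
  L <- length(model$par$W)
  obj <- list(features = model$features, dim = model$dim, layers = model$layers,
              W = stats::setNames(model$par$W, paste0("W", seq_len(L))),
              b = stats::setNames(model$par$b, paste0("b", seq_len(L))),
              w_out = model$par$w_out, b_out = model$par$b_out,
              mu = model$norm$mu, sd = model$norm$sd, offset = model$offset,
              centers = model$centers,
              cutoff = model$cutoff, seed = model$seed,
              cor_pooled = if (!is.null(model$report)) model$report$cor_pooled else NA)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fesnet
#' @export
load_fesnet <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(unname(o$W), function(w) as.matrix(w))
  b <- lapply(unname(o$b), as.numeric)
  structure(list(par = list(W = W, b = b, w_out = o$w_out, b_out = o$b_out),
                 features = o$features, dim = as.integer(o$dim),
                 layers = as.integer(o$layers),
                 norm = list(mu = o$mu, sd = o$sd), offset = o$offset,
                 centers = as.matrix(o$centers), cutoff = o$cutoff,
                 report = NULL, seed = o$seed),
            class = "fesnet")
}
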