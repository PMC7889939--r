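# Collective variables for nucleosome arrays: bead models, inter-nucleosome
# distance vectors, fraction of native contacts, radius of gyration, the
# index-reversal permutation and reversal-invariant features.

#' Construct a coarse-grained bead model of a nucleosome array
#'
#' A bead model holds 3-D bead positions (nm) together with per-bead labels:
#' the nucleosome each bead belongs to and whether the bead is part of the
#' rigid `core` (ordered histones plus inner nucleosomal DNA) or of the
#' `flexible` part (tails, outer and linker DNA).  Only core beads define
#' nucleosome centers.
#'
#' @param positions numeric matrix with 3 columns (x, y, z in nm).
#' @param nucleosome_id integer vector, one entry per bead, contiguous from 1.
#' @param group character vector per bead, `"core"` or `"flexible"`.
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(positions, nucleosome_id, group) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) .stopf("bead_model: positions must have 3 columns")
  if (nrow(positions) < 1L) .stopf("bead_model: empty model")
  if (!all(is.finite(positions))) .stopf("bead_model: non-finite positions")
  nucleosome_id <- as.integer(nucleosome_id)
  group <- as.character(group)
  if (length(nucleosome_id) != nrow(positions) || length(group) != nrow(positions))
    .stopf("bead_model: labels must match the number of beads")
  bad <- !group %in% c("core", "flexible")
  if (any(bad))
    .stopf("bead_model: unknown group label(s): %s",
           paste(unique(group[bad]), collapse = ", "))
  ids <- sort(unique(nucleosome_id))
  if (!identical(ids, seq_along(ids)))
    .stopf("bead_model: nucleosome ids must be contiguous from 1 (got %s)",
           paste(ids, collapse = ","))
  for (i in ids)
    if (!any(nucleosome_id == i & group == "core"))
      .stopf("bead_model: nucleosome %d has no core beads", i)
  structure(list(positions = positions, nucleosome_id = nucleosome_id,
                 group = group),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model: %d beads, %d nucleosomes (%d core, %d flexible beads)\n",
              nrow(x$positions), max(x$nucleosome_id),
              sum(x$group == "core"), sum(x$group == "flexible")))
  invisible(x)
}

#' Nucleosome centers of a bead model
#'
#' The center of nucleosome *i* is the unweighted centroid of its core beads.
#' Flexible beads do not contribute.
#'
#' @param model a [bead_model()].
#' @return Numeric matrix (one row per nucleosome, ordered by id) of centers in nm.
#' @export
nucleosome_centers <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  ids <- sort(unique(model$nucleosome_id))
  out <- matrix(NA_real_, length(ids), 3L)
  for (i in ids) {
    sel <- model$nucleosome_id == i & model$group == "core"
    out[i, ] <- colMeans(model$positions[sel, , drop = FALSE])
  }
  rownames(out) <- paste0("nuc", ids)
  out
}

.pair_order <- cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                     j = c(2L, 3L, 4L, 3L, 4L, 4L))
.pair_names <- c("d12", "d13", "d14", "d23", "d24", "d34")

#' Inter-nucleosome distance vector
#'
#' Euclidean distances between the four nucleosome centers in the fixed
#' lexicographic pair order `(d12, d13, d14, d23, d24, d34)`.
#'
#' @param centers numeric 4 x 3 matrix of nucleosome centers (nm).
#' @return Named numeric 6-vector of distances (nm).
#' @export
distance_vector <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 4L || ncol(centers) != 3L)
    .stopf("distance_vector: need exactly 4 centers in 3-D")
  if (!all(is.finite(centers))) .stopf("distance_vector: non-finite centers")
  d <- vapply(seq_len(6L), function(k) {
    sqrt(sum((centers[.pair_order[k, 1L], ] - centers[.pair_order[k, 2L], ])^2))
  }, numeric(1))
  names(d) <- .pair_names
  if (any(d == 0))
    message("distance_vector: coincident centers produced zero distance")
  d
}

#' Fraction of native contacts Q
#'
#' Gaussian-weighted similarity of a distance vector to a reference
#' (crystal-structure) distance vector:
#' \deqn{Q = \frac{1}{6}\sum_{i<j} \exp\left[-\frac{(d_{ij}-d^o_{ij})^2}{2\sigma^2}\right]}
#' with width `sigma` (default 2 nm).  Q is 1 exactly when `d` equals the
#' reference componentwise and decays to 0 as distances depart from it.
#'
#' @param d distance 6-vector (nm).
#' @param d_ref reference distance 6-vector (nm).
#' @param sigma Gaussian width in nm (default 2).
#' @return Q in (0, 1].
#' @export
fraction_native_contacts <- function(d, d_ref, sigma = 2) {
  stopifnot(length(d) == 6L, length(d_ref) == 6L, sigma > 0, all(d > 0),
            all(d_ref > 0))
  mean(exp(-(d - d_ref)^2 / (2 * sigma^2)))
}

#' Radius of gyration of a bead model
#'
#' Unweighted root-mean-square distance of all beads (core and flexible)
#' from their centroid.
#'
#' @param model a [bead_model()], or a bare matrix of positions.
#' @param which `"all"` (default) or `"core"`; which beads enter.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(model, which = c("all", "core")) {
  which <- match.arg(which)
  if (inherits(model, "bead_model")) {
    pos <- model$positions
    if (which == "core") pos <- pos[model$group == "core", , drop = FALSE]
  } else pos <- as.matrix(model)
  if (nrow(pos) < 1L) .stopf("radius_of_gyration: empty model")
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2L, ctr)^2)))
}

#' Index-reversal permutation of a distance vector
#'
#' Reversing the order of the four nucleosomes (1234 -> 4321) permutes the
#' distance vector as `(d12,...,d34) -> (d34, d24, d14, d23, d13, d12)`.
#' The free energy of a nucleosome array is (near-)invariant under this
#' relabeling, and the permutation is an involution.
#'
#' @param d distance 6-vector.
#' @return The permuted 6-vector.
#' @export
reverse_order <- function(d) {
  stopifnot(length(d) == 6L)
  out <- d[c(6L, 5L, 3L, 4L, 2L, 1L)]
  if (!is.null(names(d))) names(out) <- .pair_names
  out
}

#' Reversal-invariant features of a distance vector
#'
#' Maps `d` to `s(d) = (d12+d34, d12*d34, d13+d24, d13*d24, d14, d23)`.
#' Because sum and product are symmetric in the swapped pairs,
#' `s(d) == s(reverse_order(d))` exactly, and (sum, product) of a positive
#' pair determines the unordered pair uniquely, so no information is lost.
#'
#' @param d distance 6-vector, or a matrix with 6 columns (one row per vector).
#' @return Feature 6-vector (or matrix of feature rows).
#' @export
symmetric_features <- function(d) {
  if (is.matrix(d)) {
    stopifnot(ncol(d) == 6L)
    out <- cbind(d[, 1L] + d[, 6L], d[, 1L] * d[, 6L],
                 d[, 2L] + d[, 5L], d[, 2L] * d[, 5L],
                 d[, 3L], d[, 4L])
    colnames(out) <- c("s12p34", "s12t34", "s13p24", "s13t24", "s14", "s23")
    return(out)
  }
  stopifnot(length(d) == 6L)
  c(s12p34 = d[[1L]] + d[[6L]], s12t34 = d[[1L]] * d[[6L]],
    s13p24 = d[[2L]] + d[[5L]], s13t24 = d[[2L]] * d[[5L]],
    s14 = d[[3L]], s23 = d[[4L]])
}

#' Read a bead structure from disk
#'
#' Two formats are supported.  `csv`: a plain table with columns
#' `x, y, z, nucleosome_id, group` (coordinates in nm).  `pdb`: standard ATOM
#' records (coordinates in Angstrom, converted to nm); the chain identifier
#' maps to the nucleosome id via `chain_map` (default: chains in order of
#' appearance become ids 1, 2, ...), and the residue name `COR`/`FLX` carries
#' the core/flexible label.
#'
#' @param path file path.
#' @param format `"csv"` or `"pdb"`.
#' @param chain_map optional named integer vector mapping chain ids to
#'   nucleosome ids (PDB only).
#' @return A [bead_model()].
#' @export
read_bead_structure <- function(path, format = c("csv", "pdb"), chain_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("read_bead_structure: no such file: %s", path)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("x", "y", "z", "nucleosome_id", "group")
    miss <- setdiff(need, names(df))
    if (length(miss))
      .stopf("read_bead_structure: missing column(s) %s in %s",
             paste(miss, collapse = ", "), path)
    bad <- which(!df$group %in% c("core", "flexible"))
    if (length(bad))
      .stopf("read_bead_structure: unknown group label '%s' at line %d of %s",
             df$group[bad[1L]], bad[1L] + 1L, path)
    bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
    if (length(bad))
      .stopf("read_bead_structure: unparseable coordinates at line %d of %s",
             bad[1L] + 1L, path)
    return(bead_model(cbind(df$x, df$y, df$z), df$nucleosome_id, df$group))
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) .stopf("read_bead_structure: no ATOM records in %s", path)
  chains <- at$chain
  if (is.null(chain_map)) {
    uc <- unique(chains)
    chain_map <- stats::setNames(seq_along(uc), uc)
  }
  unknown <- setdiff(unique(chains), names(chain_map))
  if (length(unknown))
    .stopf("read_bead_structure: chain(s) %s missing from chain_map",
           paste(unknown, collapse = ","))
  grp <- ifelse(trimws(at$resid) == "COR", "core",
                ifelse(trimws(at$resid) == "FLX", "flexible", NA))
  if (anyNA(grp))
    .stopf("read_bead_structure: residue name must be COR or FLX (found '%s')",
           at$resid[which(is.na(grp))[1L]])
  bead_model(cbind(at$x, at$y, at$z) / 10, chain_map[chains], grp)
}

#' Write a bead structure to disk
#'
#' Inverse of [read_bead_structure()]; PDB output is in Angstrom with
#' nucleosomes as chains A, B, ... and residue names `COR`/`FLX`.
#'
#' @param model a [bead_model()].
#' @param path output file path.
#' @param format `"csv"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_bead_structure <- function(model, path, format = c("csv", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "bead_model"))
  if (format == "csv") {
    df <- data.frame(x = model$positions[, 1L], y = model$positions[, 2L],
                     z = model$positions[, 3L],
                     nucleosome_id = model$nucleosome_id, group = model$group)
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  n <- nrow(model$positions)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(model$positions * 10)),
                   resno = seq_len(n),
                   resid = ifelse(model$group == "core", "COR", "FLX"),
                   chain = LETTERS[model$nucleosome_id],
                   elety = rep("CA", n))
  invisible(path)
}
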