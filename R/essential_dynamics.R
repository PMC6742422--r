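# Essential dynamics: coarse-grained bead model (Calpha + nucleotide
# beads), roto-translational frame alignment, covariance PCA, and
# projections onto the leading components.

# nucleotide bead definitions: guanine ring, ribose, one bead per
# phosphate group (gamma absent in GDP), magnesium
.guanine_atoms <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
.ribose_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'", "O2'", "O3'", "C5'", "O5'")
.ribose_ring_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")
.phosphate_suffix <- c(alpha = "A", beta = "B", gamma = "G")

nucleotide_bead_groups <- function(atom_names) {
  nm <- toupper(gsub("\\*", "'", atom_names))  # some files use * for '
  groups <- list()
  gua <- which(nm %in% .guanine_atoms)
  rib <- which(nm %in% toupper(.ribose_atoms))
  missing_g <- setdiff(c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"), nm)
  missing_r <- setdiff(.ribose_ring_atoms, nm)
  if (length(missing_g) || length(missing_r))
    stop("coarse-graining error: nucleotide missing atoms ",
         paste(c(missing_g, missing_r), collapse = ", "))
  groups$guanine <- gua
  groups$ribose <- rib
  for (ph in names(.phosphate_suffix)) {
    sfx <- .phosphate_suffix[[ph]]
    idx <- which(nm %in% paste0(c("P", "O1", "O2", "O3"), sfx))
    if (length(idx)) groups[[paste0("phosphate_", ph)]] <- idx
  }
  if (!any(grepl("^phosphate", names(groups))))
    stop("coarse-graining error: nucleotide has no phosphate atoms")
  groups
}

#' Coarse-grained bead model for PCA / elastic networks
#'
#' One bead per retained Calpha (the subunit superposition cores, i.e.
#' excluding configured flexible loops and C-terminal tails), plus beads
#' for each bound nucleotide: one per guanine ring, ribose, phosphate
#' group, and magnesium ion when present (GDP therefore yields one fewer
#' phosphate bead and, by default, no Mg). Bead coordinates are
#' mass-weighted centroids of their source atoms and bead masses are the
#' summed atom masses.
#'
#' @param structure a `structure_model`.
#' @param selections list of `monomer_selection` (see [define_subunits()]).
#' @param include_mg include an Mg bead when a MG residue follows the
#'   nucleotide in the same chain (default TRUE).
#' @return object of class `bead_model`: `labels`, `classes` (calpha /
#'   guanine / ribose / phosphate_* / magnesium), `mass` (Da), `xyz`
#'   (n x 3, Angstrom), `source` (list of atom row indices).
#' @export
coarse_grain <- function(structure, selections, include_mg = TRUE) {
  masses <- atom_masses(structure)
  labels <- character(0); classes <- character(0)
  src <- list()
  for (sel in selections) {
    for (i in sel$core_idx) {
      src[[length(src) + 1]] <- i
      labels <- c(labels, sprintf("%s:CA%d", sel$label, structure$atoms$resno[i]))
      classes <- c(classes, "calpha")
    }
    if (length(sel$nuc_idx)) {
      grp <- nucleotide_bead_groups(structure$atoms$elety[sel$nuc_idx])
      for (g in names(grp)) {
        src[[length(src) + 1]] <- sel$nuc_idx[grp[[g]]]
        labels <- c(labels, sprintf("%s:%s", sel$label, g))
        classes <- c(classes, g)
      }
      if (include_mg) {
        mg <- which(structure$atoms$chain == sel$chain &
                      toupper(structure$atoms$resid) == "MG")
        if (length(mg)) {
          src[[length(src) + 1]] <- mg[1]
          labels <- c(labels, sprintf("%s:magnesium", sel$label))
          classes <- c(classes, "magnesium")
        }
      }
    }
  }
  n <- length(src)
  xyz <- matrix(0, n, 3)
  mass <- numeric(n)
  for (b in seq_len(n)) {
    idx <- src[[b]]
    m <- masses[idx]
    mass[b] <- sum(m)
    xyz[b, ] <- colSums(structure$xyz[idx, , drop = FALSE] * m) / sum(m)
  }
  structure(list(labels = labels, classes = classes, mass = mass,
                 xyz = xyz, source = src),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("bead_model: %d beads (%s)\n", length(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Map an atomic trajectory onto bead coordinates
#' @param trajectory a `trajectory_ensemble` over the full atom set.
#' @param bead_model a `bead_model` whose `source` indices refer to the
#'   trajectory's topology.
#' @return matrix, one row per frame, `3 * n_beads` columns (Angstrom).
#' @export
bead_trajectory <- function(trajectory, bead_model) {
  masses <- atom_masses(trajectory$topology)
  n_atoms <- nrow(trajectory$topology$atoms)
  nb <- length(bead_model$source)
  W <- matrix(0, n_atoms, nb)
  for (b in seq_len(nb)) {
    idx <- bead_model$source[[b]]
    W[idx, b] <- masses[idx] / sum(masses[idx])
  }
  fx <- trajectory$frames[, seq(1, 3 * n_atoms, 3), drop = FALSE] %*% W
  fy <- trajectory$frames[, seq(2, 3 * n_atoms, 3), drop = FALSE] %*% W
  fz <- trajectory$frames[, seq(3, 3 * n_atoms, 3), drop = FALSE] %*% W
  out <- matrix(0, nrow(trajectory$frames), 3 * nb)
  out[, seq(1, 3 * nb, 3)] <- fx
  out[, seq(2, 3 * nb, 3)] <- fy
  out[, seq(3, 3 * nb, 3)] <- fz
  out
}

#' Roto-translational alignment of trajectory frames
#'
#' Least-squares (Kabsch) superposition of every frame onto a reference
#' frame, removing rigid-body motion before covariance analysis.
#'
#' @param frames matrix, one row per frame, 3n columns.
#' @param reference reference coordinates (length 3n vector or n x 3
#'   matrix); default the first frame.
#' @param weights optional per-point fitting weights (e.g. bead masses).
#' @return aligned frames matrix of the same shape.
#' @export
align_frames <- function(frames, reference = NULL, weights = NULL) {
  frames <- as.matrix(frames)
  if (is.null(reference)) reference <- frames[1, ]
  ref <- if (is.matrix(reference) && ncol(reference) == 3) reference
         else matrix(as.numeric(reference), ncol = 3, byrow = TRUE)
  out <- frames
  for (i in seq_len(nrow(frames))) {
    x <- matrix(frames[i, ], ncol = 3, byrow = TRUE)
    tr <- superpose_core(x, ref, weights = weights)
    out[i, ] <- as.vector(t(apply_transform(x, tr)))
  }
  out
}

#' Coordinate covariance matrix of an aligned trajectory
#'
#' C\[i, j\] = < (x_i - <x_i>)(x_j - <x_j>) > over frames, with <...> the
#' average over sampled conformations.
#'
#' @param frames aligned frames matrix (one row per frame).
#' @param normalization "population" (divide by n, matching the plain
#'   ensemble average; default) or "sample" (n - 1).
#' @return symmetric positive semidefinite covariance matrix (3n x 3n).
#' @export
covariance_matrix <- function(frames, normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  frames <- as.matrix(frames)
  n <- nrow(frames)
  if (n < 2) stop("insufficient data: covariance needs at least 2 frames")
  ctr <- sweep(frames, 2, colMeans(frames))
  C <- crossprod(ctr) / if (normalization == "population") n else n - 1
  (C + t(C)) / 2
}

#' Leading principal components of a covariance matrix
#'
#' @param C covariance matrix.
#' @param n_modes number of leading eigenpairs to keep (default all).
#' @return object of class `mode_set`: `vectors` (unit columns, sign fixed
#'   so each vector's largest-magnitude component is positive), `values`
#'   (descending), `fractions` (share of the total variance, computed over
#'   the full spectrum), `provenance` = "PCA". Eigenvalue ties within
#'   1e-10 x trace are flagged in `degenerate`.
#' @export
principal_components <- function(C, n_modes = NULL) {
  eg <- eigen(C, symmetric = TRUE)
  total <- sum(pmax(eg$values, 0))
  if (is.null(n_modes)) n_modes <- length(eg$values)
  n_modes <- min(n_modes, length(eg$values))
  idx <- seq_len(n_modes)
  V <- eg$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  tie_tol <- 1e-10 * max(total, .Machine$double.eps)
  degenerate <- c(abs(diff(eg$values)) < tie_tol, FALSE)[idx]
  structure(list(vectors = V, values = eg$values[idx],
                 fractions = eg$values[idx] / total,
                 all_values = eg$values,
                 degenerate = degenerate, provenance = "PCA"),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes, leading fractions %s\n",
              x$provenance, ncol(x$vectors),
              paste(sprintf("%.3f", utils::head(x$fractions, 3)), collapse = ", ")))
  invisible(x)
}

#' Project frames onto a set of modes
#'
#' Centers the frames on their mean (or a supplied center) and takes dot
#' products with the mode vectors; the variance of the projection onto
#' mode k equals eigenvalue k when applied to the same data the PCA was
#' computed from (population normalization).
#'
#' @param frames aligned frames matrix.
#' @param modes a `mode_set`.
#' @param center optional length-3n centering vector (default column
#'   means of `frames`).
#' @return matrix of mode coordinates, one row per frame.
#' @export
project_modes <- function(frames, modes, center = NULL) {
  frames <- as.matrix(frames)
  if (is.null(center)) center <- colMeans(frames)
  sweep(frames, 2, center) %*% modes$vectors
}

#' Gaussian kernel density summary of a projection
#' @param proj numeric vector of mode coordinates.
#' @param n grid points (default 512).
#' @return `stats::density` object.
#' @export
projection_density <- function(proj, n = 512) stats::density(proj, n = n)
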