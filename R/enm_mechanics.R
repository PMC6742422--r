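# Heterogeneous elastic network models: construction at a distance
# cutoff, Boltzmann-inversion + iterative spring-constant parametrization
# against pair-distance fluctuations, normal modes, mode overlaps and
# classification, and beam-theory stiffness extraction.

#' Build an elastic network on a bead model
#'
#' Connects every pair of beads closer than the cutoff with a harmonic
#' spring whose rest length is the current distance (the network is built
#' on the straight reference conformation).
#'
#' @param bead_model a `bead_model`, or any list with `xyz` (n x 3,
#'   Angstrom) and `mass` (Da).
#' @param cutoff_nm distance cutoff in nm (default 0.8).
#' @param k0 initial uniform spring constant, N/m (default 1).
#' @return object of class `elastic_network`: `xyz` (Angstrom), `mass`
#'   (Da), `springs` (data.frame: i, j, rest_A, k), `cutoff_nm`,
#'   `n_components` (connected components; a warning is emitted when > 1).
#' @export
build_network <- function(bead_model, cutoff_nm = 0.8, k0 = 1) {
  stopifnot(cutoff_nm > 0, k0 > 0)
  xyz <- as.matrix(bead_model$xyz)
  n <- nrow(xyz)
  cutoff_A <- cutoff_nm * 10
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d < cutoff_A, arr.ind = TRUE)
  springs <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        rest_A = d[pairs], k = rep(k0, nrow(pairs)))
  ncomp <- n_components(n, springs)
  if (ncomp > 1)
    warning("elastic network is disconnected: ", ncomp, " components")
  structure(list(xyz = xyz, mass = bead_model$mass, springs = springs,
                 cutoff_nm = cutoff_nm, n_components = ncomp),
            class = "elastic_network")
}

n_components <- function(n, springs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(springs))) {
    a <- find(springs$i[r]); b <- find(springs$j[r])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network: %d beads, %d springs, cutoff %.2f nm, k in [%.3g, %.3g] N/m\n",
              nrow(x$xyz), nrow(x$springs), x$cutoff_nm,
              min(x$springs$k), max(x$springs$k)))
  invisible(x)
}

#' Hessian of the elastic-network potential
#'
#' Second derivatives of `sum_springs k/2 (|r_i - r_j| - rest)^2` at the
#' reference geometry: the standard anisotropic-network block structure
#' `-k e e^T` per spring. Optionally mass-weighted
#' (`M^-1/2 H M^-1/2`), in which case eigenvalues are squared angular
#' frequencies (rad^2/s^2).
#'
#' @param network an `elastic_network`.
#' @param mass_weighted logical (default TRUE).
#' @return symmetric 3n x 3n matrix; N/m entries when unweighted.
#' @export
enm_hessian <- function(network, mass_weighted = TRUE) {
  xyz <- network$xyz
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  sp <- network$springs
  for (r in seq_len(nrow(sp))) {
    i <- sp$i[r]; j <- sp$j[r]
    e <- unit(xyz[j, ] - xyz[i, ])
    blk <- sp$k[r] * tcrossprod(e)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  if (mass_weighted) {
    m_kg <- rep(network$mass * .dalton, each = 3)
    H <- H / sqrt(outer(m_kg, m_kg))
  }
  (H + t(H)) / 2
}

#' Normal modes of a (mass-weighted) Hessian
#'
#' Eigenpairs in ascending eigenvalue order with the six rigid-body modes
#' removed by magnitude threshold; each retained mode carries its angular
#' frequency omega_n = sqrt(lambda_n).
#'
#' @param hessian symmetric Hessian matrix (mass-weighted for physical
#'   frequencies).
#' @param rigid_tol rigid-mode threshold relative to the largest
#'   eigenvalue (default 1e-8).
#' @return `mode_set` with `values` (ascending), `omega` (sqrt of values),
#'   `n_rigid`, provenance "NMA".
#' @export
normal_modes <- function(hessian, rigid_tol = 1e-8) {
  eg <- eigen(hessian, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
  thr <- rigid_tol * max(vals)
  rigid <- vals < thr
  n_rigid <- sum(rigid)
  keep <- which(!rigid)
  V <- vecs[, keep, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  vals_k <- vals[keep]
  structure(list(vectors = V, values = vals_k,
                 omega = sqrt(pmax(vals_k, 0)),
                 fractions = rep(NA_real_, length(keep)),
                 n_rigid = n_rigid, rigid_values = vals[rigid],
                 provenance = "NMA"),
            class = "mode_set")
}

#' Pairwise overlaps (correlation cosines) between two mode sets
#' @param modes_a,modes_b `mode_set` objects over the same coordinates.
#' @return matrix of |cosine| values in \[0, 1\], rows = modes of `modes_a`.
#' @export
mode_overlap <- function(modes_a, modes_b) {
  abs(crossprod(modes_a$vectors, modes_b$vectors))
}

#' Thermal covariance implied by an elastic network
#'
#' kB T times the pseudo-inverse of the unweighted Hessian, with rigid
#' modes excluded by spectral truncation.
#'
#' @param network an `elastic_network`.
#' @param temperature_K temperature, K.
#' @param rigid_tol rigid-mode threshold (relative; default 1e-8).
#' @return 3n x 3n covariance matrix in Angstrom^2.
#' @export
enm_covariance <- function(network, temperature_K = 300, rigid_tol = 1e-8) {
  H <- enm_hessian(network, mass_weighted = FALSE)
  eg <- eigen(H, symmetric = TRUE)
  keep <- eg$values > rigid_tol * max(eg$values)
  lam <- eg$values[keep]; V <- eg$vectors[, keep, drop = FALSE]
  kBT <- .kB * temperature_K
  (V %*% (t(V) / lam)) * kBT * 1e20  # m^2 -> A^2
}

# Gauss-Hermite nodes/weights for a standard normal (Golub-Welsch on the
# Jacobi matrix, then change of variable x -> sqrt(2) x, w -> w/sqrt(pi))
gauss_hermite_normal <- function(q) {
  J <- matrix(0, q, q)
  off <- sqrt(seq_len(q - 1) / 2)
  J[cbind(seq_len(q - 1), 2:q)] <- off
  J[cbind(2:q, seq_len(q - 1))] <- off
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = sqrt(2) * eg$values, weights = eg$vectors[1, ]^2)
}

# cached 3-D product rule for E|mu + L z|, z ~ N(0, I3)
.gh_cache <- new.env(parent = emptyenv())
gh_grid3 <- function(q = 12L) {
  key <- as.character(q)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  gh <- gauss_hermite_normal(q)
  g <- expand.grid(gh$nodes, gh$nodes, gh$nodes)
  w <- expand.grid(gh$weights, gh$weights, gh$weights)
  out <- list(Z = as.matrix(g), w = w[, 1] * w[, 2] * w[, 3])
  .gh_cache[[key]] <- out
  out
}

# model-predicted variances of spring-pair distances (A^2). The relative
# displacement of a bonded pair is Gaussian with 3x3 covariance
# S = C_ii + C_jj - 2 C_ij, so d = |r0 + Delta| has E[d^2] = |r0|^2 + tr(S)
# exactly; E[d] is evaluated by Gauss-Hermite quadrature in the eigenframe
# of S. This full (not bond-linearized) prediction is comparable
# like-for-like with distance variances measured on sampled conformations,
# including the transverse-fluctuation contribution.
predicted_pair_variance <- function(network, C_A2, quad_points = 12L) {
  sp <- network$springs
  gh <- gh_grid3(quad_points)
  out <- numeric(nrow(sp))
  for (r in seq_len(nrow(sp))) {
    i <- sp$i[r]; j <- sp$j[r]
    dv <- network$xyz[j, ] - network$xyz[i, ]
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    S <- C_A2[ii, ii] + C_A2[jj, jj] - C_A2[ii, jj] - C_A2[jj, ii]
    S <- (S + t(S)) / 2
    eg <- eigen(S, symmetric = TRUE)
    sd3 <- sqrt(pmax(eg$values, 0))
    mu <- as.vector(crossprod(eg$vectors, dv))
    pts <- sweep(gh$Z, 2, sd3, "*")
    pts <- sweep(pts, 2, mu, "+")
    Ed <- sum(gh$w * sqrt(rowSums(pts^2)))
    out[r] <- sum(dv^2) + sum(eg$values) - Ed^2
  }
  out
}

# observed variances of spring-pair distances from a bead trajectory (A^2)
observed_pair_variance <- function(network, frames) {
  frames <- as.matrix(frames)
  sp <- network$springs
  nfr <- nrow(frames)
  out <- numeric(nrow(sp))
  ix <- function(i) (3 * i - 2):(3 * i)
  for (r in seq_len(nrow(sp))) {
    di <- frames[, ix(sp$i[r]), drop = FALSE] - frames[, ix(sp$j[r]), drop = FALSE]
    d <- sqrt(rowSums(di^2))
    out[r] <- stats::var(d) * (nfr - 1) / nfr
  }
  out
}

#' Parametrize a heterogeneous elastic network against pair-distance
#' fluctuations
#'
#' Spring constants are initialized by Boltzmann inversion,
#' `k_ij = kB T / var(d_ij)`, and refined iteratively: at each step the
#' pair-distance variances implied by the current network (via the
#' pseudo-inverse of its Hessian) are compared with the target variances
#' and each constant is updated multiplicatively by
#' `(var_model / var_target)^alpha` until the maximum relative deviation
#' of the predicted variances drops below `tol` or `max_iter` is reached.
#'
#' @param network an `elastic_network` (its `k` column seeds the uniform
#'   initialization when `init = "uniform"`).
#' @param frames bead trajectory matrix (rows = frames, Angstrom) sharing
#'   the network's bead topology; alternatively pass precomputed target
#'   variances via `target_var_A2`.
#' @param temperature_K temperature of the sampled ensemble.
#' @param tol convergence tolerance on max |var_model/var_target - 1|
#'   (default 1e-3).
#' @param max_iter maximum iterations (default 100).
#' @param alpha update exponent (default 0.5).
#' @param init "boltzmann" (default) or "uniform".
#' @param k_max cap for springs whose target variance is ~0 (default 1e4
#'   N/m).
#' @param target_var_A2 optional target variances (A^2), one per spring.
#' @return the network with fitted `springs$k`, plus attributes
#'   `converged`, `iterations`, `residual` (final max relative deviation)
#'   and `trace` (per-iteration residual).
#' @export
parametrize_heterogeneous <- function(network, frames = NULL,
                                      temperature_K = 300,
                                      tol = 1e-3, max_iter = 100, alpha = 0.5,
                                      init = c("boltzmann", "uniform"),
                                      k_max = 1e4, target_var_A2 = NULL) {
  init <- match.arg(init)
  if (is.null(target_var_A2)) {
    if (is.null(frames)) stop("supply frames or target_var_A2")
    if (ncol(as.matrix(frames)) != 3 * nrow(network$xyz))
      stop("trajectory does not share the network's bead topology")
    target_var_A2 <- observed_pair_variance(network, frames)
  }
  kBT <- .kB * temperature_K
  tv_m2 <- target_var_A2 * 1e-20
  pinned <- tv_m2 <= 0 | kBT / tv_m2 > k_max
  k <- if (init == "boltzmann") pmin(kBT / pmax(tv_m2, kBT / k_max), k_max)
       else rep(mean(network$springs$k), nrow(network$springs))
  k[pinned] <- k_max

  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    network$springs$k <- k
    vm <- predicted_pair_variance(network, enm_covariance(network, temperature_K))
    ratio <- vm / target_var_A2
    resid <- max(abs(ratio[!pinned] - 1))
    trace <- c(trace, resid)
    if (resid < tol) { converged <- TRUE; break }
    k[!pinned] <- pmin(k[!pinned] * ratio[!pinned]^alpha, k_max)
  }
  network$springs$k <- k
  attr(network, "converged") <- converged
  attr(network, "iterations") <- it
  attr(network, "residual") <- trace[length(trace)]
  attr(network, "trace") <- trace
  if (!converged)
    warning("parametrization did not converge: residual ",
            signif(trace[length(trace)], 3), " after ", it, " iterations")
  network
}
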