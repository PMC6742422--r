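# Synthetic ground-truth generators: idealized wall fragments, bent
# protofilaments, harmonic rigid-interface trajectories and Gaussian ENM
# ensembles. Every generator is deterministic under a fixed seed and
# returns its ground truth alongside the data.

.dalton <- 1.66053906660e-27  # kg

#' Rigid pseudo-subunit point cloud
#'
#' A fixed, asymmetric 20-point cloud standing in for one tubulin monomer.
#' The cloud is deliberately anisotropic so rigid-body superposition onto
#' it is well conditioned; alpha and beta variants differ so the two
#' monomer species are distinguishable.
#'
#' @param role "alpha" or "beta".
#' @return 20 x 3 matrix of local coordinates (Angstrom), centered at the
#'   origin.
#' @export
pseudo_subunit <- function(role = c("alpha", "beta")) {
  role <- match.arg(role)
  i <- 0:19
  # golden-angle spiral with role-dependent radial modulation: asymmetric,
  # full-rank inertia tensor, extent ~ 20 A x 15 A
  ga <- pi * (3 - sqrt(5))
  r <- 8 + 4 * cos(0.9 * i) + if (role == "alpha") 1.5 * sin(0.37 * i) else -2 * cos(0.53 * i)
  z <- (i - 9.5) * 1.6 + if (role == "alpha") 2 * sin(0.8 * i) else 1.2 * cos(1.1 * i)
  pts <- cbind(r * cos(ga * i), r * sin(ga * i), z)
  sweep(pts, 2, colMeans(pts))
}

#' Helical lattice specification for synthetic microtubule geometry
#'
#' @param n_protofilaments number of protofilaments (default 13).
#' @param n_subunits monomers per protofilament (default 2).
#' @param radius_A lattice radius, Angstrom (default 125, i.e. a ~25 nm
#'   wide microtubule).
#' @param rise_A axial rise per monomer, Angstrom (default 42).
#' @param start_number helical start number setting the lateral axial
#'   offset between neighboring protofilaments (default 3, the 13-3
#'   microtubule helix).
#' @return list of class `lattice_spec`.
#' @export
lattice_spec <- function(n_protofilaments = 13L, n_subunits = 2L,
                         radius_A = 125, rise_A = 42, start_number = 3L) {
  stopifnot(n_protofilaments >= 3, n_subunits >= 1, radius_A > 0, rise_A > 0)
  structure(list(n_pf = as.integer(n_protofilaments),
                 n_sub = as.integer(n_subunits),
                 radius = radius_A, rise = rise_A,
                 start_number = as.integer(start_number)),
            class = "lattice_spec")
}

site_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("too many lattice sites for single-character chain ids")
  pool[seq_len(n)]
}

#' Generate an idealized microtubule wall fragment
#'
#' Places rigid pseudo-subunits on a helical lattice around the global
#' z-axis (alpha/beta alternating along each protofilament) and returns
#' both the structure and the ground-truth reference lattice with exact
#' per-site triads.
#'
#' @param spec a [lattice_spec()].
#' @return list with `structure` (a `structure_model`, one chain per
#'   site), `lattice` (a `reference_lattice` with the true axis and
#'   triads), and `spec`.
#' @export
generate_wall_fragment <- function(spec = lattice_spec()) {
  n_sites <- spec$n_pf * spec$n_sub
  chains <- site_chain_ids(n_sites)
  # axial offset between laterally adjacent protofilaments (n-start helix)
  dimer_rise <- 2 * spec$rise
  lateral_dz <- spec$start_number * dimer_rise / spec$n_pf

  atoms <- list(); xyz <- list(); sites <- list()
  k <- 0L
  for (j in seq_len(spec$n_pf) - 1L) {
    ang <- 2 * pi * j / spec$n_pf
    xhat <- c(cos(ang), sin(ang), 0)
    zhat <- c(0, 0, 1)
    triad <- make_triad(xhat, cross3(zhat, xhat), zhat)
    for (s in seq_len(spec$n_sub) - 1L) {
      k <- k + 1L
      role <- if (s %% 2L == 0L) "alpha" else "beta"
      center <- spec$radius * xhat + c(0, 0, s * spec$rise + j * lateral_dz)
      cloud <- pseudo_subunit(role)
      pts <- sweep(cloud %*% t(triad), 2, center, "+")
      n0 <- (k - 1L) * 20L
      atoms[[k]] <- data.frame(
        eleno = n0 + 1:20, elety = "CA", elesy = "C",
        resno = 1:20, resid = "ALA", chain = chains[k], insert = "", occ = 1,
        stringsAsFactors = FALSE)
      xyz[[k]] <- pts
      sites[[k]] <- list(chain = chains[k], center = center, triad = triad,
                         core_idx = n0 + 1:20, role = role,
                         pf_index = j, long_index = s)
    }
  }
  struct <- structure_model(do.call(rbind, atoms), do.call(rbind, xyz))
  names(sites) <- chains
  lattice <- structure(list(wall = struct, axis = c(0, 0, 1),
                            origin = c(0, 0, 0), sites = sites,
                            outward = TRUE),
                       class = "reference_lattice")
  list(structure = struct, lattice = lattice, spec = spec)
}

#' Generate a protofilament bent by prescribed interface angles
#'
#' Builds a chain of rigid pseudo-subunits in which each successive
#' subunit is placed by composing the inverse of the bend/twist angle
#' decomposition, so [interface_angles()] applied downstream recovers the
#' prescribed (phi, theta, delta) exactly.
#'
#' @param angles data.frame or matrix with columns `phi`, `theta`, `delta`
#'   (degrees), one row per interface; the protofilament has
#'   `nrow(angles) + 1` subunits.
#' @param spec a [lattice_spec()] supplying radius and rise; the first
#'   subunit sits exactly on the lattice site of protofilament 0,
#'   longitudinal index 0.
#' @return list with `structure` (`structure_model`, chains `A`, `B`, ...
#'   ordered minus- to plus-end), `subunits` (list of `monomer_selection`),
#'   `triads` (list of per-subunit ground-truth triads), `angles` (the
#'   prescribed ground truth).
#' @export
generate_bent_protofilament <- function(angles, spec = lattice_spec()) {
  angles <- as.data.frame(angles)
  stopifnot(all(c("phi", "theta", "delta") %in% names(angles)))
  n_sub <- nrow(angles) + 1L
  chains <- site_chain_ids(n_sub)

  triads <- vector("list", n_sub)
  centers <- vector("list", n_sub)
  triads[[1]] <- make_triad(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  centers[[1]] <- c(spec$radius, 0, 0)
  for (i in seq_len(n_sub - 1L)) {
    M <- compose_interface_rotation(angles$phi[i], angles$theta[i], angles$delta[i])
    triads[[i + 1]] <- triads[[i]] %*% M
    centers[[i + 1]] <- centers[[i]] + spec$rise * triads[[i + 1]][, 3]
  }

  atoms <- list(); xyz <- list(); subunits <- list()
  for (i in seq_len(n_sub)) {
    role <- if ((i - 1L) %% 2L == 0L) "alpha" else "beta"
    cloud <- pseudo_subunit(role)
    pts <- sweep(cloud %*% t(triads[[i]]), 2, centers[[i]], "+")
    n0 <- (i - 1L) * 20L
    atoms[[i]] <- data.frame(
      eleno = n0 + 1:20, elety = "CA", elesy = "C",
      resno = 1:20, resid = "ALA", chain = chains[i], insert = "", occ = 1,
      stringsAsFactors = FALSE)
    xyz[[i]] <- pts
    subunits[[i]] <- structure(
      list(label = chains[i], role = role, chain = chains[i], resno = 1:20,
           atom_idx = n0 + 1:20, core_idx = n0 + 1:20,
           nucleotide = NULL, nuc_idx = integer(0),
           pf_index = 0L, long_index = i - 1L),
      class = "monomer_selection")
  }
  list(structure = structure_model(do.call(rbind, atoms), do.call(rbind, xyz)),
       subunits = subunits, triads = triads, angles = angles)
}

#' Ground truth for a harmonically fluctuating rigid interface
#'
#' @param theta0,phi0,delta0 equilibrium angles, degrees. Defaults are the
#'   relaxed GDP intra-dimer conformation observed in long explicit-solvent
#'   runs (theta0 = 9.4, phi0 = -48, delta0 = 5.2 degrees).
#' @param kappa_theta,kappa_delta harmonic stiffnesses of the bend and
#'   twist coordinates, kBT/rad^2.
#' @param temperature_K temperature (only bookkeeping: stiffnesses are in
#'   thermal units, so the sampled variance is 1/kappa rad^2).
#' @return list of class `interface_ground_truth`.
#' @export
interface_ground_truth <- function(theta0 = 9.4, phi0 = -48, delta0 = 5.2,
                                   kappa_theta = 930, kappa_delta = 990,
                                   temperature_K = 300) {
  stopifnot(kappa_theta > 0, kappa_delta > 0, theta0 >= 0, theta0 <= 90)
  structure(list(theta0 = theta0, phi0 = phi0, delta0 = delta0,
                 kappa_theta = kappa_theta, kappa_delta = kappa_delta,
                 temperature_K = temperature_K),
            class = "interface_ground_truth")
}

#' Generate a rigid-body trajectory of a harmonically fluctuating interface
#'
#' Two pseudo-subunits; the lower is fixed in lattice register, the upper
#' is re-posed every frame with angles drawn from the harmonic ensemble.
#' By default (`sampling = "angular"`) theta itself is Gaussian with
#' variance 1/kappa_theta (folded at zero; the folding correction is
#' sub-percent for theta0 >= 3 sigma) and phi fluctuates about phi0 with
#' the matched small-angle SD sigma_theta/theta0, so the equipartition
#' relation var(theta) = 1/kappa_theta holds by construction. The
#' alternative `sampling = "planar"` draws the 2-D coordinate
#' (theta cos phi, theta sin phi) from an isotropic Gaussian, which has no
#' folding at all but gives var(theta) a Rice-type deficit of order
#' (sigma/theta0)^2/4. The twist is Gaussian with variance 1/kappa_delta.
#'
#' @param truth an [interface_ground_truth()].
#' @param n_frames number of frames.
#' @param seed RNG seed (local to this call).
#' @param dt_ns frame spacing, ns (default 1).
#' @param spec [lattice_spec()] supplying rise and radius.
#' @param sampling "angular" (default) or "planar", see above.
#' @return list with `trajectory` (a `trajectory_ensemble`, chains A lower
#'   / B upper), `subunits`, `truth`, and `sampled_angles` (the per-frame
#'   ground-truth angles in degrees).
#' @export
generate_interface_trajectory <- function(truth, n_frames, seed = 1L,
                                          dt_ns = 1, spec = lattice_spec(),
                                          sampling = c("angular", "planar")) {
  stopifnot(inherits(truth, "interface_ground_truth"), n_frames >= 0)
  sampling <- match.arg(sampling)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sd_b <- sqrt(1 / truth$kappa_theta)  # rad
  sd_t <- sqrt(1 / truth$kappa_delta)
  th0 <- deg2rad(truth$theta0); ph0 <- deg2rad(truth$phi0)
  if (sampling == "planar") {
    u <- stats::rnorm(n_frames, th0 * cos(ph0), sd_b)
    v <- stats::rnorm(n_frames, th0 * sin(ph0), sd_b)
    theta <- sqrt(u^2 + v^2)
    phi <- atan2(v, u)
  } else {
    theta <- abs(stats::rnorm(n_frames, th0, sd_b))
    sd_phi <- if (th0 > 0) sd_b / th0 else pi
    phi <- stats::rnorm(n_frames, ph0, sd_phi)
    phi <- (phi + pi) %% (2 * pi) - pi
  }
  delta <- stats::rnorm(n_frames, deg2rad(truth$delta0), sd_t)

  lower_cloud <- pseudo_subunit("alpha")
  upper_cloud <- pseudo_subunit("beta")
  c_lower <- c(spec$radius, 0, 0)
  lower_pts <- sweep(lower_cloud, 2, c_lower, "+")  # identity triad
  frames <- matrix(0, nrow = max(n_frames, 0), ncol = 120)
  for (i in seq_len(n_frames)) {
    M <- compose_interface_rotation(rad2deg(phi[i]), rad2deg(theta[i]),
                                    rad2deg(delta[i]))
    c_upper <- c_lower + spec$rise * M[, 3]
    upper_pts <- sweep(upper_cloud %*% t(M), 2, c_upper, "+")
    frames[i, ] <- as.vector(t(rbind(lower_pts, upper_pts)))
  }

  atoms <- data.frame(
    eleno = 1:40, elety = "CA", elesy = "C",
    resno = rep(1:20, 2), resid = "ALA",
    chain = rep(c("A", "B"), each = 20), insert = "", occ = 1,
    stringsAsFactors = FALSE)
  topo <- structure_model(atoms, rbind(lower_pts,
                                       sweep(upper_cloud, 2, c_lower + c(0, 0, spec$rise), "+")))
  subunits <- define_subunits(topo, list(
    list(label = "lower", chain = "A", role = "alpha", exclude_cterm = 0L),
    list(label = "upper", chain = "B", role = "beta", exclude_cterm = 0L)))
  trj <- if (n_frames > 0)
    trajectory_ensemble(topo, frames, times = (seq_len(n_frames) - 1) * dt_ns)
  else trajectory_ensemble(topo, matrix(numeric(0), 0, 120), times = numeric(0))
  list(trajectory = trj, subunits = subunits, truth = truth,
       sampled_angles = data.frame(phi = rad2deg(phi), theta = rad2deg(theta),
                                   delta = rad2deg(delta)))
}

#' Sample a Gaussian conformational ensemble implied by an elastic network
#'
#' Draws frames from the multivariate normal with covariance
#' kB T x (pseudo-inverse of the unweighted Hessian), rigid-body modes
#' excluded, added to the reference geometry. At T = 0 every frame equals
#' the reference.
#'
#' @param network an `elastic_network` (see [build_network()]).
#' @param temperature_K temperature, K.
#' @param n_frames number of frames.
#' @param seed RNG seed (local to this call).
#' @return list with `frames` (n_frames x 3n matrix, Angstrom),
#'   `trajectory` (a `trajectory_ensemble` over one-bead-per-atom
#'   topology), and `model_covariance` (3n x 3n, Angstrom^2).
#' @export
generate_enm_ensemble <- function(network, temperature_K = 300, n_frames = 1000,
                                  seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  H <- enm_hessian(network, mass_weighted = FALSE)  # N/m
  eg <- eigen(H, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  lam <- eg$values[keep]; V <- eg$vectors[, keep, drop = FALSE]
  kBT <- .kB * temperature_K
  amp_m <- sqrt(kBT / lam)                       # meters
  amp_A <- amp_m * 1e10
  ref <- as.vector(t(network$xyz))               # Angstrom
  nc <- length(ref)
  if (temperature_K <= 0) {
    frames <- matrix(rep(ref, each = n_frames), n_frames, nc)
  } else {
    xi <- matrix(stats::rnorm(n_frames * length(lam)), n_frames)
    frames <- sweep(xi %*% (t(V) * amp_A), 2, ref, "+")
  }
  Cmod <- (V %*% (t(V) * amp_A^2))
  topo <- bead_topology(network)
  trj <- trajectory_ensemble(topo, frames)
  list(frames = frames, trajectory = trj, model_covariance = Cmod)
}

bead_topology <- function(network) {
  n <- nrow(network$xyz)
  atoms <- data.frame(eleno = seq_len(n), elety = "BD", elesy = "C",
                      resno = seq_len(n), resid = "BEA", chain = "A",
                      insert = "", occ = 1, stringsAsFactors = FALSE)
  structure_model(atoms, network$xyz)
}

# save/restore the global RNG state so generators are pure under `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
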