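#' Bend/twist decomposition of the relative rotation of two monomer triads
#'
#' Decomposes the rotation carrying the lower (minus-end-proximal) monomer
#' frame onto the upper monomer frame into three angles: the bend magnitude
#' theta (angle between the two z-axes), the bend direction phi (signed
#' azimuth of the upper z-axis projected onto the lower xy-plane, with
#' phi = 0 for strictly outward radial tilt), and the twist delta about the
#' tilted axis. The auxiliary frame x', y', z' is the lower frame rotated
#' by theta about P = z x Z (Rodrigues); delta = acos(x' . X) with sign
#' given by the triple product of {x', X, Z}.
#'
#' @param lower 3x3 orthonormal triad of the lower monomer (columns x,y,z).
#' @param upper 3x3 orthonormal triad of the upper monomer (columns X,Y,Z).
#' @param degeneracy_tol theta below which phi is undefined and reported 0,
#'   degrees (default 1e-6).
#' @return named numeric vector `c(phi, theta, delta)` in degrees, with
#'   attribute `degenerate` (TRUE when theta fell below the tolerance).
#'   theta is in \[0, 180\] (values near or above 90 trigger a warning);
#'   phi, delta lie in (-180, 180\].
#' @export
interface_angles <- function(lower, upper, degeneracy_tol = 1e-6) {
  stopifnot(check_triad(lower, 1e-8), check_triad(upper, 1e-8))
  M <- unname(crossprod(lower, upper))  # columns = X, Y, Z in the lower frame
  Z <- M[, 3]
  ct <- max(-1, min(1, Z[3]))
  theta <- acos(ct)
  degenerate <- rad2deg(theta) < degeneracy_tol
  if (rad2deg(theta) > 89)
    warning("bend angle near or beyond 90 degrees; direction poorly conditioned")
  if (degenerate) {
    phi <- 0
    # relative rotation is (numerically) a pure rotation about z
    delta <- atan2(M[2, 1], M[1, 1])
  } else {
    phi <- atan2(Z[2], Z[1])
    P <- c(-Z[2], Z[1], 0)  # z x Z
    # below this norm the bend rotation is numerically the identity
    xprime <- if (vnorm(P) < 1e-12) c(1, 0, 0)
              else as.vector(rotation_about(P, theta) %*% c(1, 0, 0))
    X <- M[, 1]
    cd <- max(-1, min(1, sum(xprime * X)))
    delta <- acos(cd) * sign_or_one(det(cbind(xprime, X, Z)))
  }
  out <- c(phi = rad2deg(phi), theta = rad2deg(theta), delta = rad2deg(delta))
  attr(out, "degenerate") <- degenerate
  out
}

sign_or_one <- function(x) if (x < 0) -1 else 1

# lean decomposition of a relative rotation (columns = X, Y, Z in the
# lower frame); same math as interface_angles without validation, for the
# per-frame trajectory loop. Returns c(phi, theta, delta, degenerate).
.decompose_relative <- function(M, degeneracy_tol = 1e-6) {
  Zx <- M[1, 3]; Zy <- M[2, 3]; Zz <- M[3, 3]
  theta <- acos(max(-1, min(1, Zz)))
  if (theta * 180 / pi < degeneracy_tol) {
    return(c(0, theta * 180 / pi, atan2(M[2, 1], M[1, 1]) * 180 / pi, 1))
  }
  phi <- atan2(Zy, Zx)
  pn <- sqrt(Zx * Zx + Zy * Zy)
  if (pn < 1e-12) {
    xprime <- c(1, 0, 0)
  } else {
    # Rodrigues rotation of (1,0,0) by theta about unit (-Zy, Zx, 0)/pn
    a1 <- -Zy / pn; a2 <- Zx / pn
    ct <- Zz; st <- sin(theta)
    xprime <- c(ct + (1 - ct) * a1 * a1, (1 - ct) * a1 * a2, -st * a2)
  }
  X <- M[, 1]
  cd <- max(-1, min(1, sum(xprime * X)))
  Z <- M[, 3]
  trip <- xprime[1] * (X[2] * Z[3] - X[3] * Z[2]) -
          xprime[2] * (X[1] * Z[3] - X[3] * Z[1]) +
          xprime[3] * (X[1] * Z[2] - X[2] * Z[1])
  delta <- acos(cd) * if (trip < 0) -1 else 1
  c(phi * 180 / pi, theta * 180 / pi, delta * 180 / pi, 0)
}

#' Relative rotation realizing given bend/twist angles
#'
#' Inverse of [interface_angles()]: builds the rotation matrix that, applied
#' to a lower-monomer triad, yields an upper triad with the requested bend
#' direction, bend magnitude and twist.
#'
#' @param phi,theta,delta angles in degrees (theta in \[0, 180), phi and
#'   delta in (-180, 180\]).
#' @return 3x3 rotation matrix `M` such that `upper = lower %*% M`.
#' @export
compose_interface_rotation <- function(phi, theta, delta) {
  ph <- deg2rad(phi); th <- deg2rad(theta); de <- deg2rad(delta)
  if (abs(th) < 1e-15) return(rotation_about(c(0, 0, 1), de))
  P <- c(-sin(ph), cos(ph), 0)
  Rb <- rotation_about(P, th)
  Z <- Rb %*% c(0, 0, 1)
  rotation_about(as.vector(Z), de) %*% Rb
}

#' Carry lattice triads onto a pair of monomers
#'
#' Superposes the wall-fragment site of the lower monomer onto the lower
#' monomer's core atoms (Kabsch), yielding the lower orientation triad, and
#' a second wall copy onto the upper monomer, yielding the upper triad
#' X, Y, Z. Both transported triads are the lattice site triads rotated by
#' the respective fitted rotations.
#'
#' @param frame_xyz n x 3 coordinates of the current frame (full system).
#' @param lower_sel,upper_sel `monomer_selection` objects (see
#'   [define_subunits()]); their `core_idx` atoms are used for fitting.
#' @param lattice a `reference_lattice`.
#' @param lower_site,upper_site site names (chains of the wall fragment)
#'   the monomers correspond to.
#' @param lower_pair_idx,upper_pair_idx optional atom rows of the wall
#'   structure paired 1:1 with the monomer core atoms; default the site's
#'   own atoms (valid when wall site and monomer share an atom layout).
#' @return list with `lower`, `upper` (3x3 triads in the world frame),
#'   `rmsd_lower`, `rmsd_upper` (Angstrom) and the fitted transforms.
#' @export
monomer_triads <- function(frame_xyz, lower_sel, upper_sel, lattice,
                           lower_site, upper_site,
                           lower_pair_idx = NULL, upper_pair_idx = NULL) {
  carry <- function(sel, site_name, pair_idx) {
    site <- lattice$sites[[site_name]]
    if (is.null(site)) stop("unknown lattice site: ", site_name)
    widx <- pair_idx %||% site$core_idx
    wall_xyz <- lattice$wall$xyz[widx, , drop = FALSE]
    mono_xyz <- frame_xyz[sel$core_idx, , drop = FALSE]
    if (nrow(wall_xyz) != nrow(mono_xyz))
      stop("cannot pair wall site ", site_name, " (", nrow(wall_xyz),
           " atoms) with monomer core (", nrow(mono_xyz), " atoms)")
    tr <- superpose_core(wall_xyz, mono_xyz)
    list(triad = tr$R %*% site$triad, rmsd = tr$rmsd, transform = tr)
  }
  lo <- carry(lower_sel, lower_site, lower_pair_idx)
  up <- carry(upper_sel, upper_site, upper_pair_idx)
  list(lower = lo$triad, upper = up$triad,
       rmsd_lower = lo$rmsd, rmsd_upper = up$rmsd,
       transform_lower = lo$transform, transform_upper = up$transform)
}

#' Per-frame interface angle series for a trajectory
#'
#' Applies [monomer_triads()] + [interface_angles()] at every sampled frame
#' of a trajectory for one interface.
#'
#' @param trajectory a `trajectory_ensemble`.
#' @param interface list with `label`, `class` ("intra-dimer",
#'   "inter-dimer" or "lateral"), `lower_sel`, `upper_sel`, `lower_site`,
#'   `upper_site` (see [monomer_triads()]).
#' @param lattice a `reference_lattice`.
#' @param stride keep every `stride`-th frame (default 1, i.e. every frame;
#'   with 1-ns frame times this is the every-nanosecond sampling).
#' @return data.frame of class `interface_angle_series` with columns
#'   `time_ns`, `interface`, `class`, `phi_deg`, `theta_deg`, `delta_deg`,
#'   `degenerate`.
#' @export
angle_series <- function(trajectory, interface, lattice, stride = 1L) {
  idx <- if (n_frames(trajectory) == 0) integer(0)
         else seq(1, n_frames(trajectory), by = stride)
  nk <- length(idx)
  phi <- theta <- delta <- numeric(nk)
  degen <- logical(nk)

  # hoist everything frame-independent out of the loop: wall-site cores
  # centered once, column indices of the two monomer cores precomputed
  prep <- function(sel, site_name) {
    site <- lattice$sites[[site_name]]
    if (is.null(site)) stop("unknown lattice site: ", site_name)
    if (length(site$core_idx) != length(sel$core_idx))
      stop("cannot pair wall site ", site_name, " with monomer core: ",
           length(site$core_idx), " vs ", length(sel$core_idx), " atoms")
    wall <- lattice$wall$xyz[site$core_idx, , drop = FALSE]
    wall_c <- sweep(wall, 2, colMeans(wall))
    cols <- as.vector(rbind(3 * sel$core_idx - 2, 3 * sel$core_idx - 1,
                            3 * sel$core_idx))
    list(wall_c = wall_c, cols = cols, triad = site$triad,
         n = length(sel$core_idx))
  }
  lo <- prep(interface$lower_sel, interface$lower_site)
  up <- prep(interface$upper_sel, interface$upper_site)
  fit_rot <- function(wall_c, mono) {
    mono_c <- sweep(mono, 2, colMeans(mono))
    sv <- svd(crossprod(wall_c, mono_c))
    d <- sign(det(sv$v %*% t(sv$u)))
    sv$v %*% (t(sv$u) * c(1, 1, d))
  }
  frames <- trajectory$frames
  for (k in seq_len(nk)) {
    f <- idx[k]
    TL <- fit_rot(lo$wall_c, matrix(frames[f, lo$cols], lo$n, 3, byrow = TRUE)) %*% lo$triad
    TU <- fit_rot(up$wall_c, matrix(frames[f, up$cols], up$n, 3, byrow = TRUE)) %*% up$triad
    ang <- .decompose_relative(crossprod(TL, TU))
    phi[k] <- ang[1]; theta[k] <- ang[2]; delta[k] <- ang[3]
    degen[k] <- ang[4] > 0.5
  }
  out <- data.frame(time_ns = trajectory$times[idx],
                    interface = rep(interface$label, nk),
                    class = rep(interface$class %||% "intra-dimer", nk),
                    phi_deg = phi, theta_deg = theta, delta_deg = delta,
                    degenerate = degen)
  class(out) <- c("interface_angle_series", "data.frame")
  out
}

#' Projection of the upper-monomer z-axis onto the lower xy-plane
#'
#' Returns per-frame tangential and radial components of the upper unit
#' z-vector in the lower monomer's frame, on the plotting convention where
#' the radial component is positive toward the microtubule axis (the
#' internal radial x-axis points outward, so its sign is flipped here).
#'
#' @param series an `interface_angle_series` (or any data.frame with
#'   `phi_deg` and `theta_deg` columns).
#' @return data.frame with columns `tangential` (Z . y) and `radial`
#'   (-(Z . x)).
#' @export
unit_vector_projection <- function(series) {
  st <- sin(deg2rad(series$theta_deg))
  data.frame(tangential = st * sin(deg2rad(series$phi_deg)),
             radial = -st * cos(deg2rad(series$phi_deg)))
}

#' Center-of-mass projection of a subunit in a base subunit's frame
#'
#' Mass-weighted center of mass of `subunit`, expressed per frame in the
#' lattice triad carried onto `base_subunit`, projected on the base
#' xy-plane. Optionally smoothed with a centered moving average.
#'
#' @param trajectory a `trajectory_ensemble`.
#' @param subunit,base_subunit `monomer_selection` objects.
#' @param lattice a `reference_lattice`.
#' @param base_site lattice site name for the base subunit.
#' @param window odd moving-average window in frames (1 = no smoothing).
#' @return data.frame with `time_ns`, `x`, `y` (Angstrom, base frame).
#' @export
com_projection <- function(trajectory, subunit, base_subunit, lattice,
                           base_site, window = 1L) {
  masses <- atom_masses(trajectory$topology)[subunit$atom_idx]
  site <- lattice$sites[[base_site]]
  nf <- n_frames(trajectory)
  xy <- matrix(0, nf, 2)
  for (i in seq_len(nf)) {
    fx <- frame_coords(trajectory, i)
    tr <- superpose_core(lattice$wall$xyz[site$core_idx, , drop = FALSE],
                         fx[base_subunit$core_idx, , drop = FALSE])
    triad <- tr$R %*% site$triad
    origin <- as.vector(tr$R %*% site$center + tr$t)
    com <- colSums(fx[subunit$atom_idx, , drop = FALSE] * masses) / sum(masses)
    local <- as.vector(crossprod(triad, com - origin))
    xy[i, ] <- local[1:2]
  }
  if (window > 1L) {
    xy[, 1] <- moving_average(xy[, 1], window)
    xy[, 2] <- moving_average(xy[, 2], window)
  }
  data.frame(time_ns = trajectory$times, x = xy[, 1], y = xy[, 2])
}

# centered moving average with shrinking window at the edges
moving_average <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Interface angles of a deposited structure against a wall lattice
#'
#' Convenience wrapper computing (phi, theta, delta) for one monomer pair
#' of a crystal or cryo-EM structure, using a straight microtubule wall
#' fragment as the orientation reference. Monomer core atoms are the
#' Calpha set shared (by residue number) with the wall site chain, minus
#' any configured exclusions.
#'
#' @param structure `structure_model` of the deposited structure.
#' @param lattice `reference_lattice` built from a straight wall fragment.
#' @param lower_chain,upper_chain chains of the examined monomer pair in
#'   `structure` (lower = minus-end proximal).
#' @param lower_site,upper_site wall site names to pair them with.
#' @param exclude_resno residues excluded from the superposition cores.
#' @return result of [interface_angles()] plus attributes `rmsd_lower`,
#'   `rmsd_upper`.
#' @export
published_structure_angles <- function(structure, lattice,
                                       lower_chain, upper_chain,
                                       lower_site, upper_site,
                                       exclude_resno = integer(0)) {
  pair_core <- function(mono_chain, site_name) {
    wall_at <- lattice$wall$atoms
    site_rows <- which(wall_at$chain == site_name & toupper(wall_at$elety) == "CA")
    mono_at <- structure$atoms
    mono_rows <- which(mono_at$chain == mono_chain & toupper(mono_at$elety) == "CA")
    shared <- setdiff(intersect(wall_at$resno[site_rows], mono_at$resno[mono_rows]),
                      exclude_resno)
    if (length(shared) < 3) stop("fewer than 3 shared Calpha residues between chain ",
                                 mono_chain, " and wall site ", site_name)
    list(wall_idx = site_rows[match(shared, wall_at$resno[site_rows])],
         mono_idx = mono_rows[match(shared, mono_at$resno[mono_rows])])
  }
  lo <- pair_core(lower_chain, lower_site)
  up <- pair_core(upper_chain, upper_site)
  lower_sel <- structure(list(label = lower_chain, core_idx = lo$mono_idx),
                         class = "monomer_selection")
  upper_sel <- structure(list(label = upper_chain, core_idx = up$mono_idx),
                         class = "monomer_selection")
  tri <- monomer_triads(structure$xyz, lower_sel, upper_sel, lattice,
                        lower_site, upper_site,
                        lower_pair_idx = lo$wall_idx, upper_pair_idx = up$wall_idx)
  ang <- interface_angles(tri$lower, tri$upper)
  attr(ang, "rmsd_lower") <- tri$rmsd_lower
  attr(ang, "rmsd_upper") <- tri$rmsd_upper
  ang
}
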