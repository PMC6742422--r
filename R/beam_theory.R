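# Beam-theory mapping of normal-mode frequencies to filament stiffness:
# K_bend = rho_l omega^2 / k^4 (Euler-Bernoulli flexural rigidity) and
# K_twist = rho_v I omega^2 / k^2 (torsional rigidity), with wavenumbers
# set by the vibrating-beam boundary conditions.

# free-free Euler-Bernoulli bending roots of cos(bL) cosh(bL) = 1
.free_free_bend_roots <- c(4.730040744862704, 7.853204624095838,
                           10.995607838001671, 14.137165491257464,
                           17.278759657399480)

#' Beam geometry and material parameters of a filament
#'
#' @param length_m filament length, m.
#' @param rho_l mass per unit length, kg/m (default 1.95e-14, the tubulin
#'   protofilament value).
#' @param rho_v mass per unit volume, kg/m^3 (default 1.3e3).
#' @param I second moment of the cross-sectional area about the filament
#'   axis, m^4 (default 3.42e-35).
#' @param bc boundary-condition tag; only "free-free" wavenumbers are
#'   tabulated (freely vibrating filament).
#' @return list of class `beam_geometry`.
#' @export
beam_geometry <- function(length_m, rho_l = 1.95e-14, rho_v = 1.3e3,
                          I = 3.42e-35, bc = "free-free") {
  stopifnot(length_m > 0, rho_l > 0, rho_v > 0, I > 0)
  bc <- match.arg(bc, "free-free")
  structure(list(L = length_m, rho_l = rho_l, rho_v = rho_v, I = I, bc = bc),
            class = "beam_geometry")
}

#' Wavenumber of a beam vibration mode
#' @param geometry a `beam_geometry`.
#' @param kind "bend" (flexural, roots of the free-free frequency
#'   equation) or "twist" (torsional, k = n pi / L).
#' @param order mode order (1 = fundamental).
#' @return wavenumber in 1/m.
#' @export
beam_wavenumber <- function(geometry, kind = c("bend", "twist"), order = 1L) {
  kind <- match.arg(kind)
  stopifnot(order >= 1)
  if (kind == "bend") {
    if (order > length(.free_free_bend_roots))
      stop("bending wavenumbers tabulated up to order ",
           length(.free_free_bend_roots))
    .free_free_bend_roots[order] / geometry$L
  } else {
    order * pi / geometry$L
  }
}

#' Beam-theory stiffness from a normal-mode frequency
#'
#' Converts the angular frequency of a bending or twisting normal mode
#' into the flexural rigidity K_bend = rho_l omega^2 / k^4 (N m^2) or the
#' torsional rigidity K_twist = rho_v I omega^2 / k^2 (N m^2) of the
#' equivalent continuous filament.
#'
#' @param omega angular frequency of the mode, rad/s (>= 0).
#' @param mode_label "bend" or "twist"; a mode classified "other" is
#'   refused since neither formula applies.
#' @param geometry a `beam_geometry`.
#' @param order beam mode order matching the normal mode (default 1).
#' @return stiffness in N m^2.
#' @export
beam_stiffness <- function(omega, mode_label, geometry, order = 1L) {
  if (mode_label == "other")
    stop("mode classified 'other': neither the bending nor the torsion ",
         "beam formula applies to a mixed mode")
  mode_label <- match.arg(mode_label, c("bend", "twist"))
  stopifnot(omega >= 0)
  k <- beam_wavenumber(geometry, mode_label, order)
  if (mode_label == "bend") geometry$rho_l * omega^2 / k^4
  else geometry$rho_v * geometry$I * omega^2 / k^2
}

#' Frequency of a beam mode from its stiffness (inverse of
#' [beam_stiffness()])
#' @inheritParams beam_stiffness
#' @param K stiffness, N m^2.
#' @return angular frequency, rad/s.
#' @export
beam_frequency <- function(K, mode_label, geometry, order = 1L) {
  mode_label <- match.arg(mode_label, c("bend", "twist"))
  k <- beam_wavenumber(geometry, mode_label, order)
  if (mode_label == "bend") sqrt(K * k^4 / geometry$rho_l)
  else sqrt(K * k^2 / (geometry$rho_v * geometry$I))
}

# free-free Euler-Bernoulli mode shape on s in [0, 1]
free_free_bend_shape <- function(s, order = 1L) {
  b <- .free_free_bend_roots[order]
  sig <- (cosh(b) - cos(b)) / (sinh(b) - sin(b))
  cosh(b * s) + cos(b * s) - sig * (sinh(b * s) + sin(b * s))
}

#' Classify normal modes as bend, twist or other
#'
#' Projects each mode's displacement field onto ideal beam fields about
#' the filament axis: transverse free-free bending shapes (two orders, two
#' transverse directions) and torsional fields (tangential displacement
#' about the axis with free-free axial profiles cos(n pi s)). The mode is
#' labelled by the dominant squared-projection fraction when it exceeds
#' the threshold, else "other".
#'
#' @param modes a `mode_set` over 3n bead coordinates.
#' @param positions n x 3 bead positions (Angstrom).
#' @param axis filament axis (default the principal axis of the bead
#'   cloud).
#' @param threshold dominant-fraction threshold (default 0.6).
#' @param weights optional per-bead weights used in the projection metric
#'   (default uniform; pass masses for mass-weighted mode vectors).
#' @return data.frame: mode, label, bend_fraction, twist_fraction.
#' @export
classify_modes <- function(modes, positions, axis = NULL, threshold = 0.6,
                           weights = NULL) {
  P <- as.matrix(positions)
  n <- nrow(P)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  if (is.null(axis)) {
    axis <- eigen(crossprod(Pc) / n, symmetric = TRUE)$vectors[, 1]
  }
  z <- unit(axis)
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * z) * z)
  e2 <- cross3(z, e1)
  s_ax <- Pc %*% z
  s <- as.vector((s_ax - min(s_ax)) / max(diff(range(s_ax)), .Machine$double.eps))
  r_perp <- Pc - s_ax %*% t(z)

  fields <- list()
  for (ord in 1:2) {
    psi <- free_free_bend_shape(s, ord)
    fields[[length(fields) + 1]] <- list(kind = "bend", f = outer(psi, e1))
    fields[[length(fields) + 1]] <- list(kind = "bend", f = outer(psi, e2))
  }
  tang <- t(apply(r_perp, 1, function(r) cross3(z, r)))
  for (ord in 1:2) {
    prof <- cos(ord * pi * s)
    fields[[length(fields) + 1]] <- list(kind = "twist", f = tang * prof)
  }
  w <- if (is.null(weights)) rep(1, n) else weights
  flat <- vapply(fields, function(fl) as.vector(t(fl$f * sqrt(w))), numeric(3 * n))
  kinds <- vapply(fields, `[[`, character(1), "kind")
  ortho_basis <- function(mat) {
    q <- qr(mat)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  }
  Qb <- ortho_basis(flat[, kinds == "bend", drop = FALSE])
  Qt <- ortho_basis(flat[, kinds == "twist", drop = FALSE])

  nm <- ncol(modes$vectors)
  out <- data.frame(mode = seq_len(nm), label = character(nm),
                    bend_fraction = numeric(nm), twist_fraction = numeric(nm),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nm)) {
    v <- modes$vectors[, k] * rep(sqrt(w), each = 3) /
      sqrt(sum(modes$vectors[, k]^2 * rep(w, each = 3)))
    fb <- sum(as.vector(crossprod(Qb, v))^2)
    ft <- sum(as.vector(crossprod(Qt, v))^2)
    out$bend_fraction[k] <- fb
    out$twist_fraction[k] <- ft
    out$label[k] <- if (fb >= threshold && fb > ft) "bend"
                    else if (ft >= threshold && ft > fb) "twist"
                    else "other"
  }
  out
}
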