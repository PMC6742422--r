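#' Define tubulin subunits within a structure
#'
#' Turns a declarative subunit specification into monomer selections with
#' resolved atom indices. The default superposition core is every Calpha of
#' the subunit minus configured flexible-loop and C-terminal-tail
#' exclusions.
#'
#' @param structure a `structure_model`.
#' @param subunit_spec list of per-subunit entries; each entry is a list
#'   with `label`, `chain`, `role` ("alpha" or "beta"), and optionally
#'   `resno` (residue numbers; default all in the chain), `exclude_resno`
#'   (residues dropped from the core), `exclude_cterm` (number of
#'   C-terminal residues dropped from the core, default 10), `nucleotide`
#'   (resid of the bound nucleotide, e.g. "GTP"), `pf_index`.
#' @param axis optional length-3 axis used to order subunits
#'   longitudinally; default global z. Longitudinal index 0 is the
#'   minus-end-proximal (lowest projection) subunit.
#' @return list of `monomer_selection` objects.
#' @export
define_subunits <- function(structure, subunit_spec, axis = c(0, 0, 1)) {
  at <- structure$atoms
  sels <- lapply(subunit_spec, function(sp) {
    stopifnot(!is.null(sp$label), !is.null(sp$chain), !is.null(sp$role))
    role <- match.arg(sp$role, c("alpha", "beta"))
    in_chain <- at$chain == sp$chain
    if (!any(in_chain)) stop("selection error: chain '", sp$chain,
                             "' absent from structure")
    resno <- if (is.null(sp$resno)) sort(unique(at$resno[in_chain])) else sp$resno
    if (!all(resno %in% at$resno[in_chain]))
      stop("selection error: residues ",
           paste(setdiff(resno, at$resno[in_chain]), collapse = ","),
           " absent from chain ", sp$chain)
    atom_idx <- which(in_chain & at$resno %in% resno)
    excl <- sp$exclude_resno %||% integer(0)
    ncterm <- sp$exclude_cterm %||% 10L
    core_resno <- setdiff(resno, excl)
    if (ncterm > 0 && length(core_resno) > ncterm)
      core_resno <- core_resno[seq_len(length(core_resno) - ncterm)]
    core_idx <- which(in_chain & at$resno %in% core_resno &
                        toupper(at$elety) == "CA")
    if (length(core_idx) == 0) core_idx <- atom_idx  # pseudo-subunits lack CA
    nuc_idx <- integer(0)
    if (!is.null(sp$nucleotide)) {
      nuc_idx <- which(in_chain & at$resid == sp$nucleotide)
      if (length(unique(at$resno[nuc_idx])) != 1)
        stop("nucleotide '", sp$nucleotide, "' does not resolve to exactly one residue in chain ",
             sp$chain)
    }
    structure(list(label = sp$label, role = role, chain = sp$chain,
                   resno = resno, atom_idx = atom_idx, core_idx = core_idx,
                   nucleotide = sp$nucleotide %||% NULL, nuc_idx = nuc_idx,
                   pf_index = sp$pf_index %||% 0L, long_index = NA_integer_),
              class = "monomer_selection")
  })
  # longitudinal order by projection of the subunit centroid on the axis
  z <- unit(axis)
  proj <- vapply(sels, function(s) {
    sum(colMeans(structure$xyz[s$atom_idx, , drop = FALSE]) * z)
  }, numeric(1))
  ord <- order(proj)
  for (k in seq_along(ord)) sels[[ord[k]]]$long_index <- k - 1L
  sels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_triad <- function(x, y, z) {
  m <- cbind(unit(x), unit(y), unit(z))
  colnames(m) <- c("x", "y", "z")
  m
}

check_triad <- function(m, tol = 1e-10) {
  max(abs(crossprod(m) - diag(3))) < tol && det(m) > 0
}

#' Least-squares cylinder axis through a point set
#'
#' Fits the axis (direction + point) minimizing the variance of the radial
#' distances of the points from the axis. Initialized from the principal
#' axes of the point cloud (all three tried, best fit kept), refined with
#' quasi-Newton iterations, so the fit is equivariant under rigid motion of
#' the input.
#'
#' @param points n x 3 matrix (n >= 3, not collinear).
#' @return list with `axis` (unit vector, oriented toward positive z of the
#'   initial guess), `origin` (point on the axis), `radius` (mean radial
#'   distance), `rss` (residual sum of squares of radial deviations).
#' @export
fit_cylinder_axis <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("under-determined: need >= 3 points for an axis fit")
  ctr <- colMeans(points)
  P0 <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(P0) / nrow(P0), symmetric = TRUE)$vectors

  obj_in_frame <- function(par, Q) {
    # axis direction (a,b,1)/norm in rotated frame, passing through (cx,cy,0)
    d <- unit(c(par[1], par[2], 1))
    rel <- sweep(Q, 2, c(par[3], par[4], 0))
    proj <- rel %*% d
    rad2 <- rowSums(rel^2) - as.vector(proj)^2
    r <- sqrt(pmax(rad2, 0))
    sum((r - mean(r))^2)
  }

  best <- NULL
  for (k in 1:3) {
    zc <- ev[, k]
    # rotation sending candidate axis to +z
    ref <- if (abs(zc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    xc <- unit(ref - sum(ref * zc) * zc)
    yc <- cross3(zc, xc)
    Rk <- rbind(xc, yc, zc)             # world -> candidate frame
    Q <- P0 %*% t(Rk)
    op <- stats::optim(c(0, 0, 0, 0), obj_in_frame, Q = Q,
                       method = "BFGS",
                       control = list(reltol = 1e-16, maxit = 500,
                                      ndeps = rep(1e-7, 4)))
    # polish: a second pass tightens the numeric-gradient optimum
    op <- stats::optim(op$par, obj_in_frame, Q = Q, method = "BFGS",
                       control = list(reltol = 1e-16, maxit = 200,
                                      ndeps = rep(1e-8, 4)))
    if (is.null(best) || op$value < best$op$value) best <- list(op = op, Rk = Rk)
  }
  par <- best$op$par
  d_local <- unit(c(par[1], par[2], 1))
  axis <- as.vector(t(best$Rk) %*% d_local)
  origin <- ctr + as.vector(t(best$Rk) %*% c(par[3], par[4], 0))
  rel <- sweep(points, 2, origin)
  proj <- rel %*% axis
  r <- sqrt(pmax(rowSums(rel^2) - as.vector(proj)^2, 0))
  list(axis = axis, origin = origin, radius = mean(r), rss = best$op$value)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the microtubule-bound reference lattice
#'
#' Associates an orthonormal coordinate triad with every subunit site of a
#' microtubule wall fragment: z axial (parallel to the microtubule axis), x
#' radial (pointing outward from the axis toward the site), y = z cross x
#' (tangential). Sites are the chains of the wall structure.
#'
#' @param wall_structure `structure_model` of the wall fragment; each chain
#'   is one subunit site.
#' @param axis_spec either the string "fit" (least-squares cylinder axis
#'   through the chain centroids) or a list with `axis` (length-3 vector)
#'   and `origin` (length-3 point).
#' @param outward logical; if TRUE (default) the site x-axis points from
#'   the microtubule axis toward the subunit.
#' @return object of class `reference_lattice`: the wall structure, `axis`,
#'   `origin`, and per-site list `sites` with `chain`, `center`, `triad`
#'   (3x3, columns x,y,z), `core_idx` (atom rows of the site's chain).
#' @export
build_reference_lattice <- function(wall_structure, axis_spec = "fit",
                                    outward = TRUE) {
  chains <- unique(wall_structure$atoms$chain)
  centers <- t(vapply(chains, function(ch) {
    colMeans(wall_structure$xyz[wall_structure$atoms$chain == ch, , drop = FALSE])
  }, numeric(3)))
  if (identical(axis_spec, "fit")) {
    if (length(chains) < 3)
      stop("under-determined: axis fit needs >= 3 subunit sites")
    fit <- fit_cylinder_axis(centers)
    axis <- fit$axis; origin <- fit$origin
  } else {
    axis <- unit(axis_spec$axis)
    origin <- as.numeric(axis_spec$origin)
  }
  sites <- lapply(seq_along(chains), function(i) {
    ctr <- centers[i, ]
    radial <- ctr - origin
    radial <- radial - sum(radial * axis) * axis
    if (vnorm(radial) < 1e-9)
      stop("site ", chains[i], " lies on the axis; radial direction undefined")
    x <- unit(radial) * if (outward) 1 else -1
    y <- cross3(axis, x)
    list(chain = chains[i], center = ctr, triad = make_triad(x, y, axis),
         core_idx = which(wall_structure$atoms$chain == chains[i]))
  })
  names(sites) <- chains
  structure(list(wall = wall_structure, axis = axis, origin = origin,
                 sites = sites, outward = outward),
            class = "reference_lattice")
}

#' @export
print.reference_lattice <- function(x, ...) {
  cat(sprintf("reference_lattice: %d sites, axis = (%.3f, %.3f, %.3f)\n",
              length(x$sites), x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
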