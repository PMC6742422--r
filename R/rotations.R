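#' @keywords internal
"_PACKAGE"

# Boltzmann constant, J/K
.kB <- 1.380649e-23

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis numeric length-3 axis (need not be unit length; a near-zero
#'   axis with a near-zero angle yields the identity).
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  n <- vnorm(axis)
  if (n < 1e-12) {
    if (abs(angle) < 1e-12) return(diag(3))
    stop("rotation axis is numerically zero but angle is not")
  }
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum |R x_i + t - y_i|^2` over paired points, i.e. the transform carrying
#' the mobile set onto the reference set. The reflection branch of the SVD
#' solution is rejected so `det(R) = +1` always.
#'
#' @param mobile n x 3 matrix of coordinates to be moved.
#' @param reference n x 3 matrix of target coordinates, row-paired with
#'   `mobile`.
#' @param weights optional non-negative per-point weights (e.g. masses).
#' @return list with `R` (3x3 rotation), `t` (length-3 translation),
#'   `rmsd` (RMSD after superposition, in the input units).
#' @export
superpose_core <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)

  H <- crossprod(A * w, B)  # 3x3 cross-covariance
  sv <- svd(H)
  # collinear point sets leave the rotation under-determined
  if (sv$d[2] < 1e-10 * max(sv$d[1], .Machine$double.eps))
    stop("degenerate (collinear) point set: superposition under-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)

  moved <- A %*% t(R)
  rmsd <- sqrt(sum((moved - B)^2) / n)
  list(R = R, t = t_vec, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 coordinate matrix.
#' @param tr transform list with elements `R` and `t` (as returned by
#'   [superpose_core()]).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$t, "+")
}

# quaternion helpers used by the swing-twist test oracle live in the test
# suite so they stay independent of this implementation
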