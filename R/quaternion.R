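## Quaternion algebra for rigid-body poses.
##
## Convention used throughout the package: scalar-first unit quaternions
## q = (w, x, y, z), right-handed rotations, and poses act as
## rotate-then-translate:  x' = R(q) x + t.

#' Construct a quaternion
#'
#' @param w,x,y,z numeric components, scalar (\code{w}) first.
#' @param normalize if \code{TRUE}, rescale to unit norm.
#' @return numeric length-4 vector \code{c(w, x, y, z)}.
#' @export
quaternion <- function(w, x, y, z, normalize = FALSE) {
  q <- c(w, x, y, z)
  if (any(!is.finite(q))) stop("quaternion components must be finite")
  if (normalize) q <- q / sqrt(sum(q^2))
  q
}

#' Axis-angle quaternion
#'
#' @param axis numeric length-3 rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Quaternion norm check
#' @param q quaternion.
#' @param tol tolerance on |q| - 1.
#' @keywords internal
quat_is_unit <- function(q, tol = 1e-9) {
  abs(sqrt(sum(q^2)) - 1) <= tol
}

#' Hamilton product of two quaternions
#'
#' \code{quat_multiply(q1, q2)} is the rotation q2 followed by q1.
#' @param q1,q2 quaternions (scalar first).
#' @return quaternion product.
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; v1 <- q1[2:4]
  w2 <- q2[1]; v2 <- q2[2:4]
  c(w1 * w2 - sum(v1 * v2),
    w1 * v2 + w2 * v1 + c(
      v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1]))
}

#' Quaternion conjugate
#' @param q quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Rotation matrix from a unit quaternion
#'
#' @param q unit quaternion, scalar first.
#' @return 3x3 rotation matrix \code{R} such that rotated coordinates are
#'   \code{x \%*\% t(R)} for row-vector coordinates.
#' @export
quat_to_matrix <- function(q) {
  if (!quat_is_unit(q, 1e-6)) stop("quaternion is not unit-norm")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Spherical linear interpolation between unit quaternions
#'
#' @param q1,q2 unit quaternions.
#' @param f interpolation fraction in [0, 1].
#' @return unit quaternion at fraction \code{f} along the shortest great-arc
#'   path from \code{q1} to \code{q2}.
#' @export
quat_slerp <- function(q1, q2, f) {
  d <- sum(q1 * q2)
  if (d < 0) {  # take the short way around the double cover
    q2 <- -q2
    d <- -d
  }
  if (d > 1 - 1e-10) {  # nearly parallel: linear interpolation is stable
    q <- q1 + f * (q2 - q1)
    return(q / sqrt(sum(q^2)))
  }
  theta <- acos(pmin(1, d))
  (sin((1 - f) * theta) * q1 + sin(f * theta) * q2) / sin(theta)
}

#' Angle of the relative rotation between two unit quaternions
#' @param q1,q2 unit quaternions.
#' @return angle in radians in [0, pi].
#' @export
quat_angle <- function(q1, q2) {
  d <- abs(sum(q1 * q2))
  2 * acos(pmin(1, d))
}

#' Uniform random unit quaternion
#'
#' Shoemake's method; uses the current RNG stream.
#' @return unit quaternion.
#' @keywords internal
quat_random <- function() {
  u <- stats::runif(3)
  x <- sqrt(1 - u[1]) * sin(2 * pi * u[2])
  y <- sqrt(1 - u[1]) * cos(2 * pi * u[2])
  z <- sqrt(u[1]) * sin(2 * pi * u[3])
  w <- sqrt(u[1]) * cos(2 * pi * u[3])
  q <- c(w, x, y, z)
  q / sqrt(sum(q^2))
}

#' Quaternion aligning one direction onto another
#'
#' Returns the minimal rotation taking unit(\code{a}) to unit(\code{b}).
#' @param a,b numeric length-3 vectors.
#' @return unit quaternion.
#' @keywords internal
quat_align <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # opposite: rotate pi about any axis orthogonal to a
    ax <- c(1, 0, 0)
    if (abs(a[1]) > 0.9) ax <- c(0, 1, 0)
    axis <- c(a[2] * ax[3] - a[3] * ax[2],
              a[3] * ax[1] - a[1] * ax[3],
              a[1] * ax[2] - a[2] * ax[1])
    return(quat_from_axis_angle(axis, pi))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  quat_from_axis_angle(axis, acos(pmin(1, pmax(-1, d))))
}
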