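#' @useDynLib osteoplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

norm3 <- function(v) sqrt(sum(v^2))
unit3 <- function(v) v / norm3(v)

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues rotation by `angle_deg` degrees about `axis` (right-handed).
#'
#' @param axis length-3 numeric, need not be normalized
#' @param angle_deg rotation angle in degrees
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit3(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform applied to points
#'
#' @param pts n x 3 matrix (or length-3 vector) of points in mm
#' @param R 3x3 rotation matrix
#' @param center rotation center (mm)
#' @param translation translation applied after rotation (mm)
#' @return transformed points, same shape as input
#' @export
apply_rigid <- function(pts, R = diag(3), center = c(0, 0, 0),
                        translation = c(0, 0, 0)) {
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, 1, 3) else as.matrix(pts)
  out <- sweep(p, 2, center) %*% t(R)
  out <- sweep(out, 2, center + translation, `+`)
  if (single) drop(out) else out
}

# signed angle (deg) from vector a to b in 2D, positive counter-clockwise
angle2d_signed <- function(a, b) {
  rad2deg(atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)))
}

# unsigned angle (deg) between 3D/2D vectors
angle_between <- function(a, b) {
  ca <- sum(a * b) / (norm3(a) * norm3(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}
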