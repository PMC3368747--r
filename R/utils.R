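# Small geometric helpers shared across modules. World coordinates are the
# DICOM patient system (LPS), millimetres, throughout the package.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 10) {
    stop("cannot normalise a (near-)zero vector")
  }
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' rotation formula: the 3x3 matrix rotating vectors by
#' `angle_deg` degrees (right-hand rule) about `axis`.
#'
#' @param axis Numeric length-3 axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(R %*% t(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

# clamp into [-1, 1] before acos to absorb rounding
clamp1 <- function(x) pmin(1, pmax(-1, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
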