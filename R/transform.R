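#' Rigid-body transforms
#'
#' A rigid transform is stored as a 4x4 homogeneous matrix with rotation
#' block `R` (orthonormal, det +1) and translation `t` in mm; it maps
#' follow-up coordinates into the baseline frame via `p' = R p + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return An object of class `rigid_transform` (a 4x4 matrix).
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 0, 0))
#' transform_points(tr, matrix(0, 1, 3))
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("rotation block is not orthonormal")
  }
  if (det(R) < 0) stop("rotation block has negative determinant (reflection)")
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  structure(M, class = c("rigid_transform", "matrix"))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation", format(rotation_angle_deg(x), digits = 4),
      "deg, translation", format(sqrt(sum(x[1:3, 4]^2)), digits = 4), "mm\n")
  print(unclass(x))
  invisible(x)
}

#' @rdname rigid_transform
#' @param axis rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) {
    if (angle_deg != 0) stop("zero axis with nonzero angle")
    return(diag(3))
  }
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rigid_transform
#' @param tr,a,b rigid transforms.
#' @export
transform_compose <- function(a, b) {
  # applies b first, then a
  M <- unclass(a) %*% unclass(b)
  rigid_transform(orthonormalize_rotation(M[1:3, 1:3]), M[1:3, 4])
}

#' @rdname rigid_transform
#' @export
transform_invert <- function(tr) {
  R <- tr[1:3, 1:3]
  rigid_transform(t(R), -t(R) %*% tr[1:3, 4])
}

#' @rdname rigid_transform
#' @param points n x 3 matrix (mm).
#' @export
transform_points <- function(tr, points) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(tr[1:3, 1:3]), 2, tr[1:3, 4], `+`)
}

#' @rdname rigid_transform
#' @param scan a [surface_scan()].
#' @export
transform_scan <- function(tr, scan) {
  scan$vertices <- transform_points(tr, scan$vertices)
  scan
}

#' @rdname rigid_transform
#' @export
rotation_angle_deg <- function(tr) {
  R <- unclass(tr)[1:3, 1:3]
  c_ <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_))) * 180 / pi
}

#' @rdname rigid_transform
#' @export
translation_mm <- function(tr) {
  unclass(tr)[1:3, 4]
}

# Project a near-rotation onto SO(3) (polar decomposition via SVD).
orthonormalize_rotation <- function(R) {
  s <- svd(R)
  D <- diag(3)
  D[3, 3] <- sign(det(s$u %*% t(s$v)))
  s$u %*% D %*% t(s$v)
}
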