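## Low-level 3D geometry: rotations, internal-coordinate atom placement,
## torsions, principal axes, least-squares superposition.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `theta` degrees
#' about the (not necessarily unit) axis vector.
#'
#' @param axis numeric length-3 axis vector.
#' @param theta rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  n <- sqrt(sum(axis^2))
  if (!is.finite(n) || n < 1e-12) stop("rotation axis has zero length")
  u <- axis / n
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3, 3)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

rot_z <- function(theta) rotation_about_axis(c(0, 0, 1), theta)
rot_y <- function(theta) rotation_about_axis(c(0, 1, 0), theta)
rot_x <- function(theta) rotation_about_axis(c(1, 0, 0), theta)

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' IUPAC-signed torsion a-b-c-d in degrees, in (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinates.
#' @return angle in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  b0 <- a - b; b1 <- unitv(c - b); b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cross3(b1, v) * w), sum(v * w)) * 180 / pi
}

#' Bond angle of three points (degrees)
#' @param a,b,c numeric length-3 coordinates; vertex at `b`.
#' @export
bond_angle <- function(a, b, c) {
  v1 <- unitv(a - b); v2 <- unitv(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom D bonded to `c` with bond length `bond`, angle b-c-D `angle`
#' (degrees) and torsion a-b-c-D `torsion` (degrees).
#'
#' @param a,b,c numeric length-3 reference coordinates.
#' @param bond,angle,torsion internal coordinates (Angstrom / degrees).
#' @return numeric length-3 coordinate of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}

#' First principal axis of a point cloud
#'
#' Unit vector along the dominant principal component; sign is oriented so
#' that the vector points from the first toward the last point.
#'
#' @param x n-by-3 coordinate matrix, n >= 2.
#' @return unit length-3 vector.
#' @export
principal_axis <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 3, nrow(x) >= 2)
  xc <- sweep(x, 2, colMeans(x))
  v <- svd(xc, nu = 0, nv = 1)$v[, 1]
  span <- x[nrow(x), ] - x[1, ]
  if (sum(v * span) < 0) v <- -v
  as.numeric(v)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `ref`
#' (row-matched n-by-3 matrices). Reflections are excluded.
#'
#' @param mobile,ref n-by-3 matrices with matched rows.
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd`, and
#'   `transform(x)` applying the fit to any m-by-3 matrix.
#' @export
kabsch <- function(mobile, ref) {
  stopifnot(is.matrix(mobile), is.matrix(ref),
            ncol(mobile) == 3, all(dim(mobile) == dim(ref)))
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- t(R %*% t(P)) + matrix(cr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  tvec <- cr - as.numeric(R %*% cm)
  list(R = R, t = tvec, rmsd = rmsd,
       transform = function(x) sweep(t(R %*% t(x)), 2, tvec, `+`))
}

#' Root-mean-square deviation of matched coordinate sets
#' @param a,b n-by-3 matrices with matched rows.
#' @export
rmsd_coords <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

## ZYZ Euler decomposition R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma),
## angles in degrees, beta in [0, 180]. Degenerate beta ~ 0/180: alpha = 0.
euler_zyz <- function(R) {
  R <- unname(R)
  beta <- acos(max(-1, min(1, R[3, 3]))) * 180 / pi
  if (abs(R[3, 3]) > 1 - 1e-12) {
    alpha <- 0
    gamma <- if (R[3, 3] > 0) atan2(R[2, 1], R[1, 1]) * 180 / pi
             else atan2(R[2, 1], -R[1, 1]) * 180 / pi
  } else {
    alpha <- atan2(R[2, 3], R[1, 3]) * 180 / pi
    gamma <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  }
  c(alpha = as.numeric(alpha), beta = as.numeric(beta),
    gamma = as.numeric(gamma))
}

rot_zyz <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_y(beta) %*% rot_z(gamma)
}
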