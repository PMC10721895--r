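# Internal 3D geometry helpers shared across modules. Coordinates are in
# Angstrom throughout; conversions to nm happen only at reporting surfaces.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
rotation_about_axis <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
}

# Kabsch superposition: returns list(R, t, rmsd) mapping xyz_b onto xyz_a,
# i.e. xyz_b %*% t(R) + t approximates xyz_a. Rotation is proper (det +1).
#' @noRd
kabsch <- function(xyz_a, xyz_b) {
  stopifnot(nrow(xyz_a) == nrow(xyz_b), ncol(xyz_a) == 3, ncol(xyz_b) == 3)
  ca <- colMeans(xyz_a); cb <- colMeans(xyz_b)
  a0 <- sweep(xyz_a, 2, ca); b0 <- sweep(xyz_b, 2, cb)
  h <- crossprod(b0, a0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  dd <- diag(c(1, 1, d))
  rot <- sv$v %*% dd %*% t(sv$u)
  fitted <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - a0)^2)))
  list(R = rot, t = ca - as.numeric(cb %*% t(rot)), rmsd = rmsd)
}

# Rotation angle (degrees) of a proper rotation matrix.
#' @noRd
rotation_angle_deg <- function(R) {
  tr <- sum(diag(R))
  rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
}

# Least-squares line through points: principal axis + centroid.
#' @noRd
fit_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  sv <- svd(x0)
  dir <- sv$v[, 1]
  # orient consistently (positive y component preferred, then x, then z)
  key <- which.max(abs(dir))
  if (dir[key] < 0) dir <- -dir
  list(centroid = ctr, direction = dir)
}

# Distance between two (near-)parallel lines: perpendicular component of the
# centroid offset relative to the mean direction.
#' @noRd
line_distance <- function(ax1, ax2) {
  u <- ax1$direction + ax2$direction
  u <- u / sqrt(sum(u^2))
  d <- ax2$centroid - ax1$centroid
  perp <- d - sum(d * u) * u
  sqrt(sum(perp^2))
}

#' @noRd
angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' @noRd
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  rad2deg(atan2(y, x))
}
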