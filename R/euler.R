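# Orientation conventions
#
# Euler angles are Z-X-Z intrinsic, in degrees: R = Rz(phi) %*% Rx(theta) %*%
# Rz(psi). The matrix maps particle/box-frame coordinates into tomogram
# (world) coordinates; column 3 is the box z axis, which extraction aligns
# with the local filament tangent. psi is the in-plane (spin) angle about the
# filament axis.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles in degrees to (-180, 180]
#' @param a numeric vector of angles in degrees
#' @return wrapped angles
#' @keywords internal
wrap180 <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

#' Euler angles (Z-X-Z intrinsic, degrees) to rotation matrix
#'
#' @param phi,theta,psi Euler angles in degrees
#' @return 3x3 rotation matrix (box frame to world frame)
#' @export
eul2rot <- function(phi, theta, psi) {
  rot_z(phi) %*% rot_x(theta) %*% rot_z(psi)
}

#' Rotation matrix to Z-X-Z intrinsic Euler angles (degrees)
#'
#' Inverse of [eul2rot()]. At the gimbal singularity (theta = 0 or 180) the
#' split between phi and psi is not unique; phi is set to 0.
#'
#' @param R 3x3 rotation matrix
#' @return named numeric vector c(phi, theta, psi), theta in [0, 180]
#' @export
rot2eul <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- rad2deg(acos(ct))
  if (abs(ct) > 1 - 1e-10) {
    # R = Rz(phi + sign * psi): fold everything into psi
    psi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    if (ct < 0) psi <- -psi
    return(c(phi = 0, theta = theta, psi = wrap180(psi)))
  }
  phi <- rad2deg(atan2(R[1, 3], -R[2, 3]))
  psi <- rad2deg(atan2(R[3, 1], R[3, 2]))
  c(phi = wrap180(phi), theta = theta, psi = wrap180(psi))
}

# Frame whose z axis equals the given unit tangent; x,y chosen deterministically
# (used for the first frame of a filament; subsequent frames parallel-transport)
frame_from_tangent <- function(tz) {
  tz <- tz / sqrt(sum(tz^2))
  up <- if (abs(tz[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  tx <- up - sum(up * tz) * tz
  tx <- tx / sqrt(sum(tx^2))
  ty <- c(
    tz[2] * tx[3] - tz[3] * tx[2],
    tz[3] * tx[1] - tz[1] * tx[3],
    tz[1] * tx[2] - tz[2] * tx[1]
  )
  cbind(tx, ty, tz, deparse.level = 0)
}
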