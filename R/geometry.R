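# Angle helpers: the API speaks degrees (the convention of the optical
# metrology literature); all trigonometry is done in radians internally.
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#'
#' @param x angle(s) in degrees.
#' @param period wrapping period in degrees (360 by default; 90 for
#'   quantities defined modulo the fourfold blade symmetry).
#' @return angles wrapped into `[0, period)`.
#' @export
wrap_angle <- function(x, period = 360) {
  ((x %% period) + period) %% period
}

#' Rotation matrix about an arbitrary axis
#'
#' Builds the 3x3 matrix for a right-handed rotation of `angle_deg`
#' degrees about `axis` (Rodrigues' formula). This is the elementary
#' transform from which the local-to-global pose map is composed.
#'
#' @param axis numeric length-3 axis vector (need not be normalized, but
#'   must be non-zero).
#' @param angle_deg rotation angle in degrees.
#' @return a 3x3 orthogonal matrix with determinant +1 that leaves
#'   `axis` invariant.
#' @examples
#' rotation_matrix(c(0, 1, 0), 90) %*% c(0, 0, 1)  # -> x-hat
#' @export
rotation_matrix <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, is.finite(axis), is.finite(angle_deg))
  n2 <- sum(axis^2)
  if (n2 == 0) stop("rotation axis must be non-zero")
  n <- axis / sqrt(n2)
  th <- deg2rad(angle_deg)
  c_ <- cos(th); s_ <- sin(th)
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(n)
}

#' Tilt axis direction for a given azimuth
#'
#' The tilt of the rotor axis by polar angle theta happens about a
#' horizontal axis psi, itself obtained by rotating the global Y axis
#' about Z by the azimuth phi.
#'
#' @param phi_deg azimuth in degrees.
#' @return unit 3-vector `(-sin(phi), cos(phi), 0)`.
#' @export
tilt_axis <- function(phi_deg) {
  p <- deg2rad(phi_deg)
  c(-sin(p), cos(p), 0)
}

#' Rotor axis direction from spherical angles
#'
#' The rotor axis is `R_psi(theta) . Z-hat` with psi the tilt axis at
#' azimuth phi; this evaluates to the standard spherical parametrisation
#' `(sin(theta) cos(phi), sin(theta) sin(phi), cos(theta))`.
#'
#' @param phi_deg azimuth of the axis in degrees.
#' @param theta_deg polar angle (inclination from global Z) in degrees,
#'   in `[0, 90)`.
#' @return unit 3-vector.
#' @export
axis_from_angles <- function(phi_deg, theta_deg) {
  p <- deg2rad(phi_deg); t <- deg2rad(theta_deg)
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

#' Spherical angles of a rotor-axis direction
#'
#' Inverse of [axis_from_angles()]. The sign of `axis` is flipped if
#' needed so that the returned polar angle is below 90 degrees
#' (axes are orientation-free; the convention is `z . Z > 0`).
#'
#' @param axis numeric length-3 direction (non-zero).
#' @return list with `phi_deg` in `[0, 360)` and `theta_deg` in `[0, 90]`.
#'   For an axis aligned with Z the azimuth is conventionally 0.
#' @export
angles_from_axis <- function(axis) {
  n <- axis / sqrt(sum(axis^2))
  if (n[3] < 0) n <- -n
  theta <- rad2deg(acos(min(1, max(-1, n[3]))))
  phi <- if (n[1] == 0 && n[2] == 0) 0 else wrap_angle(rad2deg(atan2(n[2], n[1])))
  list(phi_deg = phi, theta_deg = theta)
}

#' Construct a rotor pose
#'
#' A pose is the full rigid placement of the impeller at one instant:
#' the center `OR` (intersection of the rotor axis with the blade-root
#' reference plane), the axis orientation in spherical angles, and the
#' blade angle alpha of the first main blade about the axis.
#'
#' @param center numeric length-3, global coordinates of OR in mm.
#' @param phi_deg axis azimuth in degrees.
#' @param theta_deg axis polar angle in degrees, `[0, 90)`.
#' @param alpha_deg blade angle in degrees.
#' @param frame integer frame index (optional).
#' @param time_s acquisition time in seconds (optional).
#' @return an object of class `rotor_pose`.
#' @export
rotor_pose <- function(center, phi_deg = 0, theta_deg = 0, alpha_deg = 0,
                       frame = NA_integer_, time_s = NA_real_) {
  stopifnot(length(center) == 3, is.finite(center),
            theta_deg >= 0, theta_deg < 90)
  structure(list(center = as.numeric(center),
                 phi_deg = wrap_angle(phi_deg),
                 theta_deg = theta_deg,
                 alpha_deg = wrap_angle(alpha_deg),
                 frame = frame, time_s = time_s),
            class = "rotor_pose")
}

#' @export
print.rotor_pose <- function(x, ...) {
  cat(sprintf(
    "rotor pose: OR = (%.4f, %.4f, %.4f) mm, phi = %.3f deg, theta = %.4f deg, alpha = %.3f deg\n",
    x$center[1], x$center[2], x$center[3], x$phi_deg, x$theta_deg, x$alpha_deg))
  invisible(x)
}

#' Rotation part of the local-to-global pose transform
#'
#' Composes `R_z(alpha) . R_psi(theta)`: first the tilt that carries the
#' global Z axis onto the rotor axis, then the blade rotation about that
#' (already tilted) axis.
#'
#' @param pose a `rotor_pose`.
#' @return 3x3 rotation matrix.
#' @export
pose_rotation <- function(pose) {
  psi <- tilt_axis(pose$phi_deg)
  z_ax <- axis_from_angles(pose$phi_deg, pose$theta_deg)
  rotation_matrix(z_ax, pose$alpha_deg) %*% rotation_matrix(psi, pose$theta_deg)
}

#' Map rotor-local coordinates to global coordinates
#'
#' `(X,Y,Z) = OR + R_z(alpha) . R_psi(theta) . (x,y,z)`.
#'
#' @param pose a `rotor_pose`.
#' @param p_local numeric length-3 point, or an `n x 3` matrix of points,
#'   in rotor-local mm.
#' @return point(s) in global mm, same shape as the input.
#' @export
local_to_global <- function(pose, p_local) {
  M <- pose_rotation(pose)
  if (is.matrix(p_local)) {
    sweep(p_local %*% t(M), 2, pose$center, "+")
  } else {
    as.numeric(M %*% p_local + pose$center)
  }
}

#' Map global coordinates to rotor-local coordinates
#'
#' Exact inverse of [local_to_global()].
#'
#' @inheritParams local_to_global
#' @param p_global numeric length-3 point or `n x 3` matrix, global mm.
#' @return point(s) in rotor-local mm.
#' @export
global_to_local <- function(pose, p_global) {
  M <- pose_rotation(pose)
  if (is.matrix(p_global)) {
    sweep(p_global, 2, pose$center, "-") %*% M
  } else {
    as.numeric(crossprod(M, p_global - pose$center))
  }
}

#' Convert a list of poses to the standard pose table
#'
#' @param poses list of `rotor_pose` objects.
#' @return data.frame with columns
#'   `frame,time_s,X_mm,Y_mm,Z_mm,phi_deg,theta_deg,alpha_deg`.
#' @export
pose_table <- function(poses) {
  do.call(rbind, lapply(poses, function(p) {
    data.frame(frame = p$frame, time_s = p$time_s,
               X_mm = p$center[1], Y_mm = p$center[2], Z_mm = p$center[3],
               phi_deg = p$phi_deg, theta_deg = p$theta_deg,
               alpha_deg = p$alpha_deg)
  }))
}

#' Rebuild pose objects from a pose table
#'
#' @param df data.frame in the layout written by [pose_table()].
#' @return list of `rotor_pose` objects.
#' @export
poses_from_table <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    rotor_pose(center = c(df$X_mm[i], df$Y_mm[i], df$Z_mm[i]),
               phi_deg = df$phi_deg[i], theta_deg = df$theta_deg[i],
               alpha_deg = df$alpha_deg[i],
               frame = df$frame[i], time_s = df$time_s[i])
  })
}

#' Write / read pose tables as CSV
#'
#' @param df pose table (see [pose_table()]).
#' @param path file path.
#' @export
write_pose_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  utils::read.csv(path)
}

# Circular statistics -------------------------------------------------

#' Circular mean of angles in degrees
#'
#' @param x angles in degrees.
#' @param w optional non-negative weights.
#' @param period period in degrees (360, or 90 for blade-symmetric
#'   quantities).
#' @return mean angle in `[0, period)`; `NA` if the resultant vector is
#'   (numerically) zero.
#' @export
circular_mean <- function(x, w = NULL, period = 360) {
  if (is.null(w)) w <- rep(1, length(x))
  th <- deg2rad(x * 360 / period)
  s <- sum(w * sin(th)); c_ <- sum(w * cos(th))
  if (sqrt(s^2 + c_^2) < 1e-12 * sum(w)) return(NA_real_)
  wrap_angle(rad2deg(atan2(s, c_)) * period / 360, period)
}

# Angle between two directions, degrees.
angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  rad2deg(acos(min(1, max(-1, ca))))
}
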