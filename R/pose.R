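#' Rigid-body poses
#'
#' A pose is a rotation (unit quaternion, scalar-first) plus a translation
#' in Angstrom. Poses act about a model's center of mass: applying a pose
#' with rotation R and translation t to coordinates x with center c gives
#' `R (x - c) + c + t`, which decouples rotation from translation in the
#' pose optimizer.
#'
#' @param quaternion length-4 numeric, scalar first; normalized on input.
#' @param translation length-3 numeric, Angstrom.
#' @return An object of class `pose`.
#' @export
pose <- function(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(length(quaternion) == 4, length(translation) == 3,
            all(is.finite(quaternion)), all(is.finite(translation)))
  n <- sqrt(sum(quaternion^2))
  if (n < 1e-12) stop("zero quaternion is not a rotation")
  structure(list(q = quaternion / n, t = as.numeric(translation)),
            class = "pose")
}

#' @rdname pose
#' @export
pose_identity <- function() pose()

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> angle %.2f deg, |t| = %.2f A\n",
              pose_angle(x), sqrt(sum(x$t^2))))
  invisible(x)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

quat_from_axis_angle <- function(axis, angle_rad) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12 || abs(angle_rad) < 1e-15) return(c(1, 0, 0, 0))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * axis / n)
}

#' Pose composition and inversion
#'
#' `pose_compose(p2, p1)` is the pose that applies `p1` first, then `p2`
#' (both acting about the same center). `pose_inverse(p)` undoes `p`.
#'
#' @param p2,p1,p poses.
#' @return A `pose`.
#' @export
pose_compose <- function(p2, p1) {
  R2 <- quat_to_matrix(p2$q)
  pose(quat_multiply(p2$q, p1$q), as.numeric(R2 %*% p1$t) + p2$t)
}

#' @rdname pose_compose
#' @export
pose_inverse <- function(p) {
  qi <- quat_conjugate(p$q)
  Ri <- quat_to_matrix(qi)
  pose(qi, -as.numeric(Ri %*% p$t))
}

#' @rdname pose_compose
#' @export
pose_rotation_matrix <- function(p) quat_to_matrix(p$q)

#' Rotation angle of a pose, degrees in [0, 180]
#' @param p a pose.
#' @export
pose_angle <- function(p) {
  w <- min(1, abs(p$q[1]))
  2 * acos(w) * 180 / pi
}

#' Pose from z-y-z Euler angles
#'
#' @param alpha,beta,gamma Euler angles (z-y-z convention).
#' @param translation optional translation.
#' @param degrees interpret angles in degrees (default) or radians.
#' @export
pose_from_euler <- function(alpha, beta, gamma, translation = c(0, 0, 0),
                            degrees = TRUE) {
  f <- if (degrees) pi / 180 else 1
  qz1 <- quat_from_axis_angle(c(0, 0, 1), alpha * f)
  qy <- quat_from_axis_angle(c(0, 1, 0), beta * f)
  qz2 <- quat_from_axis_angle(c(0, 0, 1), gamma * f)
  pose(quat_multiply(quat_multiply(qz1, qy), qz2), translation)
}

#' Distance between two poses
#'
#' Rotational part in degrees (quaternion double cover handled) and
#' translational part in Angstrom.
#'
#' @param a,b poses.
#' @return named numeric `c(angle = , shift = )`.
#' @export
pose_distance <- function(a, b) {
  dq <- quat_multiply(quat_conjugate(a$q), b$q)
  ang <- 2 * acos(min(1, abs(dq[1]))) * 180 / pi
  c(angle = ang, shift = sqrt(sum((a$t - b$t)^2)))
}

# pose from a 6-vector chart (tx,ty,tz, rx,ry,rz): axis-angle increment
# (radians) composed onto a base pose. Used by the L-BFGS refiners.
pose_from_chart <- function(par, base) {
  ang <- sqrt(sum(par[4:6]^2))
  qd <- quat_from_axis_angle(par[4:6], ang)
  pose(quat_multiply(qd, base$q), base$t + par[1:3])
}
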