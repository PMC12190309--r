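#' Quaternion algebra (Hamilton convention, scalar-first)
#'
#' Orientation is represented throughout the package as unit quaternions in
#' the Hamilton convention with the scalar component first, i.e. a rotation by
#' angle \eqn{\theta} about unit axis \eqn{\hat{n}} is
#' \eqn{q = (\cos(\theta/2),\ \hat{n}\sin(\theta/2))}. Quaternions map the
#' sensor frame to the world frame: \eqn{v_w = q \otimes v_s \otimes q^*}.
#'
#' All functions are vectorised over rows: a "quaternion" argument is an
#' n-by-4 numeric matrix with columns `qw, qx, qy, qz` (a single quaternion
#' may be given as a length-4 vector).
#'
#' @param q,q1,q2 quaternion matrices (n x 4) or length-4 vectors.
#' @name quaternion
NULL

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  stopifnot(ncol(q) == 4)
  q
}

#' @describeIn quaternion Normalise each row to unit norm.
#' @export
quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n == 0)) stop("cannot normalise a zero quaternion")
  q / n
}

#' @describeIn quaternion Quaternion conjugate (inverse for unit quaternions).
#' @export
quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' @describeIn quaternion Hamilton product `q1 %*% q2`, row-wise.
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- as_quat_matrix(q1)
  q2 <- as_quat_matrix(q2)
  if (nrow(q1) == 1 && nrow(q2) > 1) q1 <- q1[rep(1, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1 && nrow(q1) > 1) q2 <- q2[rep(1, nrow(q1)), , drop = FALSE]
  stopifnot(nrow(q1) == nrow(q2))
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(
    qw = w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    qx = w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    qy = w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    qz = w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

#' @describeIn quaternion Rotate 3-vectors (n x 3 matrix `v`) by `q`.
#' @param v n x 3 matrix of vectors (or length-3 vector).
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  qv <- cbind(0, v)
  out <- quat_multiply(quat_multiply(q, qv), quat_conjugate(q))
  out[, 2:4, drop = FALSE]
}

#' @describeIn quaternion Quaternion for rotation `angle_rad` about `axis`.
#' @param axis length-3 axis (need not be unit length).
#' @param angle_rad rotation angle(s) in radians.
#' @export
quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_rad / 2
  cbind(qw = cos(half), qx = axis[1] * sin(half),
        qy = axis[2] * sin(half), qz = axis[3] * sin(half))
}

#' @describeIn quaternion Exponential map: rotation vectors (n x 3, radians,
#'   axis times angle) to unit quaternions.
#' @param rotvec n x 3 matrix of rotation vectors.
#' @export
quat_exp <- function(rotvec) {
  if (is.null(dim(rotvec))) rotvec <- matrix(rotvec, ncol = 3)
  theta <- sqrt(rowSums(rotvec^2))
  # sinc(theta/2) stable near zero
  k <- ifelse(theta < 1e-12, 0.5, sin(theta / 2) / theta)
  cbind(qw = cos(theta / 2), qx = rotvec[, 1] * k,
        qy = rotvec[, 2] * k, qz = rotvec[, 3] * k)
}

#' @describeIn quaternion Logarithm map: unit quaternions to rotation vectors
#'   (axis times angle, radians), with angle in `[0, pi]` after sign fixing.
#' @export
quat_log <- function(q) {
  q <- as_quat_matrix(q)
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  theta <- 2 * atan2(vn, q[, 1])
  k <- ifelse(vn < 1e-12, 2, theta / vn)
  q[, 2:4, drop = FALSE] * k
}

#' @describeIn quaternion Rotation matrix (3 x 3, sensor-to-world) for a
#'   single unit quaternion.
#' @export
quat_to_matrix <- function(q) {
  q <- as_quat_matrix(q)
  stopifnot(nrow(q) == 1)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @describeIn quaternion Unit quaternion from a rotation matrix (Shepperd's
#'   method, numerically stable for all rotations).
#' @param R 3 x 3 rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  stopifnot(all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- matrix(q, ncol = 4, dimnames = list(NULL, c("qw", "qx", "qy", "qz")))
  quat_normalize(q)
}

#' @describeIn quaternion Intrinsic Z-Y-X Euler angles (radians), returned as
#'   an n x 3 matrix with columns `z, y, x`. The decomposition satisfies
#'   `R = Rz(z) Ry(y) Rx(x)`.
#' @export
quat_to_euler_zyx <- function(q) {
  q <- as_quat_matrix(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rotation-matrix elements needed for the ZYX extraction
  r11 <- 1 - 2 * (y^2 + z^2)
  r21 <- 2 * (x * y + w * z)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  cbind(z = atan2(r21, r11),
        y = asin(pmin(1, pmax(-1, -r31))),
        x = atan2(r32, r33))
}

#' @describeIn quaternion Compose a quaternion from intrinsic Z-Y-X Euler
#'   angles (radians; vectors recycle to a common length).
#' @param z,y,x Euler angles in radians about the Z (medio-lateral),
#'   Y (vertical) and X (antero-posterior) axes.
#' @export
euler_zyx_to_quat <- function(z, y, x) {
  n <- max(length(z), length(y), length(x))
  z <- rep_len(z, n); y <- rep_len(y, n); x <- rep_len(x, n)
  qz <- cbind(cos(z / 2), 0, 0, sin(z / 2))
  qy <- cbind(cos(y / 2), 0, sin(y / 2), 0)
  qx <- cbind(cos(x / 2), sin(x / 2), 0, 0)
  quat_multiply(quat_multiply(qz, qy), qx)
}

# Enforce temporal continuity: flip signs so dot(q_t, q_{t+1}) >= 0.
quat_enforce_continuity <- function(q) {
  q <- as_quat_matrix(q)
  if (nrow(q) < 2) return(q)
  s <- cumprod(c(1, sign(rowSums(q[-nrow(q), , drop = FALSE] *
                                   q[-1, , drop = FALSE]) + 1e-300)))
  q * s
}

# Spherical linear interpolation between paired rows of q1 and q2 at t in [0,1].
quat_slerp <- function(q1, q2, t) {
  q1 <- as_quat_matrix(q1)
  q2 <- as_quat_matrix(q2)
  d <- rowSums(q1 * q2)
  q2[d < 0, ] <- -q2[d < 0, , drop = FALSE]
  d <- abs(pmin(1, d))
  theta <- acos(d)
  small <- theta < 1e-8
  w1 <- ifelse(small, 1 - t, sin((1 - t) * theta) / sin(pmax(theta, 1e-30)))
  w2 <- ifelse(small, t, sin(t * theta) / sin(pmax(theta, 1e-30)))
  quat_normalize(q1 * w1 + q2 * w2)
}
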