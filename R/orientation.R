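# Quaternion algebra and gradient-descent (Madgwick) orientation estimation.
#
# Convention: quaternions are numeric length-4 vectors (w, x, y, z) mapping
# the sensor frame to the global frame: v_global = q (x) v_body (x) q*.
# The global frame has the y-axis up (gravity along -y as sensed specific
# force +y), the x-axis along the horizontal reference direction (magnetic
# north when a magnetometer is used, otherwise the initial heading), and a
# transverse z-axis.

#' Quaternion product
#' @param p,q quaternions as numeric `(w, x, y, z)`.
#' @return the Hamilton product `p (x) q`.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Quaternion conjugate
#' @param q quaternion `(w, x, y, z)`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit norm
#' @param q quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotate a 3-vector by a quaternion (sensor frame to global frame)
#' @param q unit quaternion.
#' @param v length-3 vector.
#' @export
quat_rotate <- function(q, v) {
  out <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  out[2:4]
}

#' Quaternion from an axis-angle rotation
#' @param axis length-3 rotation axis (normalized internally).
#' @param angle rotation angle, radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion (sensor frame to global frame)
#' @param q unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Objective f(q) = R(q)^T d - s for a global reference direction d and a
# normalized sensor observation s, plus its analytic gradient J^T f.
# Used with d = (0, 1, 0) for gravity and with the magnetic field reference
# for the MARG update.
.ref_gradient <- function(q, d, s) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  dx <- d[1]; dy <- d[2]; dz <- d[3]
  v1 <- dx * (1 - 2 * (y^2 + z^2)) + dy * 2 * (x * y + w * z) + dz * 2 * (x * z - w * y)
  v2 <- dx * 2 * (x * y - w * z) + dy * (1 - 2 * (x^2 + z^2)) + dz * 2 * (y * z + w * x)
  v3 <- dx * 2 * (x * z + w * y) + dy * 2 * (y * z - w * x) + dz * (1 - 2 * (x^2 + y^2))
  f <- c(v1 - s[1], v2 - s[2], v3 - s[3])
  J <- matrix(c(
    2 * (dy * z - dz * y), 2 * (dy * y + dz * z), 2 * (-2 * dx * y + dy * x - dz * w), 2 * (-2 * dx * z + dy * w + dz * x),
    2 * (dz * x - dx * z), 2 * (dx * y - 2 * dy * x + dz * w), 2 * (dx * x + dz * z), 2 * (-dx * w - 2 * dy * z + dz * y),
    2 * (dx * y - dy * x), 2 * (dx * z - dy * w - 2 * dz * x), 2 * (dx * w + dy * z - 2 * dz * y), 2 * (dx * x + dy * y)
  ), nrow = 3, byrow = TRUE)
  as.numeric(crossprod(J, f))
}

#' Estimate sensor orientation with the gradient-descent (Madgwick) filter
#'
#' Fuses the gyroscope with the accelerometer (and, optionally, the
#' magnetometer when present and enabled) to estimate the per-sample unit
#' quaternion mapping the sensor frame to the global frame. With
#' `beta = 0` the filter reduces to pure gyroscope strap-down integration.
#'
#' When no initial quaternion is given, `q0` is derived from the mean
#' accelerometer direction over the first `madgwick.init_s` seconds of quiet
#' standing (smallest rotation aligning sensed gravity with global +y).
#'
#' @param rec [imu_recording()].
#' @param beta filter gain (dimensionless); default from `cfg`.
#' @param q0 optional initial unit quaternion `(w, x, y, z)`.
#' @param cfg configuration list, see [ss_config()].
#' @return object of class `orientation_series`: list with `q` (n x 4
#'   matrix of unit quaternions), `beta`, `fs`.
#' @export
estimate_orientation <- function(rec, beta = NULL, q0 = NULL, cfg = ss_config()) {
  if (!inherits(rec, "imu_recording")) stop("`rec` must be an imu_recording")
  if (rec$fs <= 0) stop("fs must be positive")
  beta <- beta %||% cfg[["madgwick.beta"]]
  use_mag <- isTRUE(cfg[["madgwick.use_magnetometer"]]) && !is.null(rec$mag)
  n <- length(rec$t)
  acc_norm <- sqrt(rowSums(rec$acc^2))
  if (beta > 0 && any(acc_norm == 0)) {
    stop("accelerometer observation has zero norm at sample ",
         which(acc_norm == 0)[1L], "; cannot normalize the gravity reference")
  }
  if (is.null(q0)) {
    n_init <- max(1L, min(n, round(cfg[["madgwick.init_s"]] * rec$fs)))
    a0 <- colMeans(rec$acc[seq_len(n_init), , drop = FALSE])
    if (sqrt(sum(a0^2)) == 0) stop("cannot initialize: zero mean accelerometer over init window")
    q0 <- .quat_align(a0 / sqrt(sum(a0^2)), c(0, 1, 0))
  }
  q0 <- quat_normalize(q0)
  Q <- matrix(NA_real_, n, 4L)
  Q[1L, ] <- q0
  q <- q0
  for (i in seq_len(n - 1L)) {
    dt <- rec$t[i + 1L] - rec$t[i]
    gyr <- rec$gyr[i + 1L, ]
    qdot <- 0.5 * quat_multiply(q, c(0, gyr))
    if (beta > 0) {
      s <- rec$acc[i + 1L, ] / acc_norm[i + 1L]
      grad <- .ref_gradient(q, c(0, 1, 0), s)
      if (use_mag) {
        m <- rec$mag[i + 1L, ]
        mn <- sqrt(sum(m^2))
        if (mn > 0) {
          h <- quat_rotate(q, m / mn)
          b <- c(sqrt(h[1]^2 + h[3]^2), h[2], 0)  # horizontal + vertical field
          grad <- grad + .ref_gradient(q, b, m / mn)
        }
      }
      gn <- sqrt(sum(grad^2))
      if (gn > 0) qdot <- qdot - beta * grad / gn
    }
    q <- quat_normalize(q + qdot * dt)
    Q[i + 1L, ] <- q
  }
  structure(list(q = Q, beta = beta, fs = rec$fs), class = "orientation_series")
}

# Smallest rotation taking unit vector `from` to unit vector `to`.
.quat_align <- function(from, to) {
  d <- sum(from * to)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees: pick any axis orthogonal to `from`
    axis <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * from) * from
    return(quat_from_axis_angle(axis, pi))
  }
  axis <- c(from[2] * to[3] - from[3] * to[2],
            from[3] * to[1] - from[1] * to[3],
            from[1] * to[2] - from[2] * to[1])
  quat_normalize(c(1 + d, axis))
}

#' Rotate body-frame acceleration into the global frame
#'
#' Applies the per-sample orientation to the measured specific force and
#' subtracts gravity `(0, g, 0)`, yielding global-frame acceleration whose
#' horizontal components `acc_x` and `acc_z` feed the stride-length
#' integration.
#'
#' @param rec [imu_recording()].
#' @param ori orientation from [estimate_orientation()].
#' @param g gravitational acceleration, m/s^2.
#' @return [global_sprint()].
#' @export
to_global <- function(rec, ori, g = G_DEFAULT) {
  n <- length(rec$t)
  if (nrow(ori$q) != n) stop("orientation length does not match the recording")
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    out[i, ] <- quat_rotate(ori$q[i, ], rec$acc[i, ])
  }
  out[, 2L] <- out[, 2L] - g
  global_sprint(rec$t, out[, 1L], out[, 2L], out[, 3L], fs = rec$fs,
                foot = rec$foot)
}

#' Pitch angle about the global z-axis of an orientation series
#'
#' Convenience for validating foot-angle time profiles: the angle between
#' the global x-axis and the body x-axis projected on the x-y (sagittal)
#' plane.
#'
#' @param ori orientation from [estimate_orientation()].
#' @return numeric vector of angles, radians.
#' @export
orientation_pitch <- function(ori) {
  apply(ori$q, 1L, function(q) {
    bx <- quat_rotate(q, c(1, 0, 0))
    atan2(bx[2], bx[1])
  })
}
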