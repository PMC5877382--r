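#' Quaternion algebra for orientation processing
#'
#' Quaternions are stored scalar-first as numeric vectors `c(w, x, y, z)` or as
#' n-by-4 matrices (one quaternion per row). The Hamilton convention is used
#' throughout, and an orientation quaternion represents the rotation from the
#' global/navigation frame to the sensor body frame: a vector with global
#' coordinates `v` has body coordinates `q (0,v) q*`. All public angle
#' arguments and return values are in degrees unless stated otherwise;
#' internal math is in radians.
#'
#' @name quaternions
NULL

#' Construct a quaternion
#'
#' @param w Scalar part (or a length-4 vector / n-by-4 matrix holding whole
#'   quaternions, in which case the remaining arguments are ignored).
#' @param x,y,z Vector parts.
#' @return A numeric n-by-4 matrix with columns `w, x, y, z`.
#' @export
quat <- function(w, x = NULL, y = NULL, z = NULL) {
  if (is.matrix(w)) {
    stopifnot(ncol(w) == 4)
    q <- w
  } else if (is.null(x) && length(w) == 4) {
    q <- matrix(w, nrow = 1)
  } else {
    q <- cbind(w, x, y, z)
  }
  dimnames(q) <- list(NULL, c("w", "x", "y", "z"))
  q
}

quat_identity <- function(n = 1) {
  quat(cbind(rep(1, n), 0, 0, 0))
}

#' Quaternion Hamilton product
#'
#' Computes `q1` \eqn{\otimes} `q2`, vectorized over rows (with recycling of a
#' single-row operand). The result is unit-norm whenever both inputs are.
#'
#' @param q1,q2 Quaternions as length-4 vectors or n-by-4 matrices.
#' @return An n-by-4 quaternion matrix.
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- quat(q1); q2 <- quat(q2)
  if (nrow(q1) == 1L && nrow(q2) > 1L) q1 <- q1[rep(1L, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1L && nrow(q1) > 1L) q2 <- q2[rep(1L, nrow(q1)), , drop = FALSE]
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  quat(cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  ))
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) {
  q <- quat(q)
  quat(cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4]))
}

quat_norm <- function(q) {
  q <- quat(q)
  sqrt(rowSums(q^2))
}

#' @rdname quat_multiply
#' @export
quat_normalize <- function(q) {
  q <- quat(q)
  n <- quat_norm(q)
  if (any(n < 1e-12)) stop("cannot normalize a (near-)zero quaternion")
  quat(q / n)
}

#' Axis-angle quaternion construction
#'
#' Builds the rotation quaternion `(cos(theta/2), axis * sin(theta/2))`.
#'
#' @param axis Unit 3-vector; a non-unit axis is normalized with a warning, a
#'   zero axis is an error.
#' @param theta Rotation angle in radians.
#' @return A 1-by-4 quaternion matrix.
#' @export
from_axis_angle <- function(axis, theta) {
  stopifnot(length(axis) == 3, length(theta) == 1)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("rotation axis must be non-zero")
  if (abs(nrm - 1) > 1e-9) {
    warning("axis is not unit length; normalizing")
    axis <- axis / nrm
  } else {
    axis <- axis / nrm
  }
  quat(c(cos(theta / 2), axis * sin(theta / 2)))
}

#' Rotate 3-vectors by quaternions
#'
#' Applies the quaternion sandwich product `q (0,v) q*`, vectorized over rows.
#' Under the package convention this maps global coordinates to body
#' coordinates for an orientation quaternion; use [quat_conjugate()] for the
#' inverse (body-to-global) map.
#'
#' @param q Quaternion(s), n-by-4 or 1-by-4.
#' @param v 3-vector or n-by-3 matrix.
#' @return n-by-3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- quat(q)
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  stopifnot(ncol(v) == 3)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1]; qv <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (qv x v) + 2 qv x (qv x v)
  t1 <- cross3(qv, v)
  v + 2 * w * t1 + 2 * cross3(qv, t1)
}

cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' Convert between quaternions and rotation matrices
#'
#' `quat_to_matrix` returns the 3-by-3 matrix `R` with `R v = q (0,v) q*`;
#' `quat_from_matrix` is its inverse (Shepperd's method), returning a
#' unit quaternion with non-negative scalar part.
#'
#' @param q A quaternion (length-4 or 1-by-4).
#' @param R A 3-by-3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(quat(q))
  w <- q[1, 1]; x <- q[1, 2]; y <- q[1, 3]; z <- q[1, 4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_matrix
#' @export
quat_from_matrix <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(quat(q))
}

#' Geodesic distance between rotations
#'
#' Smallest rotation angle (radians) taking one orientation to the other;
#' insensitive to the q / -q sign ambiguity.
#'
#' @param q1,q2 Quaternions (length-4 vectors or n-by-4 matrices).
#' @return Numeric vector of angles in radians, in `[0, pi]`.
#' @export
quat_geodesic <- function(q1, q2) {
  q1 <- quat(q1); q2 <- quat(q2)
  if (nrow(q1) == 1L && nrow(q2) > 1L) q1 <- q1[rep(1L, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1L && nrow(q1) > 1L) q2 <- q2[rep(1L, nrow(q1)), , drop = FALSE]
  d <- abs(rowSums(q1 * q2) / (quat_norm(q1) * quat_norm(q2)))
  2 * acos(pmin(1, d))
}

#' Single-step gyroscope integration
#'
#' Advances an orientation by first-order Euler integration of the body-frame
#' angular rate: `q_k = normalize(q_{k-1} + 0.5 * q_{k-1} (0, omega) dt)`,
#' with `omega` supplied in deg/s and converted internally to rad/s.
#'
#' @param q_prev Unit quaternion at the previous sample.
#' @param omega Angular velocity, deg/s, body frame (length-3).
#' @param dt Sample period in seconds (> 0).
#' @return A 1-by-4 unit quaternion.
#' @export
integrate_gyro <- function(q_prev, omega, dt) {
  stopifnot(dt > 0, length(omega) == 3)
  q_prev <- quat(q_prev)
  om <- omega * pi / 180
  qdot <- 0.5 * quat_multiply(q_prev, quat(c(0, om)))
  quat_normalize(q_prev + qdot * dt)
}

#' Construct a unit-quaternion orientation signal
#'
#' Normalizes every valid sample and enforces sign continuity
#' (`dot(q_k, q_{k-1}) >= 0`): `q` and `-q` encode the same rotation and a
#' consistent sign is required for numerical differentiation.
#'
#' @param q n-by-4 quaternion matrix (rows may be NA where `gap` is TRUE).
#' @param fs Sample rate, Hz.
#' @param t0 Absolute start time, s.
#' @param gap Logical gap mask (TRUE = placeholder sample); defaults to rows
#'   containing NA.
#' @return An object of class `quat_signal` with fields `q`, `fs`, `t0`, `gap`.
#' @export
quat_signal <- function(q, fs, t0 = 0, gap = NULL) {
  q <- quat(q)
  stopifnot(is.numeric(fs), fs > 0)
  n <- nrow(q)
  if (is.null(gap)) gap <- rowSums(is.na(q)) > 0
  stopifnot(length(gap) == n)
  valid <- which(!gap)
  if (length(valid)) {
    q[valid, ] <- quat_normalize(q[valid, , drop = FALSE])
    # sign continuity across valid samples (gaps are skipped, not reset)
    if (length(valid) > 1) {
      dots <- rowSums(q[valid[-1], , drop = FALSE] * q[valid[-length(valid)], , drop = FALSE])
      flips <- cumsum(c(FALSE, dots < 0)) %% 2 == 1
      q[valid[flips], ] <- -q[valid[flips], , drop = FALSE]
    }
  }
  structure(list(q = q, fs = fs, t0 = t0, gap = as.logical(gap)),
            class = "quat_signal")
}

#' @exportS3Method base::print
print.quat_signal <- function(x, ...) {
  cat(sprintf("<quat_signal> %d samples @ %g Hz, t0 = %g s, %d gap sample(s)\n",
              nrow(x$q), x$fs, x$t0, sum(x$gap)))
  invisible(x)
}

#' @export
length.quat_signal <- function(x) nrow(x$q)

qsig_time <- function(x) x$t0 + (seq_len(nrow(x$q)) - 1) / x$fs

#' Numerical quaternion differentiation to angular velocity
#'
#' Inverts single-step gyro integration: with
#' `qdot_k = (q_k - q_{k-1}) / dt`, the body angular rate is
#' `omega_k = 2 vec(q*_{k-1} qdot_k) / Re(q*_{k-1} q_k)` (reported in
#' deg/s). The scalar divisor (the cosine of the half-step angle, within
#' 1e-4 of one at gait rates) makes the formula the exact algebraic inverse
#' of the renormalized first-order integration step, so that
#' differentiate-integrate round trips are lossless rather than accumulating
#' a second-order rate error. The first sample copies the second; gap
#' samples propagate to the output mask.
#'
#' @param qsig A [quat_signal()] with at least 2 samples.
#' @return An object of class `angvel_signal`: fields `omega` (n-by-3, deg/s,
#'   body frame), `fs`, `t0`, `gap`.
#' @export
differentiate_quats <- function(qsig) {
  stopifnot(inherits(qsig, "quat_signal"), nrow(qsig$q) >= 2)
  q <- qsig$q
  n <- nrow(q)
  dt <- 1 / qsig$fs
  qdot <- (q[-1, , drop = FALSE] - q[-n, , drop = FALSE]) / dt
  prod <- quat_multiply(quat_conjugate(q[-n, , drop = FALSE]), qdot)
  # Re(q*_{k-1} q_k) = 1 + dt * Re(q*_{k-1} qdot_k)
  wp <- pmax(1 + dt * prod[, 1], 1e-6)
  omega <- 2 * prod[, 2:4, drop = FALSE] / wp * 180 / pi
  omega <- rbind(omega[1, ], omega)
  gap <- qsig$gap | c(qsig$gap[1], qsig$gap[-n])  # a diff touching a gap is a gap
  gap[1] <- gap[2]
  omega[gap, ] <- NA_real_
  angvel_signal(omega, qsig$fs, qsig$t0, gap)
}

#' Construct an angular-velocity signal
#'
#' @param omega n-by-3 matrix, deg/s, body frame.
#' @param fs Sample rate, Hz.
#' @param t0 Start time, s.
#' @param gap Logical gap mask; defaults to rows with NA.
#' @return An object of class `angvel_signal`.
#' @export
angvel_signal <- function(omega, fs, t0 = 0, gap = NULL) {
  if (!is.matrix(omega)) omega <- matrix(omega, ncol = 3)
  stopifnot(ncol(omega) == 3, fs > 0)
  if (is.null(gap)) gap <- rowSums(is.na(omega)) > 0
  stopifnot(length(gap) == nrow(omega))
  structure(list(omega = omega, fs = fs, t0 = t0, gap = as.logical(gap)),
            class = "angvel_signal")
}

#' @exportS3Method base::print
print.angvel_signal <- function(x, ...) {
  cat(sprintf("<angvel_signal> %d samples @ %g Hz, %d gap sample(s)\n",
              nrow(x$omega), x$fs, sum(x$gap)))
  invisible(x)
}

#' Integrate an angular-velocity signal into an orientation signal
#'
#' Convenience chain of [integrate_gyro()] over a whole recording.
#'
#' @param omega An `angvel_signal` (deg/s, body frame).
#' @param q0 Initial orientation (unit quaternion), default identity.
#' @return A [quat_signal()].
#' @export
integrate_angvel <- function(omega, q0 = quat_identity()) {
  stopifnot(inherits(omega, "angvel_signal"))
  om <- omega$omega * pi / 180
  n <- nrow(om)
  dt <- 1 / omega$fs
  q <- matrix(NA_real_, n, 4)
  cur <- as.numeric(quat_normalize(quat(q0)))
  q[1, ] <- cur
  for (k in seq_len(n - 1) + 1) {
    o <- om[k, ]
    if (anyNA(o)) o <- c(0, 0, 0)  # hold orientation through gaps
    w <- cur[1]; x <- cur[2]; y <- cur[3]; z <- cur[4]
    nw <- w - 0.5 * dt * (x * o[1] + y * o[2] + z * o[3])
    nx <- x + 0.5 * dt * (w * o[1] + y * o[3] - z * o[2])
    ny <- y + 0.5 * dt * (w * o[2] - x * o[3] + z * o[1])
    nz <- z + 0.5 * dt * (w * o[3] + x * o[2] - y * o[1])
    nn <- sqrt(nw * nw + nx * nx + ny * ny + nz * nz)
    cur <- c(nw, nx, ny, nz) / nn
    q[k, ] <- cur
  }
  quat_signal(q, omega$fs, omega$t0, gap = omega$gap)
}

#' Swing-twist decomposition
#'
#' Factors a rotation `qr` into `qr = twist %*% swing` (quaternion product),
#' where the twist is a rotation about `axis` and the swing's rotation axis is
#' perpendicular to `axis`. The twist is obtained by projecting the vector
#' part of `qr` onto `axis` and renormalizing `(w, proj)`; the swing is
#' `twist* %*% qr`. In the degenerate 180-degree-swing case (projection and
#' scalar part both ~0) the twist is the identity and the attribute
#' `degenerate` is set on the result.
#'
#' @param qr Unit quaternion.
#' @param axis Unit 3-vector twist axis.
#' @return List with unit quaternions `twist` and `swing` and logical
#'   `degenerate`.
#' @export
swing_twist <- function(qr, axis) {
  qr <- quat(qr)
  stopifnot(length(axis) == 3)
  axis <- axis / sqrt(sum(axis^2))
  w <- qr[, 1]
  proj <- qr[, 2:4, drop = FALSE] %*% axis  # component of vec(qr) along axis
  tw <- cbind(w, proj %*% t(axis))
  nrm <- sqrt(rowSums(tw^2))
  degen <- nrm < 1e-9
  tw[degen, ] <- rep(c(1, 0, 0, 0), each = sum(degen))
  tw[!degen, ] <- tw[!degen, , drop = FALSE] / nrm[!degen]
  twist <- quat(tw)
  swing <- quat_multiply(quat_conjugate(twist), qr)
  list(twist = twist, swing = swing, degenerate = degen)
}

#' Signed twist angle about an axis
#'
#' Extracts the signed rotation angle (degrees, in (-180, 180]) of a twist
#' quaternion whose vector part is parallel to `axis`; positive when the
#' vector part aligns with `+axis`.
#'
#' @param twist Twist quaternion(s) (n-by-4), e.g. from [swing_twist()].
#' @param axis Unit 3-vector.
#' @return Numeric vector of angles in degrees.
#' @export
twist_angle <- function(twist, axis) {
  twist <- quat(twist)
  stopifnot(length(axis) == 3)
  axis <- axis / sqrt(sum(axis^2))
  v <- twist[, 2:4, drop = FALSE]
  comp <- as.numeric(v %*% axis)
  perp <- sqrt(pmax(0, rowSums(v^2) - comp^2))
  if (any(perp > 1e-6 * pmax(abs(comp), 1e-12) + 1e-9)) {
    stop("twist vector part is not parallel to the supplied axis")
  }
  ang <- 2 * atan2(comp, twist[, 1]) * 180 / pi
  # wrap to (-180, 180]
  ang <- ((ang + 180) %% 360) - 180
  ang[ang == -180] <- 180
  ang
}

#' Spherical linear interpolation between quaternion samples
#'
#' @param q1,q2 Unit quaternions (n-by-4, recycled if 1-by-4).
#' @param f Interpolation fraction(s) in `[0, 1]`.
#' @return Interpolated unit quaternions (n-by-4).
#' @export
quat_slerp <- function(q1, q2, f) {
  q1 <- quat(q1); q2 <- quat(q2)
  n <- max(nrow(q1), nrow(q2), length(f))
  if (nrow(q1) == 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  if (nrow(q2) == 1L) q2 <- q2[rep(1L, n), , drop = FALSE]
  f <- rep_len(f, n)
  d <- rowSums(q1 * q2)
  q2[d < 0, ] <- -q2[d < 0, , drop = FALSE]
  d <- abs(d)
  out <- matrix(NA_real_, n, 4)
  close <- d > 1 - 1e-9
  if (any(close)) {
    out[close, ] <- q1[close, , drop = FALSE] * (1 - f[close]) +
      q2[close, , drop = FALSE] * f[close]
  }
  if (any(!close)) {
    th <- acos(pmin(1, d[!close]))
    s <- sin(th)
    a <- sin((1 - f[!close]) * th) / s
    b <- sin(f[!close] * th) / s
    out[!close, ] <- q1[!close, , drop = FALSE] * a + q2[!close, , drop = FALSE] * b
  }
  quat_normalize(quat(out))
}
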