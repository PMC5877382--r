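#' Complementary-filter orientation estimation
#'
#' Gyroscope integration with a gravity-referenced tilt correction: at each
#' sample the orientation is advanced by first-order integration of the body
#' angular rate, then rotated a small fraction `accel_gain` of the way toward
#' the orientation implied by the accelerometer's gravity direction. The
#' correction axis is perpendicular to gravity in the body frame, so pitch and
#' roll drift are compensated while the yaw angle is never corrected (no
#' magnetometer is used and no absolute heading exists).
#'
#' @name ahrs
NULL

#' AHRS configuration
#'
#' @param accel_gain Static accelerometer filter gain in `[0, 1]`
#'   (dimensionless). The default 1e-4 weights the accelerometer just enough
#'   to cancel gyro tilt drift over tens of seconds without admitting motion
#'   acceleration into the tilt estimate.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param freefall_g Fraction of `gravity` below which the accelerometer
#'   correction is skipped (free-fall / impact guard).
#' @param max_gap_bridge Longest gap (s) bridged by gyro-only prediction.
#' @param init_window Duration (s) over which the accelerometer is averaged
#'   for the initial tilt. A single sample would be polluted by motion
#'   acceleration, and with the small correction gain an initial tilt error
#'   decays with a time constant of `1/(gain * sample_rate)` seconds, so a
#'   good start matters; averaging over about a stride cancels the periodic
#'   motion component.
#' @return A list of class `ahrs_config`.
#' @export
ahrs_config <- function(accel_gain = 1e-4, gravity = 9.81,
                        freefall_g = 0.5, max_gap_bridge = 0.5,
                        init_window = 2) {
  stopifnot(accel_gain >= 0, accel_gain <= 1, gravity > 0, init_window >= 0)
  structure(list(accel_gain = accel_gain, gravity = gravity,
                 freefall_g = freefall_g, max_gap_bridge = max_gap_bridge,
                 init_window = init_window),
            class = "ahrs_config")
}

#' IMU recording container
#'
#' @param acc 3-channel `gait_ts`, m/s^2, body frame.
#' @param gyro An [angvel_signal()], deg/s, body frame.
#' @param location Sensor location label, one of poll, withers, sternum,
#'   sacrum, LF, RF, LH, RH.
#' @return A list of class `imu_recording`. Acc and gyro must share the time
#'   base; the union of their gap masks is used.
#' @export
imu_recording <- function(acc, gyro, location = c("sacrum", "withers", "sternum",
                                                  "poll", "LF", "RF", "LH", "RH")) {
  location <- match.arg(location)
  stopifnot(inherits(acc, "gait_ts"), ncol(acc$data) == 3,
            inherits(gyro, "angvel_signal"))
  if (abs(acc$fs - gyro$fs) > 1e-9 || nrow(acc$data) != nrow(gyro$omega)) {
    stop("acc and gyro must share a time base")
  }
  gap <- acc$gap | gyro$gap
  acc$gap <- gap; gyro$gap <- gap
  structure(list(acc = acc, gyro = gyro, location = location,
                 fs = acc$fs, t0 = acc$t0),
            class = "imu_recording")
}

#' @exportS3Method base::print
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s: %d samples @ %g Hz, %d gap(s)\n",
              x$location, nrow(x$acc$data), x$fs, sum(x$acc$gap)))
  invisible(x)
}

# orientation with yaw 0 whose predicted gravity matches the measured direction
init_from_gravity <- function(f_b) {
  fn <- f_b / sqrt(sum(f_b^2))
  z <- c(0, 0, 1)
  ax <- c(z[2] * fn[3] - z[3] * fn[2],
          z[3] * fn[1] - z[1] * fn[3],
          z[1] * fn[2] - z[2] * fn[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (fn[3] > 0) return(quat_identity())
    return(quat(c(0, 1, 0, 0)))  # upside-down: 180 deg about x
  }
  from_axis_angle(ax / s, atan2(s, sum(z * fn)))
}

#' Estimate orientation from an IMU recording
#'
#' @param imu An [imu_recording()].
#' @param cfg An [ahrs_config()].
#' @return A [quat_signal()] of per-sample orientations (global-to-body
#'   convention). The initial orientation is taken from the first valid
#'   accelerometer sample's gravity direction with yaw 0. Gaps up to
#'   `cfg$max_gap_bridge` seconds are bridged by holding the last angular
#'   rate; longer gaps are held at constant orientation and stay masked.
#' @export
estimate_orientation <- function(imu, cfg = ahrs_config()) {
  stopifnot(inherits(imu, "imu_recording"))
  acc <- imu$acc$data
  om <- imu$gyro$omega * pi / 180
  gap <- imu$acc$gap
  n <- nrow(acc)
  dt <- 1 / imu$fs
  gain <- cfg$accel_gain
  g <- cfg$gravity
  maxbridge <- round(cfg$max_gap_bridge * imu$fs)

  first <- which(!gap)[1]
  if (is.na(first)) stop("recording contains no valid samples")
  q <- matrix(NA_real_, n, 4)
  iw <- which(!gap & seq_len(n) <= first + round(cfg$init_window * imu$fs))
  f0 <- if (length(iw) > 1) colMeans(acc[iw, , drop = FALSE]) else acc[first, ]
  cur <- as.numeric(init_from_gravity(f0))
  q[seq_len(first), ] <- rep(cur, each = first)
  lastom <- c(0, 0, 0)
  gaplen <- 0L
  for (k in (first + 1):n) {
    if (k > n) break
    isgap <- gap[k]
    o <- if (isgap) { gaplen <- gaplen + 1L; if (gaplen <= maxbridge) lastom else c(0, 0, 0) }
         else { gaplen <- 0L; lastom <- om[k, ]; om[k, ] }
    # gyro prediction: q <- normalize(q + 0.5 q (0,o) dt)
    w <- cur[1]; x <- cur[2]; y <- cur[3]; z <- cur[4]
    nw <- w - 0.5 * dt * (x * o[1] + y * o[2] + z * o[3])
    nx <- x + 0.5 * dt * (w * o[1] + y * o[3] - z * o[2])
    ny <- y + 0.5 * dt * (w * o[2] - x * o[3] + z * o[1])
    nz <- z + 0.5 * dt * (w * o[3] + x * o[2] - y * o[1])
    nn <- sqrt(nw * nw + nx * nx + ny * ny + nz * nz)
    cur <- c(nw, nx, ny, nz) / nn
    if (!isgap && gain > 0) {
      f <- acc[k, ]
      fmag <- sqrt(sum(f^2))
      if (fmag > cfg$freefall_g * g) {
        # predicted gravity direction in body frame: q (0,0,1) q*
        w <- cur[1]; x <- cur[2]; y <- cur[3]; z <- cur[4]
        gp <- c(2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x * x + y * y))
        fm <- f / fmag
        ax <- c(gp[2] * fm[3] - gp[3] * fm[2],
                gp[3] * fm[1] - gp[1] * fm[3],
                gp[1] * fm[2] - gp[2] * fm[1])
        s <- sqrt(sum(ax^2))
        if (s > 1e-12) {
          ang <- gain * atan2(s, max(-1, min(1, sum(gp * fm))))
          dq <- c(cos(ang / 2), sin(ang / 2) * ax / s)
          # body-side correction: cur <- dq* applied so that predicted gravity
          # rotates toward the measured direction: q_new = dq_body x q? We
          # require q_new (0,0,1) q_new* moved toward fm, with rotation about
          # an axis perpendicular to gravity (yaw preserved):
          cur <- as.numeric(quat_multiply(quat(dq), quat(cur)))
          cur <- cur / sqrt(sum(cur^2))
        }
      }
    }
    q[k, ] <- cur
  }
  quat_signal(q, imu$fs, imu$t0, gap = gap)
}

#' Rotate body-frame acceleration into the navigation frame
#'
#' Expresses the measured specific force in the gravity-aligned navigation
#' frame (z up) and subtracts gravity, leaving motion acceleration.
#'
#' @param imu An [imu_recording()].
#' @param qsig Orientation [quat_signal()] on the same time base (e.g. from
#'   [estimate_orientation()]).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return 3-channel `gait_ts` of motion acceleration in m/s^2, z positive up.
#' @export
rotate_to_navigation <- function(imu, qsig, gravity = 9.81) {
  stopifnot(inherits(imu, "imu_recording"), inherits(qsig, "quat_signal"))
  if (nrow(qsig$q) != nrow(imu$acc$data)) stop("orientation and IMU lengths differ")
  nav <- quat_rotate(quat_conjugate(qsig$q), imu$acc$data)
  nav[, 3] <- nav[, 3] - gravity
  gap <- imu$acc$gap | qsig$gap
  nav[gap, ] <- NA_real_
  gait_ts(nav, imu$fs, imu$t0, gap = gap, units = "m/s^2")
}
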