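#' Kinematic gait simulator with ground truth
#'
#' Generates paired IMU and OMC-like recordings of an idealized horse trial
#' by prescribing limb and upper-body kinematics directly (no force model —
#' the processing pipeline consumes kinematics only): cannon-bone sagittal
#' swing with a quiet mid-stance plateau and the configured protraction /
#' retraction angles reached exactly at the hoof events, an outward coronal
#' swing-phase hump, and a two-harmonic per-stride upper-body vertical
#' displacement whose peak/trough differences can be set to inject a known
#' asymmetry. Gyroscope signals are obtained by differentiating the truth
#' orientation (so integration recovers it exactly), accelerometers measure
#' the rotated gravity plus motion acceleration plus hoof impact / toe-off
#' transients, and the OMC stream is the same motion expressed in a different
#' (rotated) frame, delayed by a known lag and degraded with position noise
#' and random occlusion gaps. Everything is deterministic under the
#' configured seed.
#'
#' @name synthetic_gait
NULL

#' Gait configuration
#'
#' Defaults represent straight-line walk and trot in hand; the derived
#' drift-removal cutoffs (2/3 of stride frequency) fall at 0.57 Hz (walk) and
#' 0.87 Hz (trot), inside the ranges typical of the two gaits.
#'
#' @param gait `"walk"` or `"trot"` (selects the defaults below).
#' @param stride_freq Strides per second.
#' @param duty_factor Stance fraction of the stride.
#' @param protraction,retraction Sagittal angles (deg) reached exactly at
#'   hoof-on / hoof-off.
#' @param coronal_amp Peak outward (abduction) coronal angle during swing, deg.
#' @param vert_amp Named vector of upper-body vertical peak-to-peak
#'   displacement per location, mm.
#' @param asymmetry List with `max_diff_mm`, `min_diff_mm` and `locations`
#'   (which upper-body locations receive the injected asymmetry).
#' @param n_strides Number of complete strides.
#' @param timing_cv Stride-to-stride timing variability (coefficient of
#'   variation of stride duration, from a smooth seeded phase modulation).
#'   Natural gait is only quasi-periodic; this is also what makes the
#'   cross-correlation lag between the two systems identifiable beyond one
#'   stride period.
#' @param heading Constant heading (yaw) of the horse, deg.
#' @return List of class `gait_config`.
#' @export
gait_config <- function(gait = c("walk", "trot"),
                        stride_freq = NULL, duty_factor = NULL,
                        protraction = NULL, retraction = NULL,
                        coronal_amp = NULL, vert_amp = NULL,
                        asymmetry = list(max_diff_mm = 0, min_diff_mm = 0,
                                         locations = "sacrum"),
                        n_strides = 12, timing_cv = 0.02, heading = 0) {
  gait <- match.arg(gait)
  def <- if (gait == "walk") {
    list(stride_freq = 0.85, duty_factor = 0.62, protraction = 22,
         retraction = -23, coronal_amp = 4,
         vert_amp = c(withers = 35, sacrum = 40, sternum = 30))
  } else {
    list(stride_freq = 1.3, duty_factor = 0.42, protraction = 28,
         retraction = -29, coronal_amp = 5,
         vert_amp = c(withers = 55, sacrum = 60, sternum = 45))
  }
  cfg <- list(
    gait = gait,
    stride_freq = stride_freq %||% def$stride_freq,
    duty_factor = duty_factor %||% def$duty_factor,
    protraction = protraction %||% def$protraction,
    retraction = retraction %||% def$retraction,
    coronal_amp = coronal_amp %||% def$coronal_amp,
    vert_amp = vert_amp %||% def$vert_amp,
    asymmetry = utils::modifyList(list(max_diff_mm = 0, min_diff_mm = 0,
                                       locations = "sacrum"), asymmetry),
    n_strides = n_strides, timing_cv = timing_cv, heading = heading
  )
  stopifnot(cfg$duty_factor > 0, cfg$duty_factor < 1, cfg$stride_freq > 0,
            cfg$coronal_amp >= 0, all(cfg$vert_amp >= 0))
  if (cfg$coronal_amp > abs(cfg$protraction)) {
    warning("coronal amplitude exceeds protraction; configuration is atypical")
  }
  structure(cfg, class = "gait_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sensor configuration
#'
#' @param sample_rate Hz (IMU and OMC alike).
#' @param gyro_noise_sd White gyroscope noise, deg/s per axis.
#' @param gyro_bias Constant residual gyroscope bias after calibration,
#'   deg/s (length 3). The default is the small residual of a
#'   factory-calibrated MEMS gyroscope; note that with the orientation
#'   filter's accelerometer gain of 1e-4 at 200 Hz the steady-state tilt
#'   error is about 50 times the bias (in degrees per deg/s of bias), so
#'   large uncalibrated biases are not a supported operating point.
#' @param acc_noise_sd White accelerometer noise, m/s^2 per axis.
#' @param impact_acc,toeoff_acc Amplitudes (m/s^2) of the hoof-impact and
#'   toe-off transients on the limb accelerometers; 40 ms raised-cosine pulses.
#' @param omc_pos_noise_sd Optical marker position noise, mm (the relative
#'   precision of a calibrated optical setup).
#' @param omc_quat_noise_deg Optical rigid-body orientation noise, deg.
#' @param omc_gap_rate Marker-occlusion gaps per minute.
#' @param omc_gap_len Mean occlusion length, samples.
#' @param lag Time offset of the OMC recording relative to the IMU clock, s
#'   (positive = OMC stream delayed).
#' @param relative_rotation Fixed rotation between the IMU sensor frame and
#'   the OMC rigid-body frame, as the unit quaternion `q` such that the OMC
#'   angular velocity is `quat_rotate(q, w_imu)`.
#' @param gravity m/s^2.
#' @param seed Integer RNG seed; identical configurations yield bit-identical
#'   trials.
#' @return List of class `sensor_config`.
#' @export
sensor_config <- function(sample_rate = 200, gyro_noise_sd = 0.5,
                          gyro_bias = c(0.02, -0.015, 0.01), acc_noise_sd = 0.05,
                          impact_acc = 12, toeoff_acc = 8,
                          omc_pos_noise_sd = 1.9, omc_quat_noise_deg = 0.05,
                          omc_gap_rate = 2, omc_gap_len = 10,
                          lag = 0.7315,
                          relative_rotation = from_axis_angle(c(1, 2, 3) / sqrt(14), 0.35),
                          gravity = 9.81, seed = 1L) {
  stopifnot(sample_rate > 0, gyro_noise_sd >= 0, acc_noise_sd >= 0,
            omc_pos_noise_sd >= 0, omc_gap_rate >= 0)
  structure(list(sample_rate = sample_rate, gyro_noise_sd = gyro_noise_sd,
                 gyro_bias = gyro_bias, acc_noise_sd = acc_noise_sd,
                 impact_acc = impact_acc, toeoff_acc = toeoff_acc,
                 omc_pos_noise_sd = omc_pos_noise_sd,
                 omc_quat_noise_deg = omc_quat_noise_deg,
                 omc_gap_rate = omc_gap_rate, omc_gap_len = omc_gap_len,
                 lag = lag, relative_rotation = quat(relative_rotation),
                 gravity = gravity, seed = as.integer(seed)),
            class = "sensor_config")
}

LIMBS <- c("LF", "RF", "LH", "RH")
UPPER <- c("withers", "sacrum", "sternum")

limb_phases <- function(gait) {
  if (gait == "trot") c(LF = 0, RF = 0.5, LH = 0.5, RH = 0) # diagonal pairs
  else c(LF = 0, RH = 0.25, RF = 0.5, LH = 0.75)            # four-beat walk
}

# C1 cosine ease from a to b over u in [0, 1]
ease <- function(u, a, b) a + (b - a) * (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

# sagittal cannon angle over stride phase u in [0, 1); stance = [0, duty)
sagittal_profile <- function(u, pro, ret, duty, ease_frac = 0.2) {
  e <- ease_frac * duty
  th <- numeric(length(u))
  s1 <- u < e                       # settle from protraction after hoof-on
  th[s1] <- ease(u[s1] / e, pro, 0)
  s3 <- u >= duty - e & u < duty    # rotate out to retraction before hoof-off
  th[s3] <- ease((u[s3] - (duty - e)) / e, 0, ret)
  sw <- u >= duty                   # swing arc retraction -> protraction
  th[sw] <- ease((u[sw] - duty) / (1 - duty), ret, pro)
  th                                # mid-stance plateau stays 0
}

# outward coronal hump during swing (zero through stance)
coronal_profile <- function(u, amp, duty) {
  th <- numeric(length(u))
  sw <- u >= duty
  v <- (u[sw] - duty) / (1 - duty)
  th[sw] <- amp * sin(pi * v)^2
  th
}

# two-harmonic vertical displacement (mm) over stride angle theta = 2*pi*phase;
# phase0 places the troughs near 13% and 63% of the stride (about the two
# diagonal mid-stances, where the trunk is lowest) and keeps every extremum
# well inside the stride window. Peaks sit at
# eta = pi/2 and 3pi/2 with values +-(pp/2 + max_diff/2), troughs at eta = 0
# and pi with values -pp/2 +- min_diff/2, so the configured peak and trough
# differences are realized exactly when only one of them is nonzero.
vert_profile <- function(theta, pp_amp, max_diff, min_diff, phase0 = 1.6) {
  eta <- theta - phase0 / 2
  -(pp_amp / 2) * cos(2 * eta) +
    (min_diff / 2) * cos(eta) + (max_diff / 2) * sin(eta)
}

qz_deg <- function(a) from_axis_angle(c(0, 0, 1), a * pi / 180)
qx_deg <- function(a) from_axis_angle(c(1, 0, 0), a * pi / 180)

# truth orientation rows for vectors of sagittal/coronal angles (deg):
# q = qy(+-theta_c) x qx(-theta_s) x qz(-heading), global-to-body passive.
# The coronal sign is mirrored between body sides so that "outward" tilt is
# positive on either side (matching the analysis-side axis mirroring).
compose_limb_quats <- function(theta_s, theta_c, heading, left) {
  sgn <- if (left) 1 else -1
  hs <- -theta_s * pi / 360               # half-angle of qx(-theta_s)
  hc <- sgn * theta_c * pi / 360          # half-angle of qy(+-theta_c)
  qy <- cbind(cos(hc), 0, sin(hc), 0)
  qx <- cbind(cos(hs), sin(hs), 0, 0)
  q <- quat_multiply(quat(qy), quat(qx))
  if (abs(heading) > 1e-12) {
    q <- quat_multiply(q, from_axis_angle(c(0, 0, 1), -heading * pi / 180))
  }
  q
}

small_rot_quats <- function(n, sd_deg) {
  v <- matrix(stats::rnorm(3 * n, 0, sd_deg * pi / 180), n, 3)
  ang <- sqrt(rowSums(v^2))
  ax <- v / pmax(ang, 1e-12)
  quat(cbind(cos(ang / 2), ax * sin(ang / 2)))
}

random_gap_mask <- function(n, fs, rate_per_min, mean_len) {
  mask <- rep(FALSE, n)
  k <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (k > 0) {
    starts <- sample.int(n, k, replace = TRUE)
    lens <- pmax(1, stats::rpois(k, mean_len))
    for (i in seq_len(k)) {
      mask[starts[i]:min(n, starts[i] + lens[i] - 1)] <- TRUE
    }
  }
  mask
}

raised_cos_pulse <- function(t, centers, amp, width) {
  out <- numeric(length(t))
  for (tc in centers) {
    idx <- which(abs(t - tc) < width / 2)
    out[idx] <- out[idx] + amp * 0.5 * (1 + cos(2 * pi * (t[idx] - tc) / width))
  }
  out
}

#' Simulate a paired IMU / OMC trial
#'
#' @param g A [gait_config()].
#' @param s A [sensor_config()].
#' @return Object of class `synthetic_trial`: `imu` (named list of
#'   [imu_recording()]s per location), `omc` (per limb: `pos` mm and `quat`;
#'   per upper-body location: `pos`), and `truth` (orientations, limb-angle
#'   signals, hoof events, vertical displacement and acceleration, per-stride
#'   extrema, lag, relative rotation, configs).
#' @export
simulate_trial <- function(g = gait_config(), s = sensor_config()) {
  stopifnot(inherits(g, "gait_config"), inherits(s, "sensor_config"))
  set.seed(s$seed)
  fs <- s$sample_rate
  Ts <- 1 / g$stride_freq
  dur <- (g$n_strides + 3) * Ts
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  phases <- limb_phases(g$gait)

  # smooth seeded phase modulation: Phi(t) = t/Ts + W(t) counts strides;
  # scaled so stride durations vary with the configured CV
  nw <- 4
  wf <- stats::runif(nw, 0.03, 0.12)
  wp <- stats::runif(nw, 0, 2 * pi)
  wc <- stats::rnorm(nw)
  sdWp <- sqrt(sum((wc * 2 * pi * wf)^2) / 2)
  wc <- if (sdWp > 0) wc * (g$timing_cv / Ts) / sdWp else wc * 0
  Phi <- function(tt) tt / Ts + colSums(wc * sin(outer(2 * pi * wf, tt) +
                                                   wp))
  # event times: invert Phi (monotone for small modulation) on a fine grid
  tg <- seq(-2 * Ts - abs(s$lag), dur + 2 * Ts, by = 1 / (4 * fs))
  Pg <- Phi(tg)
  phi_inv <- function(targets) stats::approx(Pg, tg, xout = targets)$y

  limb_events <- list()
  imu <- list()
  truth_orient <- list()
  truth_angles <- list()
  omc <- list()
  g_vec <- c(0, 0, s$gravity)

  eval_limb <- function(tt, limb) {
    u <- (Phi(tt) - 1 - phases[[limb]]) %% 1
    list(
      sag = sagittal_profile(u, g$protraction, g$retraction, g$duty_factor),
      cor = coronal_profile(u, g$coronal_amp, g$duty_factor)
    )
  }

  for (limb in LIMBS) {
    ons <- phi_inv(1 + phases[[limb]] + (-1:(g$n_strides + 1)))
    offs <- phi_inv(1 + phases[[limb]] + g$duty_factor + (-1:(g$n_strides + 1)))
    ons <- ons[!is.na(ons) & ons >= 0 & ons <= dur]
    offs <- offs[!is.na(offs) & offs >= 0 & offs <= dur]
    limb_events[[limb]] <- stride_set(limb, ons, offs)

    ang <- eval_limb(t, limb)
    qtrue <- compose_limb_quats(ang$sag, ang$cor, g$heading,
                                left = limb %in% c("LF", "LH"))
    qs_true <- quat_signal(qtrue, fs, 0)
    truth_orient[[limb]] <- qs_true
    truth_angles[[limb]] <- data.frame(time = t, sagittal = ang$sag,
                                       coronal = ang$cor)

    om_ideal <- differentiate_quats(qs_true)
    om_noisy <- om_ideal$omega +
      matrix(rep(s$gyro_bias, each = n), n, 3) +
      matrix(stats::rnorm(3 * n, 0, s$gyro_noise_sd), n, 3)
    gyro <- angvel_signal(om_noisy, fs, 0)

    f_b <- quat_rotate(qs_true$q, matrix(g_vec, n, 3, byrow = TRUE))
    pulse <- raised_cos_pulse(t, ons, s$impact_acc, 0.04) +
      raised_cos_pulse(t, offs, s$toeoff_acc, 0.04)
    f_b[, 3] <- f_b[, 3] + pulse
    f_b <- f_b + matrix(stats::rnorm(3 * n, 0, s$acc_noise_sd), n, 3)
    acc <- gait_ts(f_b, fs, 0, units = "m/s^2")
    imu[[limb]] <- imu_recording(acc, gyro, limb)

    # OMC rigid body: same motion at t - lag, re-axed by the relative rotation
    ang_o <- eval_limb(t - s$lag, limb)
    q_omc <- compose_limb_quats(ang_o$sag, ang_o$cor, g$heading,
                                left = limb %in% c("LF", "LH"))
    q_omc <- quat_multiply(quat_multiply(qz_deg(40), q_omc),
                           quat_conjugate(s$relative_rotation))
    q_omc <- quat_multiply(q_omc, quat_conjugate(small_rot_quats(n, s$omc_quat_noise_deg)))
    gapm <- random_gap_mask(n, fs, s$omc_gap_rate, s$omc_gap_len)
    q_omc[gapm, ] <- NA_real_
    pos <- cbind(1000 * (t - s$lag), 80 * sin(2 * pi * Phi(t - s$lag)),
                 120 + 15 * sin(2 * pi * Phi(t - s$lag))) +
      matrix(stats::rnorm(3 * n, 0, s$omc_pos_noise_sd), n, 3)
    pos[gapm, ] <- NA_real_
    omc[[limb]] <- list(pos = gait_ts(pos, fs, 0, units = "mm"),
                        quat = quat_signal(q_omc, fs, 0, gap = gapm))
  }

  # upper-body locations
  truth_vdisp <- list()
  truth_vacc <- list()
  truth_extrema <- list()
  ref_strides <- limb_events[["LF"]]
  for (loc in UPPER) {
    amp <- g$vert_amp[[loc]]
    asym_here <- loc %in% g$asymmetry$locations
    md <- if (asym_here) g$asymmetry$max_diff_mm else 0
    mnd <- if (asym_here) g$asymmetry$min_diff_mm else 0
    dfun <- function(tt) {
      vert_profile(2 * pi * (Phi(tt) - 1 - phases[["LF"]]), amp, md, mnd)
    }
    d <- dfun(t)                                    # mm
    h <- 1e-4
    a_z <- (dfun(t + h) - 2 * d + dfun(t - h)) / h^2 / 1000  # m/s^2
    truth_vdisp[[loc]] <- gait_ts(d, fs, 0, units = "mm")
    truth_vacc[[loc]] <- gait_ts(a_z, fs, 0, units = "m/s^2")

    # small twice-per-stride tilt so orientation estimation is exercised
    th2 <- 2 * pi * (Phi(t) - 1 - phases[["LF"]])
    p1 <- 2.5 * sin(2 * th2)
    p2 <- 1.5 * sin(2 * th2 + 1.1)
    hx <- -p1 * pi / 360; hy <- -p2 * pi / 360
    q_ub <- quat_multiply(quat(cbind(cos(hy), 0, sin(hy), 0)),
                          quat(cbind(cos(hx), sin(hx), 0, 0)))
    qs_ub <- quat_signal(q_ub, fs, 0)
    om_ub <- differentiate_quats(qs_ub)$omega +
      matrix(rep(s$gyro_bias, each = n), n, 3) +
      matrix(stats::rnorm(3 * n, 0, s$gyro_noise_sd), n, 3)
    a_nav <- cbind(0.5 * sin(th2 + 0.4), 0.3 * sin(th2 + 2.0), a_z)
    f_b <- quat_rotate(q_ub, sweep(a_nav, 2, g_vec, "+")) +
      matrix(stats::rnorm(3 * n, 0, s$acc_noise_sd), n, 3)
    imu[[loc]] <- imu_recording(gait_ts(f_b, fs, 0, units = "m/s^2"),
                                angvel_signal(om_ub, fs, 0), loc)
    truth_orient[[loc]] <- qs_ub

    gapm <- random_gap_mask(n, fs, s$omc_gap_rate, s$omc_gap_len)
    pos <- cbind(1000 * (t - s$lag), 40 * sin(pi * Phi(t - s$lag)),
                 1500 + dfun(t - s$lag)) +
      matrix(stats::rnorm(3 * n, 0, s$omc_pos_noise_sd), n, 3)
    pos[gapm, ] <- NA_real_
    omc[[loc]] <- list(pos = gait_ts(pos, fs, 0, units = "mm"))

    # analytic per-stride extrema on a dense phase grid
    sdf <- ref_strides$strides
    th_grid <- seq(0, 2 * pi, length.out = 20001)[-20001]
    dd <- vert_profile(th_grid, amp, md, mnd)
    pk <- find_peaks(dd, min_prominence = 0.1 * diff(range(dd)))
    tr <- find_peaks(-dd, min_prominence = 0.1 * diff(range(dd)))
    pk <- sort(pk[order(dd[pk], decreasing = TRUE)[1:2]])
    tr <- sort(tr[order(dd[tr])[1:2]])
    next_of <- function(from, cand) {
      after <- cand[cand > from]
      if (length(after)) after[1] else cand[1]
    }
    row1 <- data.frame(
      max1 = dd[pk[1]], max2 = dd[pk[2]], min1 = dd[tr[1]], min2 = dd[tr[2]],
      range_up1 = dd[next_of(tr[1], pk)] - dd[tr[1]],
      range_up2 = dd[next_of(tr[2], pk)] - dd[tr[2]],
      range_down1 = dd[pk[1]] - dd[next_of(pk[1], tr)],
      range_down2 = dd[pk[2]] - dd[next_of(pk[2], tr)],
      flagged = FALSE)
    ex <- cbind(stride = seq_len(nrow(sdf)),
                row1[rep(1L, nrow(sdf)), , drop = FALSE])
    rownames(ex) <- NULL
    class(ex) <- c("stride_extrema_set", "data.frame")
    truth_extrema[[loc]] <- ex
  }

  structure(list(
    imu = imu,
    omc = omc,
    truth = list(orientation = truth_orient, limb_angles = truth_angles,
                 events = limb_events, vdisp = truth_vdisp, vacc = truth_vacc,
                 stride_extrema = truth_extrema,
                 lag = s$lag, relative_rotation = s$relative_rotation,
                 ref_limb = "LF"),
    gait_config = g, sensor_config = s,
    fs = fs, duration = dur
  ), class = "synthetic_trial")
}

#' @exportS3Method base::print
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %s, %d strides @ %g Hz, %.1f s, seed %d\n",
              x$gait_config$gait, x$gait_config$n_strides, x$fs, x$duration,
              x$sensor_config$seed))
  invisible(x)
}

#' Ground-truth parameter tables for a synthetic trial
#'
#' @param trial A [simulate_trial()] result.
#' @return List with `limb` (per-stride true protraction, retraction,
#'   abduction, adduction and ROMs per limb) and `symmetry` (per-stride true
#'   symmetry parameters per upper-body location).
#' @export
truth_parameters <- function(trial) {
  stopifnot(inherits(trial, "synthetic_trial"))
  g <- trial$gait_config
  limb_tab <- do.call(rbind, lapply(LIMBS, function(limb) {
    ns <- nrow(trial$truth$events[[limb]]$strides)
    data.frame(limb = limb, stride = seq_len(ns),
               protraction = g$protraction, retraction = g$retraction,
               abduction = g$coronal_amp, adduction = 0,
               sagittal_rom = abs(g$protraction - g$retraction),
               coronal_rom = g$coronal_amp)
  }))
  sym_tab <- do.call(rbind, lapply(UPPER, function(loc) {
    sp <- symmetry_parameters(trial$truth$stride_extrema[[loc]])
    cbind(location = loc, as.data.frame(sp))
  }))
  list(limb = limb_tab, symmetry = sym_tab)
}
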