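#' End-to-end gait processing
#'
#' `process_trial()` runs the full chain on one trial: orientation
#' estimation, hoof-event detection on the limb sensors, swing-twist limb
#' angles, cyclic integration of upper-body vertical acceleration,
#' stride-frequency-tuned drift removal and per-stride symmetry parameters.
#' If an OMC stream is present the two systems are synchronized by
#' angular-velocity correlation, rotationally aligned with the Kabsch
#' algorithm, and the same parameters are extracted from the optical data
#' using the IMU-derived stride timing, yielding per-stride paired
#' measurements for agreement analysis. [agreement_report()] pools paired
#' measurements (typically over several subjects) into Bland-Altman / ICC
#' summary tables at per-stride and trial-mean level.
#'
#' @name pipeline
NULL

lowpass_angvel <- function(av, cutoff, order) {
  ts3 <- gait_ts(av$omega, av$fs, av$t0, gap = av$gap, units = "deg/s")
  f <- lowpass_denoise(ts3, cutoff = cutoff, order = order)
  angvel_signal(f$data, av$fs, av$t0, gap = av$gap)
}

pick_channel <- function(sig, j, units = NULL) {
  gait_ts(sig$data[, j], sig$fs, sig$t0, gap = sig$gap,
          units = units %||% sig$units)
}

#' Process one trial
#'
#' @param imu Named list of [imu_recording()]s (limbs `LF, RF, LH, RH` and
#'   upper-body locations), e.g. `simulate_trial(...)$imu` or a read bundle.
#' @param omc Optional named list of OMC streams (per limb: `pos` + `quat`;
#'   per upper-body location: `pos`), on the same sample rate.
#' @param config A [pipeline_config()].
#' @param subject,trial_id Labels attached to the paired output rows.
#' @param gait Optional gait label attached to the output.
#' @param verbose Log per-stage progress to stderr.
#' @return Object of class `gait_pipeline`: stride events, limb-angle
#'   signals and per-stride parameters (both systems where available),
#'   per-stride symmetry results, sync/alignment reports, per-sample
#'   displacement residuals, and `paired` long-format tables ready for
#'   [agreement_report()].
#' @export
process_trial <- function(imu, omc = NULL, config = pipeline_config(),
                          subject = "S1", trial_id = "T1", gait = NA_character_,
                          verbose = FALSE) {
  if (inherits(imu, "synthetic_trial")) {
    if (is.null(omc)) omc <- imu$omc
    gait <- imu$gait_config$gait
    imu <- imu$imu
  }
  say <- function(...) if (verbose) message(sprintf(...))
  limbs <- intersect(c("LF", "RF", "LH", "RH"), names(imu))
  uppers <- intersect(config$upper_locations, names(imu))
  if (!length(limbs)) stop("no limb recordings present")

  detector <- hoof_detector_quiet_gyro(
    omega_threshold = config$events$omega_threshold,
    min_stance = config$events$min_stance,
    lowpass_cutoff = config$events$lowpass_cutoff,
    refine_window = config$events$refine_window,
    acc_prominence = config$events$acc_prominence)

  say("stage: hoof events")
  events <- lapply(imu[limbs], detect_hoof_events, detector = detector)
  ref_limb <- if (config$ref_limb %in% limbs) config$ref_limb else limbs[1]
  ref_strides <- events[[ref_limb]]

  say("stage: orientation")
  acfg <- ahrs_config(accel_gain = config$ahrs$accel_gain,
                      gravity = config$ahrs$gravity)
  orient <- lapply(imu[c(limbs, uppers)], estimate_orientation, cfg = acfg)

  say("stage: limb angles (IMU)")
  angles_imu <- lapply(limbs, function(lb) {
    limb_angle_signals(orient[[lb]], events[[lb]],
                       lowpass_cutoff = config$lowpass$cutoff)
  })
  names(angles_imu) <- limbs
  params_imu <- lapply(limbs, function(lb) {
    extract_limb_parameters(angles_imu[[lb]], events[[lb]])
  })
  names(params_imu) <- limbs

  say("stage: upper-body displacement (IMU)")
  vdisp_imu <- list()
  for (loc in uppers) {
    nav <- rotate_to_navigation(imu[[loc]], orient[[loc]],
                                gravity = config$ahrs$gravity)
    az <- pick_channel(nav, 3, units = "m/s^2")
    vdisp_imu[[loc]] <- cyclic_integrate(az, ref_strides)
  }
  stride_freq <- if (length(uppers)) {
    sf_loc <- if (config$stride_freq_location %in% uppers) {
      config$stride_freq_location
    } else uppers[1]
    estimate_stride_frequency(
      lowpass_denoise(vdisp_imu[[sf_loc]], cutoff = config$lowpass$cutoff,
                      order = config$lowpass$order))
  } else {
    # no upper-body sensor: fall back to the reference limb's stride timing
    1 / stats::median(ref_strides$strides$duration)
  }
  say("stride frequency: %.3f Hz", stride_freq)
  sym_imu <- list()
  for (loc in uppers) {
    v <- highpass_drift_removal(vdisp_imu[[loc]], stride_freq,
                                order = config$highpass$order)
    v <- lowpass_denoise(v, cutoff = config$lowpass$cutoff,
                         order = config$lowpass$order)
    vdisp_imu[[loc]] <- v
    sym_imu[[loc]] <- trim_edge_strides(
      symmetry_parameters(stride_extrema(v, ref_strides)),
      ref_strides, v, stride_freq, config$trim_strides)
  }

  sync <- NULL; alignment <- NULL; params_omc <- NULL
  sym_omc <- NULL; residuals <- NULL; vdisp_omc <- NULL; angles_omc <- NULL
  if (!is.null(omc)) {
    say("stage: time synchronization")
    omc_limbs <- intersect(limbs, names(omc))
    sync_limb <- if (ref_limb %in% omc_limbs) ref_limb else omc_limbs[1]
    if (!is.null(sync_limb) && !is.null(omc[[sync_limb]]$quat)) {
      mag_imu <- lowpass_denoise(angvel_magnitude(imu[[sync_limb]]$gyro),
                                 cutoff = config$lowpass$cutoff)
      om_omc <- differentiate_quats(omc[[sync_limb]]$quat)
      mag_omc <- lowpass_denoise(angvel_magnitude(om_omc),
                                 cutoff = config$lowpass$cutoff)
      sync <- estimate_lag(mag_imu, mag_omc, max_lag = config$sync$max_lag)
      say("lag: %.4f s (corr %.3f)", sync$lag, sync$peak_corr)

      say("stage: rotational alignment + limb angles (OMC)")
      alignment <- list(); angles_omc <- list(); params_omc <- list()
      for (lb in omc_limbs) {
        if (is.null(omc[[lb]]$quat)) next
        q_sync <- resample_to_lag(omc[[lb]]$quat, sync$lag)
        om_sync <- differentiate_quats(q_sync)
        om_imu_f <- lowpass_angvel(imu[[lb]]$gyro, config$lowpass$cutoff,
                                   config$lowpass$order)
        om_omc_f <- lowpass_angvel(om_sync, config$lowpass$cutoff,
                                   config$lowpass$order)
        mask <- variance_exclusion_mask(
          angvel_magnitude(om_imu_f), angvel_magnitude(om_omc_f),
          threshold = config$alignment$variance_threshold,
          window = config$alignment$variance_window)
        if (mean(mask) > 0.9) {
          # broadband optical noise puts every window above the fixed
          # threshold; fall back to excluding the worst-disagreeing quartile
          mask <- variance_exclusion_mask(
            angvel_magnitude(om_imu_f), angvel_magnitude(om_omc_f),
            threshold = NULL, window = config$alignment$variance_window)
        }
        alignment[[lb]] <- tryCatch(
          kabsch_align(om_imu_f, om_omc_f, mask),
          error = function(e) { warning(conditionMessage(e)); NULL })
        a <- limb_angle_signals(q_sync, events[[lb]],
                                lowpass_cutoff = config$lowpass$cutoff)
        angles_omc[[lb]] <- a
        params_omc[[lb]] <- extract_limb_parameters(a, events[[lb]])
      }
    }
    say("stage: upper-body displacement (OMC)")
    sym_omc <- list(); residuals <- list(); vdisp_omc <- list()
    for (loc in intersect(uppers, names(omc))) {
      z <- pick_channel(omc[[loc]]$pos, 3, units = "mm")
      if (!is.null(sync)) z <- resample_to_lag(z, sync$lag)
      z$data[, 1] <- z$data[, 1] - mean(z$data[!z$gap, 1])
      v <- highpass_drift_removal(z, stride_freq, order = config$highpass$order)
      v <- lowpass_denoise(v, cutoff = config$lowpass$cutoff,
                           order = config$lowpass$order)
      vdisp_omc[[loc]] <- v
      sym_omc[[loc]] <- trim_edge_strides(
        symmetry_parameters(stride_extrema(v, ref_strides)),
        ref_strides, v, stride_freq, config$trim_strides)
      residuals[[loc]] <- tryCatch(residual_stats(vdisp_imu[[loc]], v),
                                   error = function(e) NULL)
    }
  }

  paired <- build_paired(params_imu, params_omc, sym_imu, sym_omc,
                         subject, trial_id, gait)
  structure(list(
    events = events, ref_limb = ref_limb, stride_freq = stride_freq,
    orientation = orient,
    angles_imu = angles_imu, params_imu = params_imu,
    angles_omc = angles_omc, params_omc = params_omc,
    vdisp_imu = vdisp_imu, vdisp_omc = vdisp_omc,
    sym_imu = sym_imu, sym_omc = sym_omc,
    sync = sync, alignment = alignment, residuals = residuals,
    paired = paired,
    subject = subject, trial_id = trial_id, gait = gait, config = config
  ), class = "gait_pipeline")
}

# drop strides whose window lies within k stride periods of a filter segment
# edge (recording boundary or long dropout): the drift-removal high-pass needs
# about one stride to settle after each edge
trim_edge_strides <- function(sym, strides, vdisp, stride_freq, k) {
  if (k <= 0 || !nrow(sym)) return(sym)
  margin <- k / stride_freq
  fs <- vdisp$fs
  longgap <- rep(FALSE, length(vdisp$gap))
  runs <- logical_runs(vdisp$gap)
  if (nrow(runs)) {
    long <- runs[runs[, 2] - runs[, 1] + 1 >= round(0.25 * fs), , drop = FALSE]
    for (r in seq_len(nrow(long))) longgap[long[r, 1]:long[r, 2]] <- TRUE
  }
  edge_t <- ts_time(vdisp)[longgap]
  t_lo <- vdisp$t0
  t_hi <- vdisp$t0 + (length(vdisp) - 1) / fs
  sdf <- strides$strides
  keep <- vapply(sym$stride, function(i) {
    a <- sdf$on[i] - margin
    b <- sdf$next_on[i] + margin
    a >= t_lo && b <= t_hi && !any(edge_t >= a & edge_t <= b)
  }, logical(1))
  sym[keep, , drop = FALSE]
}

LIMB_PARAMS <- c("protraction", "retraction", "abduction", "adduction",
                 "sagittal_rom", "coronal_rom")
SYM_PARAMS <- c("min_diff", "max_diff", "range_diff_up", "range_diff_down",
                "si_up", "si_down")

build_paired <- function(params_imu, params_omc, sym_imu, sym_omc,
                         subject, trial_id, gait) {
  rows <- list()
  if (!is.null(params_omc)) {
    for (lb in names(params_omc)) {
      a <- params_imu[[lb]]; b <- params_omc[[lb]]
      if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) next
      common <- intersect(a$stride, b$stride)
      a <- a[match(common, a$stride), ]; b <- b[match(common, b$stride), ]
      for (p in LIMB_PARAMS) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject, trial = trial_id, gait = gait,
          group = lb, parameter = p, stride = common,
          value_imu = a[[p]], value_omc = b[[p]])
      }
    }
  }
  if (!is.null(sym_omc)) {
    for (loc in names(sym_omc)) {
      a <- sym_imu[[loc]]; b <- sym_omc[[loc]]
      if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) next
      common <- intersect(a$stride, b$stride)
      a <- a[match(common, a$stride), ]; b <- b[match(common, b$stride), ]
      for (p in SYM_PARAMS) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject, trial = trial_id, gait = gait,
          group = loc, parameter = p, stride = common,
          value_imu = a[[p]], value_omc = b[[p]])
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' @exportS3Method base::print
print.gait_pipeline <- function(x, ...) {
  cat(sprintf("<gait_pipeline> subject %s trial %s (%s)\n", x$subject,
              x$trial_id, x$gait))
  cat(sprintf("  reference limb %s, %d strides, stride frequency %.3f Hz\n",
              x$ref_limb, nrow(x$events[[x$ref_limb]]$strides), x$stride_freq))
  if (!is.null(x$sync)) {
    cat(sprintf("  sync lag %.4f s (corr %.3f)\n", x$sync$lag, x$sync$peak_corr))
  }
  if (!is.null(x$paired)) {
    cat(sprintf("  %d paired per-stride measurements\n", nrow(x$paired)))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.gait_pipeline <- function(object, ...) {
  x <- object
  print(x)
  for (lb in names(x$params_imu)) {
    p <- x$params_imu[[lb]]
    if (!nrow(p)) next
    cat(sprintf("  %s: protraction %6.2f deg, retraction %7.2f deg, sag ROM %6.2f deg (IMU, stride means)\n",
                lb, mean(p$protraction), mean(p$retraction), mean(p$sagittal_rom)))
  }
  for (loc in names(x$sym_imu)) {
    s <- x$sym_imu[[loc]]
    if (!nrow(s)) next
    cat(sprintf("  %s: max_diff %6.2f mm, min_diff %6.2f mm, SI_up %6.3f (IMU, stride means)\n",
                loc, mean(s$max_diff, na.rm = TRUE), mean(s$min_diff, na.rm = TRUE),
                mean(s$si_up, na.rm = TRUE)))
  }
  invisible(x)
}

#' Agreement tables from pooled paired measurements
#'
#' Summarizes per-stride paired measurements (typically pooled over several
#' subjects and trials) into one row per (gait, group, parameter, level):
#' Bland-Altman bias with its confidence interval, upper and lower limits of
#' agreement, and the ICC from a subject-grouped random-intercept model, at
#' per-stride and trial-mean levels.
#'
#' @param paired Long-format data frame as produced in
#'   `process_trial()$paired` (columns `subject`, `trial`, `gait`, `group`,
#'   `parameter`, `stride`, `value_imu`, `value_omc`); rows from several
#'   trials can simply be `rbind`-ed.
#' @param conf Confidence level.
#' @param loa_mult LOA multiplier.
#' @param icc_mode Response mode for [icc_mixed()].
#' @return Data frame of class `agreement_table` with columns `gait`,
#'   `group`, `parameter`, `level`, `n`, `bias`, `bias_lo`, `bias_hi`,
#'   `loa_lower`, `loa_upper`, `icc`.
#' @export
agreement_report <- function(paired, conf = 0.95, loa_mult = 1.96,
                             icc_mode = "raw") {
  stopifnot(is.data.frame(paired))
  out <- list()
  for (gt in unique(paired$gait)) {
    pg <- paired[paired$gait %in% gt, ]
    for (grp in unique(pg$group)) {
      for (p in unique(pg$parameter)) {
        sub <- pg[pg$group == grp & pg$parameter == p, ]
        sub <- sub[stats::complete.cases(sub[, c("value_imu", "value_omc")]), ]
        if (nrow(sub) < 3) next
        pm <- suppressWarnings(paired_measurements(
          sub$value_imu, sub$value_omc, subject = sub$subject,
          trial = sub$trial, stride = sub$stride))
        icc <- tryCatch(icc_mixed(pm, mode = icc_mode)$icc,
                        error = function(e) NA_real_)
        for (lev in c("per_stride", "trial_mean")) {
          ba <- tryCatch(suppressWarnings(
            bland_altman(pm, level = lev, conf = conf, loa_mult = loa_mult)),
            error = function(e) NULL)
          if (is.null(ba)) next
          out[[length(out) + 1]] <- data.frame(
            gait = gt, group = grp, parameter = p, level = lev, n = ba$n,
            bias = ba$bias, bias_lo = ba$loa_ci$bias[1],
            bias_hi = ba$loa_ci$bias[2],
            loa_lower = ba$loa_lower, loa_upper = ba$loa_upper, icc = icc)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("agreement_table", "data.frame")
  res
}

#' Write an agreement table (or any report) as JSON
#'
#' @param x An `agreement_table` (or any data frame / list).
#' @param path Output file path.
#' @export
write_agreement_json <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
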