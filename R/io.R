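#' Columnar text file formats
#'
#' All recordings are exchanged as plain tab-separated text with a fixed
#' header; missing samples (e.g. occluded optical frames) are empty fields
#' and become gap-masked placeholder samples on load, so the time base stays
#' uniform. A trial bundle is a directory with one file per sensor location
#' plus a YAML manifest declaring locations, sample rates and units.
#'
#' @name io_formats
NULL

IMU_HEADER <- c("time_s", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
OMC_HEADER_POS <- c("time_s", "pos_x_mm", "pos_y_mm", "pos_z_mm")
OMC_HEADER_QUAT <- c(OMC_HEADER_POS, c("qw", "qx", "qy", "qz"))

check_uniform_time <- function(tm, path) {
  dt <- diff(tm)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6) {
    stop(sprintf("%s: non-uniform time base (jitter %.3g s)", path, max(dt) - min(dt)))
  }
  1 / stats::median(dt)
}

read_columnar <- function(path, header) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "numeric", na.strings = c("", "NA"))
  missing_cols <- setdiff(header, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df[, header, drop = FALSE]
}

#' Read / write an IMU recording
#'
#' File format: tab-separated columns `time_s, acc_x, acc_y, acc_z
#' (m/s^2), gyro_x, gyro_y, gyro_z (deg/s)`; missing samples as empty fields.
#'
#' @param path File path.
#' @param location Sensor location label.
#' @return `read_imu` returns an [imu_recording()].
#' @export
read_imu <- function(path, location = "sacrum") {
  df <- read_columnar(path, IMU_HEADER)
  fs <- check_uniform_time(df$time_s, path)
  acc <- as.matrix(df[, c("acc_x", "acc_y", "acc_z")])
  gyr <- as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")])
  gap <- rowSums(is.na(acc)) > 0 | rowSums(is.na(gyr)) > 0
  imu_recording(gait_ts(acc, fs, df$time_s[1], gap = gap, units = "m/s^2"),
                angvel_signal(gyr, fs, df$time_s[1], gap = gap),
                location)
}

#' @rdname read_imu
#' @param imu An [imu_recording()].
#' @param digits Numeric precision written.
#' @export
write_imu <- function(imu, path, digits = 9) {
  df <- data.frame(time_s = ts_time(imu$acc),
                   acc_x = imu$acc$data[, 1], acc_y = imu$acc$data[, 2],
                   acc_z = imu$acc$data[, 3],
                   gyro_x = imu$gyro$omega[, 1], gyro_y = imu$gyro$omega[, 2],
                   gyro_z = imu$gyro$omega[, 3])
  df[imu$acc$gap, -1] <- NA
  write_columnar(df, path, digits)
}

write_columnar <- function(df, path, digits) {
  df[, -1] <- lapply(df[, -1, drop = FALSE], function(x) signif(x, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write an OMC stream
#'
#' File format: tab-separated columns `time_s, pos_x_mm, pos_y_mm, pos_z_mm`
#' and optionally `qw, qx, qy, qz` (rigid-body orientation); occluded frames
#' as empty fields. Quaternions are renormalized and made sign-continuous on
#' load; a norm deviating more than 0.01 from 1 is an error.
#'
#' @param path File path.
#' @return `read_omc` returns a list with `pos` (`gait_ts`, mm) and `quat`
#'   (a [quat_signal()] or NULL).
#' @export
read_omc <- function(path) {
  first <- readLines(path, n = 1)
  has_quat <- grepl("\\bqw\\b", first)
  df <- read_columnar(path, if (has_quat) OMC_HEADER_QUAT else OMC_HEADER_POS)
  fs <- check_uniform_time(df$time_s, path)
  pos <- as.matrix(df[, c("pos_x_mm", "pos_y_mm", "pos_z_mm")])
  gap <- rowSums(is.na(pos)) > 0
  out <- list(pos = gait_ts(pos, fs, df$time_s[1], gap = gap, units = "mm"),
              quat = NULL)
  if (has_quat) {
    q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
    qgap <- rowSums(is.na(q)) > 0
    nrm <- sqrt(rowSums(q[!qgap, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 0.01)) {
      stop(sprintf("%s: quaternion norm deviates more than 0.01 from 1", path))
    }
    out$quat <- quat_signal(q, fs, df$time_s[1], gap = qgap)
  }
  out
}

#' @rdname read_omc
#' @param omc List with `pos` (`gait_ts`, mm) and optional `quat`
#'   ([quat_signal()]).
#' @param digits Numeric precision written.
#' @export
write_omc <- function(omc, path, digits = 9) {
  df <- data.frame(time_s = ts_time(omc$pos),
                   pos_x_mm = omc$pos$data[, 1], pos_y_mm = omc$pos$data[, 2],
                   pos_z_mm = omc$pos$data[, 3])
  gap <- omc$pos$gap
  if (!is.null(omc$quat)) {
    df$qw <- omc$quat$q[, 1]; df$qx <- omc$quat$q[, 2]
    df$qy <- omc$quat$q[, 3]; df$qz <- omc$quat$q[, 4]
    gap <- gap | omc$quat$gap
  }
  df[gap, -1] <- NA
  write_columnar(df, path, digits)
}

#' Write / read a synthetic trial as a trial bundle
#'
#' A bundle directory contains `manifest.yaml`, `imu_<location>.tsv` per IMU,
#' and `omc_<location>.tsv` per optical stream.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Bundle directory (created if needed).
#' @return `write_trial_bundle` returns `dir`; `read_trial_bundle` returns a
#'   list with `imu`, `omc` and `manifest`.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    sample_rate = trial$fs,
    gait = trial$gait_config$gait,
    units = list(acc = "m/s^2", gyro = "deg/s", pos = "mm"),
    imu_locations = names(trial$imu),
    omc_locations = names(trial$omc)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (loc in names(trial$imu)) {
    write_imu(trial$imu[[loc]], file.path(dir, paste0("imu_", loc, ".tsv")))
  }
  for (loc in names(trial$omc)) {
    write_omc(trial$omc[[loc]], file.path(dir, paste0("omc_", loc, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_trial_bundle
#' @export
read_trial_bundle <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  imu <- lapply(manifest$imu_locations, function(loc) {
    read_imu(file.path(dir, paste0("imu_", loc, ".tsv")), loc)
  })
  names(imu) <- manifest$imu_locations
  omc <- lapply(manifest$omc_locations, function(loc) {
    read_omc(file.path(dir, paste0("omc_", loc, ".tsv")))
  })
  names(omc) <- manifest$omc_locations
  list(imu = imu, omc = omc, manifest = manifest)
}
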