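#' Hoof-event detection and stride segmentation
#'
#' Strides are delimited by successive hoof-on events of one limb; each stride
#' splits into a stance phase (hoof-on to hoof-off) and a swing phase
#' (hoof-off to the next hoof-on). The detector shipped here is a documented
#' baseline operating on limb-mounted cannon-bone sensors: stance candidates
#' are contiguous regions where the low-pass-filtered angular-velocity
#' magnitude stays below a threshold for a minimum duration; the region
#' boundaries are then refined to the nearest acceleration-magnitude
#' transients (hoof impact before the quiet region, toe-off push after it).
#' The detector is pluggable: any function mapping an [imu_recording()] to a
#' two-column data frame of event times can be substituted.
#'
#' @name stride_events
NULL

#' Stride set constructor
#'
#' @param limb Limb label.
#' @param hoof_on,hoof_off Sorted event times, s. Events must alternate
#'   on < off < next on.
#' @return Object of class `stride_set`: the event vectors plus a `strides`
#'   data frame with columns `on`, `off`, `next_on`, `stance`, `swing`,
#'   `duration`, `midstance`.
#' @export
stride_set <- function(limb, hoof_on, hoof_off) {
  hoof_on <- sort(hoof_on)
  hoof_off <- sort(hoof_off)
  strides <- NULL
  for (i in seq_along(hoof_on)) {
    off <- hoof_off[hoof_off > hoof_on[i]][1]
    nxt <- hoof_on[hoof_on > hoof_on[i]][1]
    if (is.na(off) || is.na(nxt) || off >= nxt) next
    strides <- rbind(strides, c(hoof_on[i], off, nxt))
  }
  if (is.null(strides)) {
    strides <- matrix(numeric(0), ncol = 3)
  }
  strides <- as.data.frame(strides)
  names(strides) <- c("on", "off", "next_on")
  strides$stance <- strides$off - strides$on
  strides$swing <- strides$next_on - strides$off
  strides$duration <- strides$next_on - strides$on
  strides$midstance <- strides$on + 0.5 * strides$stance
  if (nrow(strides) && any(strides$stance <= 0 | strides$swing <= 0)) {
    stop("hoof events do not alternate (on < off < next on)")
  }
  structure(list(limb = limb, hoof_on = hoof_on, hoof_off = hoof_off,
                 strides = strides),
            class = "stride_set")
}

#' @exportS3Method base::print
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %s: %d strides (%d on / %d off events)\n",
              x$limb, nrow(x$strides), length(x$hoof_on), length(x$hoof_off)))
  if (nrow(x$strides)) {
    cat(sprintf("  mean stride %.3f s (stance %.3f, swing %.3f)\n",
                mean(x$strides$duration), mean(x$strides$stance),
                mean(x$strides$swing)))
  }
  invisible(x)
}

#' Baseline quiet-gyro hoof-event detector
#'
#' Returns a detector function for use with [detect_hoof_events()].
#'
#' @param omega_threshold Stance threshold on the low-pass-filtered
#'   angular-velocity magnitude, deg/s.
#' @param min_stance Minimum stance duration, s.
#' @param lowpass_cutoff Cutoff for pre-smoothing the magnitude signal, Hz.
#' @param refine_window Search window (s) for the acceleration-transient
#'   refinement of each region boundary; set to 0 to disable refinement.
#' @param acc_prominence Minimum prominence (m/s^2) for an acceleration peak
#'   to be accepted as an impact/toe-off transient.
#' @return A function `(imu) -> data.frame(event, time)` with event in
#'   `c("hoof_on", "hoof_off")`.
#' @export
hoof_detector_quiet_gyro <- function(omega_threshold = 20, min_stance = 0.08,
                                     lowpass_cutoff = 15, refine_window = 0.2,
                                     acc_prominence = 3) {
  force(omega_threshold); force(min_stance); force(lowpass_cutoff)
  force(refine_window); force(acc_prominence)
  function(imu) {
    mag <- angvel_magnitude(imu$gyro)
    mag <- lowpass_denoise(mag, cutoff = lowpass_cutoff)
    m <- mag$data[, 1]
    m[mag$gap] <- Inf  # a gap cannot count as stance
    quiet <- logical_runs(m < omega_threshold)
    if (!nrow(quiet)) return(data.frame(event = character(0), time = numeric(0)))
    minlen <- round(min_stance * imu$fs)
    quiet <- quiet[quiet[, 2] - quiet[, 1] + 1 >= minlen, , drop = FALSE]
    # stance regions too close to the recording boundaries cannot be
    # delimited (no room for the transient search / the events lie outside)
    w <- round(refine_window * imu$fs)
    quiet <- quiet[quiet[, 1] > 1 + w & quiet[, 2] < length(m) - w, , drop = FALSE]
    if (!nrow(quiet)) return(data.frame(event = character(0), time = numeric(0)))
    accmag <- sqrt(rowSums(imu$acc$data^2))
    accmag[imu$acc$gap] <- NA
    tt <- ts_time(imu$acc)
    ons <- offs <- numeric(nrow(quiet))
    for (r in seq_len(nrow(quiet))) {
      i1 <- quiet[r, 1]; i2 <- quiet[r, 2]
      on_i <- i1
      if (w > 0) {
        lo <- max(1, i1 - w)
        pk <- find_peaks(accmag[lo:i1], min_prominence = acc_prominence)
        if (length(pk)) on_i <- lo + pk[length(pk)] - 1  # nearest preceding peak
      }
      off_i <- i2
      if (w > 0) {
        hi <- min(length(accmag), i2 + w)
        pk <- find_peaks(accmag[i2:hi], min_prominence = acc_prominence)
        if (length(pk)) off_i <- i2 + pk[1] - 1  # nearest following peak
      }
      ons[r] <- tt[on_i]; offs[r] <- tt[off_i]
    }
    data.frame(event = rep(c("hoof_on", "hoof_off"), each = length(ons)),
               time = c(ons, offs))
  }
}

#' Detect hoof events on a limb recording
#'
#' @param imu A limb-mounted [imu_recording()].
#' @param detector A detector function, by default
#'   [hoof_detector_quiet_gyro()] with its default settings.
#' @return A [stride_set()]. Fewer than 2 complete strides is an error.
#' @export
detect_hoof_events <- function(imu, detector = hoof_detector_quiet_gyro()) {
  stopifnot(inherits(imu, "imu_recording"))
  ev <- detector(imu)
  ss <- stride_set(imu$location,
                   hoof_on = ev$time[ev$event == "hoof_on"],
                   hoof_off = ev$time[ev$event == "hoof_off"])
  if (nrow(ss$strides) < 2) {
    stop(sprintf("fewer than 2 complete strides detected on %s", imu$location))
  }
  ss
}

#' Mid-stance time of a stride
#'
#' Half-way through the stance phase, snapped to the nearest sample instant of
#' the supplied time base so that both measurement systems reference the
#' identical sample.
#'
#' @param stride One row of a `stride_set$strides` data frame (or any list
#'   with `on` and `off`).
#' @param fs Sample rate used for snapping, Hz (NULL = no snapping).
#' @param t0 Time-base origin, s.
#' @return Mid-stance time, s.
#' @export
midstance_time <- function(stride, fs = NULL, t0 = 0) {
  tm <- stride$on + 0.5 * (stride$off - stride$on)
  if (!is.null(fs)) tm <- t0 + round((tm - t0) * fs) / fs
  tm
}

#' Write hoof events as a tab-separated table
#'
#' @param ss A [stride_set()].
#' @param path Output file path.
#' @export
write_events <- function(ss, path) {
  df <- data.frame(
    limb = ss$limb,
    event_type = rep(c("hoof_on", "hoof_off"),
                     c(length(ss$hoof_on), length(ss$hoof_off))),
    time_s = c(ss$hoof_on, ss$hoof_off)
  )
  df <- df[order(df$time_s), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
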