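#' Zero-phase Butterworth filtering
#'
#' All filtering in the pipeline is zero-phase (forward-backward) so that
#' group delay cannot bias the time synchronization or event timing. Edge
#' transients are suppressed by odd-reflection padding before the
#' forward-backward pass. Gaps shorter than `max_interp_gap` (default 0.25 s,
#' i.e. ordinary marker-occlusion dropouts) are spline-interpolated before
#' filtering and remain flagged in the gap mask — they carry no information
#' but must not be allowed to split the signal, because every split edge
#' re-excites the filter transient, which for a drift-removal high-pass
#' tuned below 1 Hz contaminates about a stride on either side. Longer
#' dropouts do split the signal into independently filtered segments.
#'
#' @name filtering
NULL

# forward-backward IIR filter with odd-reflection padding. A constant
# settle block ahead of each pass lets the zero-state filter reach the
# steady state for the edge value before it meets real data, which removes
# the start-up transient that zero initial conditions would inject.
zero_phase_filter <- function(x, b, a, padlen, settle = 256L) {
  n <- length(x)
  p <- min(n - 1, padlen)
  if (p < 1) stop("signal too short for zero-phase filtering")
  front <- 2 * x[1] - x[(p + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - p)]
  xe <- c(rep(front[1], settle), front, x, back, rep(back[p], settle))
  y <- as.numeric(signal::filter(b, a, xe))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(settle + p + 1):(settle + p + n)]
}

butter_coefs <- function(order, cutoff, fs, type) {
  ny <- fs / 2
  if (cutoff <= 0 || cutoff >= ny) {
    stop(sprintf("cutoff %.3g Hz outside (0, Nyquist = %g Hz)", cutoff, ny))
  }
  bt <- signal::butter(order, cutoff / ny, type = type)
  list(b = bt$b, a = bt$a)
}

# apply a scalar filter function per channel, honouring the gap policy
filter_with_gaps <- function(sig, fun, min_len, max_interp_gap = NULL) {
  stopifnot(inherits(sig, "gait_ts"))
  if (is.null(max_interp_gap)) max_interp_gap <- round(0.25 * sig$fs)
  x <- sig$data
  gap <- sig$gap
  out <- x
  # linear interpolation of short gaps
  runs <- logical_runs(gap)
  longgap <- rep(FALSE, length(gap))
  if (nrow(runs)) {
    for (r in seq_len(nrow(runs))) {
      len <- runs[r, 2] - runs[r, 1] + 1
      if (len >= max_interp_gap ||
          runs[r, 1] == 1 || runs[r, 2] == length(gap)) {
        longgap[runs[r, 1]:runs[r, 2]] <- TRUE
      }
    }
    idx <- which(!longgap)
    for (j in seq_len(ncol(x))) {
      xin <- x[, j]
      fill <- which(gap & !longgap)
      if (length(fill)) {
        src <- which(!gap)
        xin[fill] <- stats::approx(src, xin[src], xout = fill)$y
      }
      out[, j] <- xin
    }
  }
  # filter each contiguous non-long-gap segment
  segs <- logical_runs(!longgap)
  for (s in seq_len(nrow(segs))) {
    i1 <- segs[s, 1]; i2 <- segs[s, 2]
    if (i2 - i1 + 1 < min_len) {
      stop(sprintf("segment of %d samples too short to filter (need >= %d)",
                   i2 - i1 + 1, min_len))
    }
    for (j in seq_len(ncol(x))) {
      out[i1:i2, j] <- fun(out[i1:i2, j])
    }
  }
  out[longgap, ] <- NA_real_
  gait_ts(out, sig$fs, sig$t0, gap = sig$gap, units = sig$units)
}

#' Low-pass noise filtering
#'
#' Fourth-order Butterworth low-pass (default cutoff 30 Hz, well above the
#' ~3-4 Hz content of gait signals at walk and trot), applied forward-backward
#' for zero phase. DC gain is 1.
#'
#' @param sig A [gait_ts()].
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order.
#' @return A filtered `gait_ts` with the same gap mask.
#' @export
lowpass_denoise <- function(sig, cutoff = 30, order = 4) {
  stopifnot(inherits(sig, "gait_ts"))
  if (sig$fs <= 2 * cutoff) {
    stop(sprintf("sample rate %g Hz too low for a %g Hz low-pass", sig$fs, cutoff))
  }
  co <- butter_coefs(order, cutoff, sig$fs, "low")
  padlen <- max(3 * order, ceiling(6 * sig$fs / cutoff))
  filter_with_gaps(sig, function(x) zero_phase_filter(x, co$b, co$a, padlen),
                   min_len = 3 * order + 1)
}

#' Stride frequency from a vertical-displacement signal
#'
#' The upper body oscillates twice per stride, so the stride frequency is the
#' reciprocal of twice the median interval between successive displacement
#' peaks.
#'
#' @param vdisp Vertical displacement `gait_ts` (single channel) containing at
#'   least 3 peaks.
#' @param min_prominence Minimum peak prominence, in signal units; defaults to
#'   20% of the signal range.
#' @return Stride frequency, Hz.
#' @export
estimate_stride_frequency <- function(vdisp, min_prominence = NULL) {
  stopifnot(inherits(vdisp, "gait_ts"), ncol(vdisp$data) == 1)
  x <- vdisp$data[, 1]
  x[vdisp$gap] <- NA
  if (is.null(min_prominence)) {
    min_prominence <- 0.2 * diff(range(x, na.rm = TRUE))
  }
  pk <- find_peaks(x, min_prominence = min_prominence)
  if (length(pk) < 3) stop("need at least 3 displacement peaks to estimate stride frequency")
  1 / (2 * stats::median(diff(pk)) / vdisp$fs)
}

#' Stride-frequency-tuned drift removal
#'
#' Fourth-order zero-phase Butterworth high-pass with cutoff at 2/3 of the
#' stride frequency, removing integration drift and floor-slope trends from a
#' vertical-displacement signal while passing the twice-per-stride content
#' unattenuated.
#'
#' @param vdisp Vertical displacement `gait_ts`.
#' @param stride_freq Stride frequency, Hz (> 0), typically from
#'   [estimate_stride_frequency()] at the sacrum.
#' @param order Filter order.
#' @return Filtered `gait_ts`.
#' @export
highpass_drift_removal <- function(vdisp, stride_freq, order = 4) {
  stopifnot(inherits(vdisp, "gait_ts"), stride_freq > 0)
  cutoff <- 2 / 3 * stride_freq
  co <- butter_coefs(order, cutoff, vdisp$fs, "high")
  padlen <- max(3 * order, ceiling(6 * vdisp$fs / cutoff))
  filter_with_gaps(vdisp, function(x) zero_phase_filter(x, co$b, co$a, padlen),
                   min_len = 3 * order + 1)
}

# local maxima with a prominence criterion; returns indices in temporal order
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  xi <- x
  xi[is.na(xi)] <- -Inf
  cand <- which(diff(sign(diff(xi))) < 0) + 1L
  cand <- cand[is.finite(x[cand])]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(xi, i), numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (min_distance > 1L && length(keep) > 1L) {
    ord <- order(promk, decreasing = TRUE)
    sel <- logical(length(keep))
    taken <- integer(0)
    for (i in ord) {
      if (!length(taken) || all(abs(keep[i] - taken) >= min_distance)) {
        sel[i] <- TRUE
        taken <- c(taken, keep[i])
      }
    }
    keep <- keep[sel]
  }
  sort(keep)
}

peak_prominence <- function(x, i) {
  n <- length(x)
  # walk left/right to the first strictly higher sample, tracking the minimum
  lmin <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  if (j < 1L) lmin <- min(x[1:i])
  rmin <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) {
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1L
  }
  if (j > n) rmin <- min(x[i:n])
  x[i] - max(lmin, rmin)
}
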