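#' Uniformly sampled time series
#'
#' Light container for uniformly sampled scalar or vector signals: an n-by-k
#' numeric matrix plus sample rate, absolute start time and a per-sample gap
#' mask (TRUE marks a placeholder sample, e.g. an occluded optical frame).
#'
#' @param data Numeric vector (scalar channel) or n-by-k matrix.
#' @param fs Sample rate, Hz.
#' @param t0 Absolute start time, s.
#' @param gap Logical gap mask; defaults to rows containing NA.
#' @param units Optional character label for the channel units.
#' @return An object of class `gait_ts`.
#' @export
gait_ts <- function(data, fs, t0 = 0, gap = NULL, units = NULL) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1)
  stopifnot(is.numeric(fs), fs > 0)
  if (is.null(gap)) gap <- rowSums(is.na(data)) > 0
  stopifnot(length(gap) == nrow(data))
  structure(list(data = data, fs = fs, t0 = t0, gap = as.logical(gap),
                 units = units),
            class = "gait_ts")
}

#' @exportS3Method base::print
print.gait_ts <- function(x, ...) {
  cat(sprintf("<gait_ts> %d samples x %d channel(s) @ %g Hz, t0 = %g s, %d gap(s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0, sum(x$gap),
              if (is.null(x$units)) "" else paste0(" [", x$units, "]")))
  invisible(x)
}

#' @export
length.gait_ts <- function(x) nrow(x$data)

#' Sample time stamps of a signal
#'
#' @param x A `gait_ts`, `quat_signal` or `angvel_signal`.
#' @return Numeric vector of absolute sample times, s.
#' @export
ts_time <- function(x) {
  n <- if (inherits(x, "gait_ts")) nrow(x$data)
       else if (inherits(x, "quat_signal")) nrow(x$q)
       else if (inherits(x, "angvel_signal")) nrow(x$omega)
       else stop("unsupported signal type")
  x$t0 + (seq_len(n) - 1) / x$fs
}

# nearest sample index for an absolute time (1-based)
ts_index <- function(x, t) {
  i <- round((t - x$t0) * x$fs) + 1
  pmin(pmax(i, 1L), length(x))
}

# contiguous runs of TRUE in a logical vector -> matrix [start, end]
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}
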