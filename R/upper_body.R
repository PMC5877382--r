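#' Upper-body vertical displacement and movement symmetry
#'
#' The upper body of a sound horse oscillates vertically twice per stride
#' (once per left and right step), giving two peaks and two troughs per
#' stride. Vertical displacement is obtained from navigation-frame vertical
#' acceleration by cyclic double integration: at each integration step the
#' mean over the previous, current and next stride is subtracted, which
#' removes the unbounded drift of naive integration. Per-stride differences
#' between the two peaks, the two troughs and the two upward/downward ranges
#' quantify left/right movement asymmetry.
#'
#' @name upper_body
NULL

cumtrapz1 <- function(x, fs) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) / fs
}

#' Cyclic double integration of vertical acceleration
#'
#' @param nav_acc_z Single-channel `gait_ts` of gravity-free navigation-frame
#'   vertical acceleration, m/s^2.
#' @param strides A [stride_set()] of the reference limb (>= 3 strides).
#' @return Single-channel `gait_ts` of vertical displacement in mm, covering
#'   the span of the stride set (samples outside it are gap-masked).
#' @export
cyclic_integrate <- function(nav_acc_z, strides) {
  stopifnot(inherits(nav_acc_z, "gait_ts"), ncol(nav_acc_z$data) == 1,
            inherits(strides, "stride_set"))
  sdf <- strides$strides
  if (nrow(sdf) < 3) stop("cyclic integration needs at least 3 strides")
  x <- nav_acc_z$data[, 1]
  gap <- nav_acc_z$gap
  if (any(gap)) {  # bridge gaps for integration; they stay masked in the output
    src <- which(!gap)
    x[gap] <- stats::approx(src, x[src], xout = which(gap), rule = 2)$y
  }
  fs <- nav_acc_z$fs
  n <- length(x)
  # stride windows as sample index ranges [on_i, next_on_i)
  w_lo <- ts_index(nav_acc_z, sdf$on)
  w_hi <- pmax(w_lo, ts_index(nav_acc_z, sdf$next_on) - 1L)
  ns <- nrow(sdf)
  # subtract the three-stride (previous/current/next) mean from the
  # integrand before each integration step; edge strides use the available
  # neighbours; the resulting displacement is not mean-subtracted again
  cyclic_demean <- function(sig) {
    out <- rep(NA_real_, n)
    for (i in seq_len(ns)) {
      nb <- max(1, i - 1):min(ns, i + 1)
      idx_nb <- unlist(lapply(nb, function(j) w_lo[j]:w_hi[j]))
      out[w_lo[i]:w_hi[i]] <- sig[w_lo[i]:w_hi[i]] - mean(sig[idx_nb])
    }
    out[is.na(out)] <- 0
    out
  }
  v <- cumtrapz1(cyclic_demean(x), fs)
  d <- cumtrapz1(cyclic_demean(v), fs)
  covered <- rep(FALSE, n)
  covered[w_lo[1]:w_hi[ns]] <- TRUE
  gait_ts(d * 1000, fs, nav_acc_z$t0, gap = gap | !covered, units = "mm")
}

#' Construct a per-stride extrema record
#'
#' Holds the two peaks, two troughs and the derived upward/downward ranges of
#' one stride of vertical displacement (all in mm). Any field may be left NA;
#' [symmetry_parameters()] uses whichever fields are present.
#'
#' @param max1,max2 Peak values in temporal order from stride start.
#' @param min1,min2 Trough values in temporal order.
#' @param range_up1,range_up2 Trough-to-next-peak amplitudes.
#' @param range_down1,range_down2 Peak-to-next-trough amplitudes.
#' @return One-row data frame of class `stride_extrema_set`.
#' @export
extrema_record <- function(max1 = NA, max2 = NA, min1 = NA, min2 = NA,
                           range_up1 = NA, range_up2 = NA,
                           range_down1 = NA, range_down2 = NA) {
  df <- data.frame(stride = 1L, max1 = max1, max2 = max2,
                   min1 = min1, min2 = min2,
                   range_up1 = range_up1, range_up2 = range_up2,
                   range_down1 = range_down1, range_down2 = range_down2,
                   flagged = FALSE)
  class(df) <- c("stride_extrema_set", "data.frame")
  df
}

#' Per-stride displacement extrema
#'
#' Within each stride window exactly two maxima and two minima are selected
#' (the two most prominent of each kind if noise produces more candidates, in
#' temporal order; `Max1` is the first peak after the stride start). Ranges
#' follow the alternation of peaks and troughs, treating the stride
#' cyclically: each trough pairs with the next peak (wrapping to the stride's
#' first peak) for the upward ranges, and each peak with the next trough for
#' the downward ranges. Strides without two clear peaks and troughs are
#' flagged and skipped.
#'
#' @param vdisp Single-channel `gait_ts` of vertical displacement (mm),
#'   already drift-removed ([highpass_drift_removal()]) and denoised.
#' @param strides A [stride_set()].
#' @param min_prominence Minimum extremum prominence, mm; defaults to 20% of
#'   the median within-stride displacement range (robust against filter edge
#'   transients outside the stride windows).
#' @return Data frame of class `stride_extrema_set`, one row per stride, with
#'   `flagged` marking skipped strides (their values are NA).
#' @export
stride_extrema <- function(vdisp, strides, min_prominence = NULL) {
  stopifnot(inherits(vdisp, "gait_ts"), ncol(vdisp$data) == 1,
            inherits(strides, "stride_set"))
  sdf <- strides$strides
  # gap samples that carry interpolated values keep them for the peak
  # geometry (an NA sentinel would distort prominences around every gap);
  # a masked sample can still never be selected as an extremum itself
  x <- vdisp$data[, 1]
  masked <- vdisp$gap | is.na(x)
  win <- function(i) {
    lo <- ts_index(vdisp, sdf$on[i])
    hi <- max(lo, ts_index(vdisp, sdf$next_on[i]) - 1L)
    c(lo, hi)
  }
  if (is.null(min_prominence)) {
    rngs <- vapply(seq_len(nrow(sdf)), function(i) {
      w <- win(i)
      diff(range(x[w[1]:w[2]], na.rm = TRUE))
    }, numeric(1))
    rngs <- rngs[is.finite(rngs)]
    min_prominence <- if (length(rngs)) 0.2 * stats::median(rngs) else 0
  }
  rows <- vector("list", nrow(sdf))
  for (i in seq_len(nrow(sdf))) {
    w <- win(i)
    lo <- w[1]; hi <- w[2]
    # prominence is evaluated with surrounding context so extrema close to a
    # stride boundary are not penalized by the window cut
    pad <- max(3L, round(0.15 * (hi - lo + 1)))
    clo <- max(1L, lo - pad); chi <- min(length(x), hi + pad)
    seg <- x[clo:chi]
    off <- lo - clo
    inwin <- function(p) {
      p <- p[p > off & p <= off + (hi - lo + 1)] - off
      p[!masked[lo + p - 1]]
    }
    pk <- inwin(find_peaks(seg, min_prominence = min_prominence))
    tr <- inwin(find_peaks(-seg, min_prominence = min_prominence))
    seg <- x[lo:hi]
    row <- data.frame(stride = i, max1 = NA_real_, max2 = NA_real_,
                      min1 = NA_real_, min2 = NA_real_,
                      range_up1 = NA_real_, range_up2 = NA_real_,
                      range_down1 = NA_real_, range_down2 = NA_real_,
                      flagged = TRUE)
    if (length(pk) >= 2 && length(tr) >= 2) {
      if (length(pk) > 2) {
        prom <- vapply(pk, function(j) peak_prominence(ifelse(is.na(seg), -Inf, seg), j), 0)
        pk <- sort(pk[order(prom, decreasing = TRUE)[1:2]])
      }
      if (length(tr) > 2) {
        prom <- vapply(tr, function(j) peak_prominence(ifelse(is.na(-seg), -Inf, -seg), j), 0)
        tr <- sort(tr[order(prom, decreasing = TRUE)[1:2]])
      }
      ext_i <- c(pk, tr)
      kind <- rep(c("max", "min"), each = 2)
      ord <- order(ext_i)
      if (all(kind[ord][-1] != kind[ord][-4])) {  # peaks and troughs alternate
        next_of <- function(from, cand) {
          after <- cand[cand > from]
          if (length(after)) after[1] else cand[1]  # cyclic wrap
        }
        row$max1 <- seg[pk[1]]; row$max2 <- seg[pk[2]]
        row$min1 <- seg[tr[1]]; row$min2 <- seg[tr[2]]
        row$range_up1 <- seg[next_of(tr[1], pk)] - seg[tr[1]]
        row$range_up2 <- seg[next_of(tr[2], pk)] - seg[tr[2]]
        row$range_down1 <- seg[pk[1]] - seg[next_of(pk[1], tr)]
        row$range_down2 <- seg[pk[2]] - seg[next_of(pk[2], tr)]
        row$flagged <- FALSE
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stride_extrema_set", "data.frame")
  out
}

si_index <- function(r1, r2) {
  out <- (r1 - r2) / pmax(r1, r2)
  out[!is.na(r1) & !is.na(r2) & r1 == 0 & r2 == 0] <- NA_real_
  out
}

#' Per-stride upper-body symmetry parameters
#'
#' Differences between the two peaks (`max_diff`), the two troughs
#' (`min_diff`) and the two upward/downward ranges (`range_diff_up/down`),
#' plus the normalized symmetry indices
#' `SI = (Range_1 - Range_2) / max(Range_1, Range_2)`: 0 indicates perfect
#' symmetry and +/-1 maximal asymmetry. SI is undefined (NA) when both
#' ranges are zero.
#'
#' @param e A `stride_extrema_set` (from [stride_extrema()] or
#'   [extrema_record()]).
#' @return Data frame of class `symmetry_result` with columns `stride`,
#'   `min_diff`, `max_diff`, `range_diff_up`, `range_diff_down` (mm) and
#'   `si_up`, `si_down` (dimensionless).
#' @export
symmetry_parameters <- function(e) {
  stopifnot(inherits(e, "stride_extrema_set"))
  out <- data.frame(
    stride = e$stride,
    min_diff = e$min1 - e$min2,
    max_diff = e$max1 - e$max2,
    range_diff_up = e$range_up1 - e$range_up2,
    range_diff_down = e$range_down1 - e$range_down2,
    si_up = si_index(e$range_up1, e$range_up2),
    si_down = si_index(e$range_down1, e$range_down2)
  )
  out <- out[!e$flagged, , drop = FALSE]
  class(out) <- c("symmetry_result", "data.frame")
  out
}

#' Write per-stride symmetry parameters as a tab-separated table
#'
#' @param sym A `symmetry_result`.
#' @param location Upper-body location label.
#' @param path Output file path.
#' @export
write_symmetry <- function(sym, location, path) {
  df <- data.frame(location = location, stride_index = sym$stride,
                   min_diff_mm = sym$min_diff, max_diff_mm = sym$max_diff,
                   range_diff_up_mm = sym$range_diff_up,
                   range_diff_down_mm = sym$range_diff_down,
                   si_up = sym$si_up, si_down = sym$si_down)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
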