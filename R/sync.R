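#' Cross-modality synchronization and rigid alignment
#'
#' An IMU stream and an optical motion capture (OMC) stream of the same trial
#' are aligned in two steps: (1) the time lag between the systems is found at
#' sub-sample resolution by maximizing the normalized correlation coefficient
#' between the angular-velocity magnitude signals of one limb, refined by
#' quadratic interpolation through the correlation peak; (2) the fixed
#' rotation between the two measurement frames is estimated with the Kabsch
#' algorithm on the paired 3D angular-velocity samples, after excluding
#' windows where the two magnitude signals disagree in variance (OMC
#' occlusion artifacts).
#'
#' @name sync_align
NULL

#' Angular-velocity magnitude
#'
#' Per-sample Euclidean norm of a 3D angular-velocity signal; invariant to
#' the relative orientation of the two systems, which is what makes it usable
#' for cross-system correlation.
#'
#' @param omega An [angvel_signal()].
#' @return A single-channel `gait_ts` in deg/s with the gap mask propagated.
#' @export
angvel_magnitude <- function(omega) {
  stopifnot(inherits(omega, "angvel_signal"))
  m <- sqrt(rowSums(omega$omega^2))
  gait_ts(m, omega$fs, omega$t0, gap = omega$gap, units = "deg/s")
}

# circular cross-correlation sums via FFT:
# returns function m -> sum_j f[j] g[j+m] for integer shifts m in [-maxm, maxm]
xcorr_sums <- function(f, g, maxm) {
  n <- length(f)
  L <- stats::nextn(n + maxm + 1, 2)
  F <- stats::fft(c(f, rep(0, L - n)))
  G <- stats::fft(c(g, rep(0, L - n)))
  cc <- Re(stats::fft(Conj(F) * G, inverse = TRUE)) / L
  # cc[m+1] holds shift m (0-based, wrapped)
  m <- -maxm:maxm
  cc[((m %% L)) + 1]
}

#' Estimate the time lag between two magnitude signals
#'
#' Finds the lag maximizing the normalized correlation coefficient between
#' `mag_a` and `mag_b` over their full overlap, excluding gap samples
#' pairwise, then refines the peak location by fitting a parabola through the
#' peak sample and its two neighbours. A positive lag means `mag_b` is
#' delayed relative to `mag_a`, i.e. `b(t) ~ a(t - lag)`.
#'
#' @param mag_a,mag_b Single-channel `gait_ts` at equal sample rates.
#' @param max_lag Largest absolute lag searched, s.
#' @param min_overlap_frac Candidate lags whose pairwise-valid overlap falls
#'   below this fraction of the best achievable overlap are not considered:
#'   on quasi-periodic gait signals a sliver of overlap can correlate
#'   spuriously well at a wrong multiple of the stride period.
#' @return Object of class `sync_result`: `lag` (s), `peak_corr`.
#' @export
estimate_lag <- function(mag_a, mag_b, max_lag = 30, min_overlap_frac = 0.5) {
  stopifnot(inherits(mag_a, "gait_ts"), inherits(mag_b, "gait_ts"))
  if (abs(mag_a$fs - mag_b$fs) > 1e-9) stop("signals must share a sample rate")
  fs <- mag_a$fs
  a <- mag_a$data[, 1]; b <- mag_b$data[, 1]
  va <- as.numeric(!mag_a$gap & is.finite(a))
  vb <- as.numeric(!mag_b$gap & is.finite(b))
  a[va == 0] <- 0; b[vb == 0] <- 0
  n <- max(length(a), length(b))
  pad <- function(x) c(x, rep(0, n - length(x)))
  a <- pad(a); va <- pad(va); b <- pad(b); vb <- pad(vb)
  maxm <- min(n - 1, round(max_lag * fs))
  N <- xcorr_sums(va, vb, maxm)
  Sa <- xcorr_sums(a * va, vb, maxm)
  Sb <- xcorr_sums(va, b * vb, maxm)
  Saa <- xcorr_sums(a^2 * va, vb, maxm)
  Sbb <- xcorr_sums(va, b^2 * vb, maxm)
  Sab <- xcorr_sums(a * va, b * vb, maxm)
  ok <- N >= max(16, min_overlap_frac * max(N))
  if (!any(ok)) stop("no usable overlap between the two signals")
  vara <- Saa - Sa^2 / N
  varb <- Sbb - Sb^2 / N
  r <- rep(-Inf, length(N))
  good <- ok & vara > 0 & varb > 0
  r[good] <- (Sab[good] - Sa[good] * Sb[good] / N[good]) /
    sqrt(vara[good] * varb[good])
  k <- which.max(r)
  mgrid <- -maxm:maxm
  peak_r <- r[k]
  delta <- 0
  if (k == 1L || k == length(r) || !is.finite(r[k - 1]) || !is.finite(r[k + 1])) {
    warning("correlation peak at search boundary; no sub-sample interpolation")
  } else {
    rm1 <- r[k - 1]; r0 <- r[k]; rp1 <- r[k + 1]
    den <- rm1 - 2 * r0 + rp1
    if (den < 0) {
      delta <- 0.5 * (rm1 - rp1) / den
      peak_r <- r0 - 0.25 * (rm1 - rp1) * delta
    }
  }
  lag <- (mgrid[k] + delta) / fs + (mag_b$t0 - mag_a$t0)
  peak_r <- max(-1, min(1, peak_r))
  if (peak_r < 0.5) warning(sprintf("low peak correlation (%.2f); sync may be unreliable", peak_r))
  structure(list(lag = lag, peak_corr = peak_r), class = "sync_result")
}

#' @exportS3Method base::print
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> lag = %.6f s, peak corr = %.3f\n",
              x$lag, x$peak_corr))
  invisible(x)
}

# Kaiser-windowed-sinc fractional delay: y[i] = x(i + shift) for sample shift
fractional_delay <- function(x, shift, halfwidth = 36L, beta = 12) {
  n <- length(x)
  si <- floor(shift)
  sf <- shift - si
  k <- -halfwidth:(halfwidth + 1L)
  u <- k - sf
  h <- ifelse(abs(u) >= halfwidth + 1, 0,
              sinc(u) * besselI(beta * sqrt(pmax(0, 1 - (u / (halfwidth + 1))^2)), 0) /
                besselI(beta, 0))
  h <- h / sum(h)
  # odd-reflection extension
  p <- halfwidth + abs(si) + 2L
  if (p >= n) p <- n - 1L
  xe <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- numeric(n)
  base <- p + si  # xe index offset so xe[base + i + k] = x[i + si + k]
  for (j in seq_along(k)) {
    idx <- base + seq_len(n) + k[j]
    idx <- pmin(pmax(idx, 1L), length(xe))
    y <- y + h[j] * xe[idx]
  }
  y
}

sinc <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))

#' Resample a signal to remove an estimated lag
#'
#' Shifts a signal forward in time by `lag` seconds onto its own time base:
#' the output at sample time `t` is the input evaluated at `t + lag`, so that
#' applying the lag returned by [estimate_lag()] to the delayed signal aligns
#' it with the reference. Integer-sample shifts are pure index shifts;
#' fractional shifts use Kaiser-windowed-sinc interpolation for `gait_ts`
#' inputs and spherical linear interpolation for `quat_signal` inputs.
#' Samples shifted in from beyond the recording are flagged as gaps.
#'
#' @param sig A `gait_ts` or `quat_signal`.
#' @param lag Time shift in seconds (positive advances the signal).
#' @return An object of the same class as `sig`.
#' @export
resample_to_lag <- function(sig, lag) {
  UseMethod("resample_to_lag")
}

#' @export
resample_to_lag.gait_ts <- function(sig, lag) {
  n <- nrow(sig$data)
  shift <- lag * sig$fs
  si <- round(shift)
  out <- sig$data
  gap <- sig$gap
  if (abs(shift - si) < 1e-9) {
    idx <- seq_len(n) + si
    inside <- idx >= 1 & idx <= n
    out[] <- NA_real_
    out[inside, ] <- sig$data[idx[inside], , drop = FALSE]
    newgap <- rep(TRUE, n)
    newgap[inside] <- gap[idx[inside]]
  } else {
    newgap <- rep(TRUE, n)
    idx <- seq_len(n) + si
    inside <- idx >= 1 & idx <= n
    newgap[inside] <- gap[pmin(pmax(idx[inside], 1L), n)]
    for (j in seq_len(ncol(out))) {
      x <- sig$data[, j]
      if (any(gap)) {  # bridge gaps so the kernel sees finite values
        src <- which(!gap)
        x[gap] <- stats::approx(src, x[src], xout = which(gap), rule = 2)$y
      }
      out[, j] <- fractional_delay(x, shift)
    }
    out[!inside, ] <- NA_real_
  }
  gait_ts(out, sig$fs, sig$t0, gap = newgap | rowSums(is.na(out)) > 0,
          units = sig$units)
}

#' @export
resample_to_lag.quat_signal <- function(sig, lag) {
  n <- nrow(sig$q)
  shift <- lag * sig$fs
  si <- floor(shift)
  sf <- shift - si
  if (abs(sf) < 1e-9 || abs(sf - 1) < 1e-9) {
    si <- round(shift); sf <- 0
  }
  idx_lo <- seq_len(n) + si
  idx_hi <- idx_lo + (sf > 0)
  inside <- idx_lo >= 1 & idx_hi <= n
  q <- matrix(NA_real_, n, 4)
  newgap <- rep(TRUE, n)
  ii <- which(inside)
  ii <- ii[!sig$gap[idx_lo[ii]] & !sig$gap[idx_hi[ii]]]
  if (length(ii)) {
    lo <- idx_lo[ii]; hi <- idx_hi[ii]
    if (sf == 0) {
      q[ii, ] <- sig$q[lo, , drop = FALSE]
    } else {
      q[ii, ] <- quat_slerp(sig$q[lo, , drop = FALSE], sig$q[hi, , drop = FALSE], sf)
    }
    newgap[ii] <- FALSE
  }
  quat_signal(q, sig$fs, sig$t0, gap = newgap | rowSums(is.na(q)) > 0)
}

#' Variance-gated exclusion mask for alignment
#'
#' Marks samples where the two synchronized angular-velocity magnitude signals
#' disagree in local variance, indicating occlusion artifacts in the optical
#' stream: excluded where `|var_w(a) - var_w(b)|` exceeds `threshold` over a
#' centred sliding window of `window` samples (partial windows at the edges
#' use the available samples). Gap samples are always excluded.
#'
#' @param mag_a,mag_b Single-channel `gait_ts`, already synchronized.
#' @param threshold Variance-difference threshold, (deg/s)^2. `NULL` selects
#'   the threshold adaptively as the `auto_quantile` quantile of the observed
#'   windowed variance differences (useful when both signals carry broadband
#'   noise that puts the absolute differences far above a fixed threshold
#'   everywhere; the worst-disagreeing windows are then excluded).
#' @param window Sliding-window length in samples.
#' @param auto_quantile Quantile used when `threshold = NULL`.
#' @return Logical vector, TRUE = excluded.
#' @export
variance_exclusion_mask <- function(mag_a, mag_b, threshold = 1e-3, window = 10L,
                                    auto_quantile = 0.75) {
  stopifnot(inherits(mag_a, "gait_ts"), inherits(mag_b, "gait_ts"))
  n <- min(nrow(mag_a$data), nrow(mag_b$data))
  a <- mag_a$data[seq_len(n), 1]
  b <- mag_b$data[seq_len(n), 1]
  va <- rolling_var(a, window)
  vb <- rolling_var(b, window)
  d <- abs(va - vb)
  if (is.null(threshold)) {
    threshold <- stats::quantile(d, auto_quantile, na.rm = TRUE, names = FALSE)
  }
  excl <- !is.na(d) & d > threshold
  excl | mag_a$gap[seq_len(n)] | mag_b$gap[seq_len(n)] | is.na(d)
}

rolling_var <- function(x, w) {
  n <- length(x)
  xz <- ifelse(is.na(x), 0, x)
  vz <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(xz))
  cs2 <- c(0, cumsum(xz^2))
  cn <- c(0, cumsum(vz))
  lo <- pmax(seq_len(n) - floor(w / 2), 1L)
  hi <- pmin(lo + w - 1L, n)
  lo <- pmax(hi - w + 1L, 1L)
  m <- cn[hi + 1] - cn[lo]
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  out <- (s2 - s^2 / m) / (m - 1)
  out[m < 2] <- NA_real_
  out
}

#' Kabsch rigid rotational alignment of paired angular velocities
#'
#' Least-squares rotation `R` minimizing `sum |R w_imu - w_omc|^2` over
#' non-excluded, per-time-instance paired samples: centroid subtraction,
#' covariance SVD, and determinant correction to guarantee a proper rotation.
#' The translation component (gyroscope bias) is reported but is not part of
#' the alignment.
#'
#' @param omega_imu,omega_omc Synchronized [angvel_signal()]s (deg/s).
#' @param mask Optional logical exclusion mask (TRUE = excluded), e.g. from
#'   [variance_exclusion_mask()].
#' @return Object of class `alignment_result`: `rotation` (unit quaternion
#'   `q` with `quat_rotate(q, w_imu) ~ w_omc`), `rotation_matrix`,
#'   `translation` (deg/s), `residual_rmsd` (deg/s), `excluded_fraction`,
#'   `n_pairs`.
#' @export
kabsch_align <- function(omega_imu, omega_omc, mask = NULL) {
  stopifnot(inherits(omega_imu, "angvel_signal"), inherits(omega_omc, "angvel_signal"))
  n <- min(nrow(omega_imu$omega), nrow(omega_omc$omega))
  A <- omega_imu$omega[seq_len(n), , drop = FALSE]
  B <- omega_omc$omega[seq_len(n), , drop = FALSE]
  valid <- !omega_imu$gap[seq_len(n)] & !omega_omc$gap[seq_len(n)] &
    stats::complete.cases(A) & stats::complete.cases(B)
  pairable <- sum(valid)
  if (!is.null(mask)) valid <- valid & !mask[seq_len(n)]
  if (sum(valid) < 100) stop("need at least 100 non-excluded paired samples")
  A <- A[valid, , drop = FALSE]
  B <- B[valid, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  if (sv$d[3] / sv$d[1] < 1e-10) {
    stop("angular-velocity samples are (near-)coplanar; rotation is not identifiable")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- Bc - Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(list(
    rotation = quat_from_matrix(R),
    rotation_matrix = R,
    translation = cb - as.numeric(R %*% ca),
    residual_rmsd = rmsd,
    excluded_fraction = 1 - sum(valid) / max(pairable, 1L),
    n_pairs = sum(valid)
  ), class = "alignment_result")
}

#' @exportS3Method base::print
print.alignment_result <- function(x, ...) {
  aa <- 2 * acos(min(1, abs(x$rotation[1, 1]))) * 180 / pi
  cat(sprintf("<alignment_result> rotation %.2f deg, residual RMSD %.3f deg/s, %d pairs (%.1f%% excluded)\n",
              aa, x$residual_rmsd, x$n_pairs, 100 * x$excluded_fraction))
  invisible(x)
}
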