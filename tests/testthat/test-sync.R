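fs <- 200

test_that("angular-velocity magnitude is the rotation-invariant norm", {
  om <- angvel_signal(rbind(c(0, 0, 0), c(3, 4, 0), c(1, 2, 2)), fs)
  m <- angvel_magnitude(om)
  expect_equal(m$data[, 1], c(0, 5, 3))
  set.seed(10)
  omr <- matrix(rnorm(300, 0, 50), 100, 3)
  for (i in 1:5) {
    q <- random_unit_quat()
    rot <- quat_rotate(quat(q), omr)
    expect_equal(sqrt(rowSums(rot^2)), sqrt(rowSums(omr^2)), tolerance = 1e-9)
  }
})

test_that("lag estimation recovers constructed shifts", {
  set.seed(11)
  sig <- bandlimited_signal()
  t <- (0:3999) / fs
  x <- sig(t)
  a <- gait_ts(x, fs)
  # identical signals
  s0 <- estimate_lag(a, a, max_lag = 2)
  expect_equal(s0$lag, 0, tolerance = 1e-9)
  expect_equal(s0$peak_corr, 1, tolerance = 1e-9)
  # shift of exactly 25 samples (head marked missing, not zero-filled)
  b <- gait_ts(c(rep(NA_real_, 25), x[1:(4000 - 25)]), fs)
  s25 <- estimate_lag(a, b, max_lag = 2)
  expect_equal(s25$lag, 0.125, tolerance = 2e-4)
  # fractional shift with noise at 20 dB SNR: better than 1 ms
  true_lag <- 12.3 / fs
  noise <- sd(x) / sqrt(100)
  an <- gait_ts(x + rnorm(4000, 0, noise), fs)
  bn <- gait_ts(sig(t - true_lag) + rnorm(4000, 0, noise), fs)
  sf <- estimate_lag(an, bn, max_lag = 1)
  expect_lt(abs(sf$lag - true_lag), 1e-3)
})

test_that("lag estimation is antisymmetric and honours gaps", {
  set.seed(12)
  sig <- bandlimited_signal()
  t <- (0:3999) / fs
  x <- sig(t); y <- sig(t - 7.4 / fs)
  a <- gait_ts(x, fs); b <- gait_ts(y, fs)
  s_ab <- estimate_lag(a, b, max_lag = 1)
  s_ba <- estimate_lag(b, a, max_lag = 1)
  expect_lt(abs(s_ab$lag + s_ba$lag), 1 / fs)
  # gap samples are excluded pairwise, not treated as zeros
  xg <- x; xg[500:700] <- NA
  ag <- gait_ts(xg, fs)
  sg <- estimate_lag(ag, b, max_lag = 1)
  expect_lt(abs(sg$lag - 7.4 / fs), 1e-3)
  expect_error(estimate_lag(gait_ts(rep(NA_real_, 100), fs), a), "overlap")
  # unrelated signals: the sync is flagged as unreliable
  set.seed(18)
  u <- gait_ts(rnorm(2000), fs); v <- gait_ts(rnorm(2000), fs)
  expect_warning(estimate_lag(u, v, max_lag = 1), "unreliable")
})

test_that("resampling to a lag shifts the time base as declared", {
  set.seed(13)
  sig <- bandlimited_signal()
  t <- (0:3999) / fs
  a <- gait_ts(sig(t), fs)
  # lag 0 is the identity
  expect_equal(resample_to_lag(a, 0)$data, a$data)
  # integer lags are pure index shifts, bit-identical in the interior
  r <- resample_to_lag(a, 10 / fs)
  expect_identical(r$data[1:(4000 - 10), 1], a$data[11:4000, 1])
  expect_true(all(r$gap[3991:4000]))
  # fractional round trip returns within 1e-6 of the signal range
  d <- 0.0123
  y <- resample_to_lag(resample_to_lag(a, d), -d)
  rng <- diff(range(a$data))
  i <- 300:3700
  expect_lt(max(abs(y$data[i, 1] - a$data[i, 1])) / rng, 1e-6)
})

test_that("quaternion resampling slerps and renormalizes", {
  t <- (0:999) / fs
  qs <- quat_signal(cbind(cos(0.4 * sin(t)), sin(0.4 * sin(t)), 0, 0), fs)
  r <- resample_to_lag(qs, 3.5 / fs)
  ok <- !r$gap
  expect_equal(sqrt(rowSums(r$q[ok, ]^2)), rep(1, sum(ok)), tolerance = 1e-12)
  # against the analytic trajectory (the quaternion half-angle is 0.4 sin t)
  ang_expect <- 0.8 * sin(t + 3.5 / fs)
  ang_got <- 2 * atan2(r$q[, 2], r$q[, 1])
  expect_lt(max(abs(ang_got[ok] - ang_expect[ok])), 1e-4)
})

test_that("variance gate excludes optical spikes but not matched noise", {
  set.seed(14)
  n <- 2000
  ma <- gait_ts(rnorm(n, 0, sqrt(1e-5)), fs)
  mb <- gait_ts(rnorm(n, 0, sqrt(1e-5)), fs)
  expect_equal(variance_exclusion_mask(ma, ma), rep(FALSE, n))
  # independent white noise of equal tiny variance: almost nothing excluded
  expect_lt(mean(variance_exclusion_mask(ma, mb)), 0.05)
  # a 3-sample 50 deg/s spike contaminates at least 10 contiguous windows
  mb2 <- mb
  mb2$data[1000:1002, 1] <- mb2$data[1000:1002, 1] + 50
  mask <- variance_exclusion_mask(ma, mb2)
  runs <- equigait:::logical_runs(mask)
  expect_gte(max(runs[, 2] - runs[, 1] + 1), 10)
  expect_true(all(mask[998:1005]))
})

test_that("Kabsch alignment recovers exact, known and noisy rotations", {
  set.seed(15)
  n <- 1500
  om <- matrix(rnorm(3 * n, 0, 80), n, 3)
  a <- angvel_signal(om, fs)
  # identical signals -> identity rotation, zero residual
  al0 <- kabsch_align(a, a)
  expect_lt(quat_geodesic(al0$rotation, quat(c(1, 0, 0, 0))), 1e-10)
  expect_lt(al0$residual_rmsd, 1e-10)
  # known 40-degree rotation, noiseless
  qrel <- from_axis_angle(c(2, -1, 2) / 3, 40 * pi / 180)
  b <- angvel_signal(quat_rotate(qrel, om), fs)
  al <- kabsch_align(a, b)
  expect_lt(quat_geodesic(al$rotation, qrel), 1e-6)
  # proper rotation: det +1, orthonormal
  R <- al$rotation_matrix
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
  # translation reports the bias between the centroids
  b2 <- angvel_signal(sweep(quat_rotate(qrel, om), 2, c(1, -2, 3), "+"), fs)
  al2 <- kabsch_align(a, b2)
  expect_equal(al2$translation, c(1, -2, 3), tolerance = 1e-9)
  expect_lt(quat_geodesic(al2$rotation, qrel), 1e-6)
})

test_that("noisy Kabsch agrees with an independent rotation search", {
  set.seed(16)
  n <- 400
  om <- matrix(rnorm(3 * n, 0, 60), n, 3)
  qrel <- from_axis_angle(c(1, 3, -2) / sqrt(14), 0.5)
  noisy <- quat_rotate(qrel, om) + matrix(rnorm(3 * n, 0, 2), n, 3)
  al <- kabsch_align(angvel_signal(om, fs), angvel_signal(noisy, fs))
  oracle <- brute_rotation_search(om, noisy)
  expect_lt(quat_geodesic(al$rotation, quat(oracle$q)), 0.05)
  expect_lte(al$residual_rmsd, oracle$rmsd + 1e-6)
})

test_that("degenerate (coplanar) angular velocities are refused", {
  set.seed(17)
  n <- 300
  om <- cbind(rnorm(n), rnorm(n), 0)  # rank-2
  b <- angvel_signal(om, fs)
  expect_error(kabsch_align(angvel_signal(om, fs), b), "coplanar")
  expect_error(kabsch_align(angvel_signal(om[1:50, ], fs),
                            angvel_signal(om[1:50, ], fs)), "100")
})
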