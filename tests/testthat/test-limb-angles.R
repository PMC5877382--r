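test_that("stride rotation composes as orientation-at-on times inverse-at-off", {
  set.seed(40)
  q <- random_unit_quat()
  expect_equal(as.numeric(stride_rotation(q, q)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  q40 <- from_axis_angle(c(0, 1, 0), 40 * pi / 180)
  expect_equal(stride_rotation(q40, c(1, 0, 0, 0)), q40, tolerance = 1e-12)
  for (i in 1:10) {
    q_on <- random_unit_quat(); q_off <- random_unit_quat()
    qr <- stride_rotation(q_on, q_off)
    expect_lt(max(abs(quat_multiply(qr, q_off) - quat(q_on))), 1e-12)
  }
})

test_that("stride axes are horizontal and de-twisted about vertical", {
  qx30 <- from_axis_angle(c(1, 0, 0), 30 * pi / 180)
  ax <- stride_axes(qx30)
  expect_equal(ax$sagittal_axis, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(ax$coronal_axis, c(0, 1, 0), tolerance = 1e-9)
  # a yaw component is discarded by the decomposition
  qr <- quat_multiply(from_axis_angle(c(0, 0, 1), 10 * pi / 180), qx30)
  ax2 <- stride_axes(qr)
  expect_equal(abs(sum(ax2$sagittal_axis * c(1, 0, 0))), 1, tolerance = 1e-6)
  expect_equal(ax2$sagittal_axis[3], 0)
  # pure yaw has no sagittal swing
  expect_error(stride_axes(from_axis_angle(c(0, 0, 1), 0.5)), "swing")
})

test_that("a constant orientation yields identically zero angles", {
  fs <- 200
  n <- 1000
  q <- quat(matrix(rep(c(0.9, 0.3, 0.3, 0.1) / sqrt(1), each = n), n, 4))
  qs <- quat_signal(q, fs)
  ss <- stride_set("RF", hoof_on = c(0.5, 1.5, 2.5, 3.5),
                   hoof_off = c(1.1, 2.1, 3.1))
  la <- limb_angle_signals(qs, ss)
  # axis estimation fails on the identity stride rotation -> strides skipped
  expect_equal(length(la$skipped), nrow(ss$strides))
})

test_that("angles are exactly zero at every mid-stance sample", {
  tr <- simulate_trial(gait_config("walk", n_strides = 6), sensor_config(seed = 41))
  ev <- detect_hoof_events(tr$imu$RF)
  qhat <- estimate_orientation(tr$imu$RF)
  la <- limb_angle_signals(qhat, ev)
  for (i in unique(la$samples$stride)) {
    seg <- la$samples[la$samples$stride == i, ]
    tm <- midstance_time(ev$strides[i, ], fs = qhat$fs)
    k <- which.min(abs(seg$time - tm))
    expect_identical(seg$sagittal[k], 0)
    expect_identical(seg$coronal[k], 0)
  }
})

test_that("a planar pendulum is recovered in the sagittal channel only", {
  # noiseless pendulum about the true sagittal axis with stance plateaus
  s0 <- sensor_config(seed = 42, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0))
  g0 <- gait_config("walk", coronal_amp = 0, n_strides = 8)
  tr <- simulate_trial(g0, s0)
  ev <- detect_hoof_events(tr$imu$LF)
  qhat <- estimate_orientation(tr$imu$LF)
  la <- limb_angle_signals(qhat, ev)
  truth <- tr$truth$limb_angles$LF
  idx <- round(la$samples$time * 200) + 1
  err <- la$samples$sagittal - truth$sagittal[idx]
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 0.5)
  expect_lt(max(abs(la$samples$coronal), na.rm = TRUE), 0.5)
})

test_that("per-stride parameters recover the configured swing", {
  s0 <- sensor_config(seed = 43, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0))
  tr <- simulate_trial(gait_config("walk", protraction = 25, retraction = -25),
                       s0)
  ev <- detect_hoof_events(tr$imu$RH)
  lp <- extract_limb_parameters(limb_angle_signals(estimate_orientation(tr$imu$RH), ev), ev)
  expect_equal(mean(lp$protraction), 25, tolerance = 0.5)
  expect_equal(mean(lp$retraction), -25, tolerance = 0.5)
  expect_equal(mean(lp$sagittal_rom), 50, tolerance = 0.5)
  # zero coronal motion collapses the coronal parameters
  g0 <- gait_config("walk", coronal_amp = 0, n_strides = 6)
  tr0 <- simulate_trial(g0, s0)
  ev0 <- detect_hoof_events(tr0$imu$LF)
  lp0 <- extract_limb_parameters(limb_angle_signals(estimate_orientation(tr0$imu$LF), ev0), ev0)
  expect_lt(max(abs(lp0$abduction)), 0.5)
  expect_lt(max(abs(lp0$coronal_rom)), 0.6)
})

test_that("sagittal ROM preserves the walk-trot ordering", {
  sw <- sensor_config(seed = 44)
  trw <- simulate_trial(gait_config("walk"), sw)
  trt <- simulate_trial(gait_config("trot"), sw)
  romof <- function(tr) {
    ev <- detect_hoof_events(tr$imu$LF)
    lp <- extract_limb_parameters(limb_angle_signals(estimate_orientation(tr$imu$LF), ev), ev)
    mean(lp$sagittal_rom)
  }
  expect_gt(romof(trt), romof(trw))
})

test_that("limb angles are invariant under a constant heading rotation", {
  s0 <- sensor_config(seed = 45, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0))
  tr0 <- simulate_trial(gait_config("walk", heading = 0, n_strides = 6), s0)
  tr1 <- simulate_trial(gait_config("walk", heading = 125, n_strides = 6), s0)
  ev <- detect_hoof_events(tr0$imu$LF)
  la0 <- limb_angle_signals(tr0$truth$orientation$LF, ev)
  la1 <- limb_angle_signals(tr1$truth$orientation$LF, ev)
  expect_equal(la1$samples$sagittal, la0$samples$sagittal, tolerance = 1e-6)
  expect_equal(la1$samples$coronal, la0$samples$coronal, tolerance = 1e-6)
})

test_that("parameter recovery holds over 200 strides at zero noise", {
  s0 <- sensor_config(seed = 46, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0))
  tr <- simulate_trial(gait_config("trot", n_strides = 50), s0)
  errs <- c()
  for (limb in c("LF", "RF", "LH", "RH")) {
    ev <- detect_hoof_events(tr$imu[[limb]])
    lp <- extract_limb_parameters(
      limb_angle_signals(estimate_orientation(tr$imu[[limb]]), ev), ev)
    errs <- c(errs, abs(lp$protraction - 28), abs(lp$retraction + 29))
  }
  expect_gt(length(errs), 2 * 200)
  expect_lt(mean(errs), 0.5)
})
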