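test_that("the same seed reproduces a bit-identical trial", {
  g <- gait_config("walk", n_strides = 5)
  s <- sensor_config(seed = 70)
  t1 <- simulate_trial(g, s)
  t2 <- simulate_trial(g, s)
  expect_identical(t1$imu$LF$acc$data, t2$imu$LF$acc$data)
  expect_identical(t1$imu$sacrum$gyro$omega, t2$imu$sacrum$gyro$omega)
  expect_identical(t1$omc$LF$quat$q, t2$omc$LF$quat$q)
  t3 <- simulate_trial(g, sensor_config(seed = 71))
  expect_false(identical(t1$imu$LF$acc$data, t3$imu$LF$acc$data))
})

test_that("truth limb angles hit the configured extrema exactly at events", {
  g <- gait_config("walk", protraction = 25, retraction = -27, n_strides = 5)
  tr <- simulate_trial(g, sensor_config(seed = 72))
  ang <- tr$truth$limb_angles$RF
  ev <- tr$truth$events$RF
  for (i in seq_len(nrow(ev$strides))) {
    i_on <- round(ev$strides$on[i] * tr$fs) + 1
    i_off <- round(ev$strides$off[i] * tr$fs) + 1
    expect_equal(ang$sagittal[i_on], 25, tolerance = 0.2)
    expect_equal(ang$sagittal[i_off], -27, tolerance = 0.2)
  }
  tp <- truth_parameters(tr)
  expect_true(all(tp$limb$protraction == 25))
  expect_true(all(tp$limb$sagittal_rom == 52))
})

test_that("noiseless gyro reconstructs the truth orientation within 0.1 degree", {
  s0 <- sensor_config(seed = 73, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0))
  tr <- simulate_trial(gait_config("trot", n_strides = 30), s0)
  qs <- tr$truth$orientation$LH
  rec <- integrate_angvel(differentiate_quats(qs), q0 = qs$q[1, ])
  expect_lt(max(quat_geodesic(rec$q, qs$q)) * 180 / pi, 0.1)
})

test_that("accelerometer magnitude averages to gravity over whole strides", {
  s0 <- sensor_config(seed = 74, acc_noise_sd = 0, gyro_noise_sd = 0,
                      gyro_bias = c(0, 0, 0), impact_acc = 0, toeoff_acc = 0)
  tr <- simulate_trial(gait_config("walk", timing_cv = 0), s0)
  ev <- tr$truth$events$LF$strides
  acc <- tr$imu$LF$acc$data
  i1 <- round(ev$on[2] * tr$fs) + 1
  i2 <- round(ev$on[10] * tr$fs)
  expect_equal(mean(sqrt(rowSums(acc[i1:i2, ]^2))), 9.81, tolerance = 0.02)
})

test_that("the OMC stream is the truth transformed by exactly (rotation, lag)", {
  s0 <- sensor_config(seed = 75, omc_pos_noise_sd = 0, omc_quat_noise_deg = 0,
                      omc_gap_rate = 0, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0), lag = 0.5)  # 100 samples
  tr <- simulate_trial(gait_config("walk"), s0)
  # angular velocity: rotated by the configured operator, delayed by lag
  om_imu <- differentiate_quats(tr$truth$orientation$RF)
  om_omc <- differentiate_quats(tr$omc$RF$quat)
  sh <- round(0.5 * tr$fs)
  n <- nrow(om_imu$omega)
  rot <- quat_rotate(s0$relative_rotation, om_imu$omega[2:(n - sh), ])
  expect_equal(om_omc$omega[(2 + sh):n, ], rot, tolerance = 1e-6)
  # upper-body marker height: delayed copy of the truth displacement
  z_omc <- tr$omc$sacrum$pos$data[, 3]
  z_tru <- tr$truth$vdisp$sacrum$data[, 1]
  expect_equal(z_omc[(1 + sh):n] - mean(z_omc[(1 + sh):n]),
               z_tru[1:(n - sh)] - mean(z_tru[1:(n - sh)]), tolerance = 1e-6)
})

test_that("configured asymmetries appear verbatim in the truth tables", {
  g0 <- gait_config("trot")
  tr0 <- simulate_trial(g0, sensor_config(seed = 76))
  tp0 <- truth_parameters(tr0)
  expect_lt(max(abs(tp0$symmetry$max_diff)), 1e-6)
  expect_lt(max(abs(tp0$symmetry$min_diff)), 1e-6)
  g1 <- gait_config("trot", asymmetry = list(max_diff_mm = 10, min_diff_mm = 0,
                                             locations = "sacrum"))
  tr1 <- simulate_trial(g1, sensor_config(seed = 76))
  tp1 <- truth_parameters(tr1)
  sac <- tp1$symmetry[tp1$symmetry$location == "sacrum", ]
  wit <- tp1$symmetry[tp1$symmetry$location == "withers", ]
  expect_equal(mean(sac$max_diff), 10, tolerance = 1e-3)
  expect_lt(max(abs(wit$max_diff)), 1e-6)
})

test_that("a fully symmetric noiseless trial yields symmetry indices near zero", {
  s0 <- sensor_config(seed = 77, gyro_noise_sd = 0, acc_noise_sd = 0,
                      gyro_bias = c(0, 0, 0), omc_pos_noise_sd = 0,
                      omc_quat_noise_deg = 0, omc_gap_rate = 0)
  tr <- simulate_trial(gait_config("walk"), s0)
  res <- quiet_trial(tr)
  for (loc in c("withers", "sacrum", "sternum")) {
    expect_lt(abs(mean(res$sym_imu[[loc]]$si_up, na.rm = TRUE)), 0.02)
    expect_lt(abs(mean(res$sym_omc[[loc]]$si_up, na.rm = TRUE)), 0.02)
  }
})

test_that("stride timing variability matches the configured level", {
  tr <- simulate_trial(gait_config("walk", n_strides = 40, timing_cv = 0.02),
                       sensor_config(seed = 78))
  dur <- tr$truth$events$LF$strides$duration
  expect_gt(sd(dur) / mean(dur), 0.005)
  expect_lt(sd(dur) / mean(dur), 0.04)
  tr0 <- simulate_trial(gait_config("walk", n_strides = 10, timing_cv = 0),
                        sensor_config(seed = 78))
  dur0 <- tr0$truth$events$LF$strides$duration
  expect_lt(sd(dur0) / mean(dur0), 1e-6)
})

test_that("atypical configurations warn but run", {
  expect_warning(gait_config("walk", coronal_amp = 30), "atypical")
})
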