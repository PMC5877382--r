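test_that("Hamilton product matches identities and the matrix-form oracle", {
  q <- quat(c(0.5, -0.5, 0.5, 0.5))
  expect_equal(quat_multiply(quat(c(1, 0, 0, 0)), q), q)
  expect_equal(as.numeric(quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))),
               c(0, 0, 0, 1))
  set.seed(1)
  for (i in 1:25) {
    q1 <- random_unit_quat(); q2 <- random_unit_quat()
    expect_equal(as.numeric(quat_multiply(q1, q2)),
                 quat_mult_matrix_oracle(q1, q2), tolerance = 1e-12)
    expect_equal(quat_norm(quat_multiply(q1, q2)), 1, tolerance = 1e-12)
  }
})

test_that("axis-angle construction agrees with the Rodrigues oracle", {
  expect_equal(as.numeric(from_axis_angle(c(0, 0, 1), pi)), c(0, 0, 0, 1),
               tolerance = 1e-12)
  expect_equal(as.numeric(from_axis_angle(c(1, 0, 0), 0)), c(1, 0, 0, 0))
  set.seed(2)
  axis <- c(1, 1, 1) / sqrt(3)
  q <- from_axis_angle(axis, 0.7)
  R <- rodrigues_oracle(axis, 0.7)
  for (i in 1:10) {
    v <- rnorm(3)
    expect_equal(as.numeric(quat_rotate(q, v)), as.numeric(R %*% v),
                 tolerance = 1e-12)
  }
  expect_warning(from_axis_angle(c(0, 0, 2), 0.3), "normaliz")
  expect_error(from_axis_angle(c(0, 0, 0), 0.3), "non-zero")
})

test_that("quaternion/matrix conversions are mutually inverse", {
  set.seed(3)
  for (i in 1:20) {
    q <- random_unit_quat()
    if (q[1] < 0) q <- -q
    R <- quat_to_matrix(q)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(as.numeric(quat_from_matrix(R)), as.numeric(q),
                 tolerance = 1e-9)
  }
})

test_that("gyro integration reproduces a constant-rate closed form", {
  # 90 deg/s about z for one second at 200 Hz
  q <- quat(c(1, 0, 0, 0))
  for (k in 1:200) q <- integrate_gyro(q, c(0, 0, 90), 1 / 200)
  yaw <- 2 * atan2(q[1, 4], q[1, 1]) * 180 / pi
  expect_lt(abs(yaw - 90), 0.1)
  # zero rate leaves the orientation untouched
  q0 <- from_axis_angle(c(1, 2, 2) / 3, 0.4)
  expect_equal(integrate_gyro(q0, c(0, 0, 0), 0.01), q0, tolerance = 1e-15)
})

test_that("differentiation inverts integration (round trip both ways)", {
  # constant orientation -> zero angular velocity
  qc <- quat(matrix(rep(c(0.5, 0.5, 0.5, 0.5), each = 50), 50, 4))
  om0 <- differentiate_quats(quat_signal(qc, fs = 100))
  expect_equal(max(abs(om0$omega)), 0)
  # integrate then differentiate recovers the rate (small dt, slow rate)
  fs <- 2000
  om <- angvel_signal(matrix(rep(c(3, -2, 5), each = 400), 400, 3), fs)
  qs <- integrate_angvel(om)
  om2 <- differentiate_quats(qs)
  expect_lt(max(abs(om2$omega[-1, ] - om$omega[-1, ])), 1e-6)
  # differentiate then integrate recovers the orientation
  t <- (0:999) / 200
  q <- quat(cbind(cos(0.3 * sin(t)), sin(0.3 * sin(t)), 0, 0))
  qs2 <- quat_signal(q, 200)
  rec <- integrate_angvel(differentiate_quats(qs2), q0 = qs2$q[1, ])
  expect_lt(max(quat_geodesic(rec$q, qs2$q)), 1e-4)
})

test_that("sign continuity is enforced and repairs injected flips", {
  t <- (0:499) / 200
  q <- quat(cbind(cos(t), sin(t), 0, 0))
  q[200:300, ] <- -q[200:300, ]         # inject a sign flip mid-signal
  qs <- quat_signal(q, 200)
  dots <- rowSums(qs$q[-1, ] * qs$q[-nrow(qs$q), ])
  expect_true(all(dots >= 0))
  om <- differentiate_quats(qs)
  # the true rate is 2 rad/s about x; a surviving flip would register as an
  # enormous one-sample spike
  expect_lt(max(abs(om$omega)), 120)
})

test_that("swing-twist recomposes exactly and matches the grid-search oracle", {
  # pure twist and pure swing cases
  qz <- from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  st <- swing_twist(qz, c(0, 0, 1))
  expect_equal(st$twist, qz, tolerance = 1e-12)
  expect_equal(as.numeric(st$swing), c(1, 0, 0, 0), tolerance = 1e-12)
  qx <- from_axis_angle(c(1, 0, 0), 30 * pi / 180)
  st <- swing_twist(qx, c(0, 0, 1))
  expect_equal(as.numeric(st$twist), c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(st$swing, qx, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    qr <- random_unit_quat()
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    st <- swing_twist(qr, axis)
    # recomposition: qr = twist x swing
    expect_lt(max(abs(quat_multiply(st$twist, st$swing) - quat(qr))), 1e-9)
    # twist vector part parallel to axis; swing axis perpendicular
    tv <- st$twist[1, 2:4]
    expect_lt(sqrt(sum((tv - sum(tv * axis) * axis)^2)), 1e-9)
    expect_lt(abs(sum(st$swing[1, 2:4] * axis)), 1e-9)
  }
  # grid-search oracle on a handful of cases (the grid is the slow part)
  for (i in 1:3) {
    qr <- random_unit_quat()
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    st <- swing_twist(qr, axis)
    got <- twist_angle(st$twist, axis) * pi / 180
    oracle <- swing_twist_grid_oracle(qr, axis)
    d <- abs(got - oracle) %% (2 * pi)
    expect_lt(min(d, 2 * pi - d), 2e-4)
  }
})

test_that("swing-twist recomposition holds over many random pairs", {
  set.seed(5)
  n <- 10000
  qr <- quat(random_unit_quat(n))
  axis <- c(0.6, -0.64, 0.48)
  st <- swing_twist(qr, axis)
  err <- abs(quat_multiply(st$twist, st$swing) - qr)
  expect_lt(max(err), 1e-9)
})

test_that("twist angles carry the sign of the reference axis", {
  expect_equal(twist_angle(quat(c(1, 0, 0, 0)), c(0, 0, 1)), 0)
  q <- from_axis_angle(c(0, 0, 1), 0.5)
  expect_equal(twist_angle(q, c(0, 0, 1)), 0.5 * 180 / pi, tolerance = 1e-9)
  expect_equal(twist_angle(q, c(0, 0, -1)), -0.5 * 180 / pi, tolerance = 1e-9)
  expect_error(twist_angle(from_axis_angle(c(1, 0, 0), 0.5), c(0, 0, 1)),
               "parallel")
})

test_that("degenerate 180-degree swing yields an identity twist with a flag", {
  qr <- from_axis_angle(c(1, 0, 0), pi)  # half-turn perpendicular to z
  st <- swing_twist(qr, c(0, 0, 1))
  expect_true(st$degenerate[1])
  expect_equal(as.numeric(st$twist), c(1, 0, 0, 0))
})

test_that("slerp interpolates on the great circle", {
  q1 <- from_axis_angle(c(0, 0, 1), 0)
  q2 <- from_axis_angle(c(0, 0, 1), 1)
  qm <- quat_slerp(q1, q2, 0.5)
  expect_equal(unname(2 * atan2(qm[1, 4], qm[1, 1])), 0.5, tolerance = 1e-12)
  expect_equal(quat_slerp(q1, q2, 0), q1, tolerance = 1e-12)
  expect_equal(quat_slerp(q1, q2, 1), q2, tolerance = 1e-12)
})
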