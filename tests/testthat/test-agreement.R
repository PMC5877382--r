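test_that("residual statistics follow the standard definitions", {
  x <- c(1, 2, 3, 4)
  expect_equal(residual_stats(x, x), list(rmse = 0, mean_residual = 0,
                                          sd_residual = 0, n = 4))
  rs <- residual_stats(x, x + 2)
  expect_equal(rs$rmse, 2)
  expect_equal(rs$mean_residual, -2)
  expect_equal(rs$sd_residual, 0)
  # gap samples are excluded pairwise for gait_ts inputs
  a <- gait_ts(c(1, NA, 3, 4), 10)
  b <- gait_ts(c(0, 2, 3, NA), 10)
  expect_equal(residual_stats(a, b)$n, 2)
  expect_error(residual_stats(gait_ts(rep(NA_real_, 5), 10), b), "overlap")
})

test_that("a known injected residual is reported back", {
  set.seed(60)
  n <- 5000
  truth <- 30 * sin(2 * pi * 2 * (1:n) / 200)
  rs <- residual_stats(truth + rnorm(n, 0, 1.85), truth)
  expect_equal(rs$rmse, 1.85, tolerance = 0.1)
  expect_lt(abs(rs$mean_residual), 0.1)
})

test_that("Bland-Altman reproduces the textbook quantities", {
  pm0 <- suppressWarnings(paired_measurements(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  ba0 <- suppressWarnings(bland_altman(pm0))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_upper, 0)
  expect_equal(ba0$loa_lower, 0)
  set.seed(61)
  d <- rnorm(500, 1.5, 2)
  pm <- paired_measurements(d + 10, rep(10, 500), subject = rep(1:5, each = 100))
  ba <- bland_altman(pm)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_true(ba$loa_ci$bias[1] < ba$bias && ba$bias < ba$loa_ci$bias[2])
})

test_that("the 1.96-SD limits cover about 95% of differences", {
  set.seed(62)
  n <- 10000
  d <- rnorm(n, 0.5, 3)
  pm <- paired_measurements(d, rep(0, n), subject = rep(1:10, each = 1000))
  ba <- bland_altman(pm)
  cov <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_equal(cov, 0.95, tolerance = 0.01)
})

test_that("swapping the systems negates the bias and mirrors the limits", {
  set.seed(63)
  a <- rnorm(300, 5, 1); b <- rnorm(300, 4, 1)
  subj <- rep(1:3, each = 100)
  ba_ab <- bland_altman(paired_measurements(a, b, subject = subj))
  ba_ba <- bland_altman(paired_measurements(b, a, subject = subj))
  expect_equal(ba_ba$bias, -ba_ab$bias)
  expect_equal(ba_ba$loa_upper, -ba_ab$loa_lower)
  expect_equal(ba_ba$loa_lower, -ba_ab$loa_upper)
})

test_that("trial means give narrower limits than per-stride differences", {
  set.seed(64)
  n_sub <- 6; n_tr <- 5; n_str <- 20
  subj <- rep(1:n_sub, each = n_tr * n_str)
  tri <- rep(rep(1:n_tr, each = n_str), n_sub)
  d <- rnorm(n_sub * n_tr * n_str, 0, 2)  # independent stride noise
  pm <- paired_measurements(d, rep(0, length(d)), subject = subj, trial = tri)
  ba_s <- bland_altman(pm, "per_stride")
  ba_t <- bland_altman(pm, "trial_mean")
  expect_lt(ba_t$loa_upper - ba_t$loa_lower,
            0.5 * (ba_s$loa_upper - ba_s$loa_lower))
})

test_that("ICC follows the printed variance-component formula", {
  # direct arithmetic: t00 = 3, sigma2 = 1, nj = 4
  expect_equal(3 / (3 + 1 / 4), 0.923, tolerance = 1e-3)
  # recovery: t00 = 4, sigma2 = 1, nj = 50, 20 groups
  set.seed(65)
  iccs <- replicate(20, {
    subj <- rep(1:20, each = 50)
    x <- rep(rnorm(20, 0, 2), each = 50) + rnorm(1000)
    icc_mixed(x, subj)$icc
  })
  expect_lt(abs(median(iccs) - 4 / (4 + 1 / 50)), 0.05)
  # report fields feed the same formula
  subj <- rep(1:20, each = 50)
  x <- rep(rnorm(20, 0, 2), each = 50) + rnorm(1000)
  r <- icc_mixed(x, subj)
  expect_equal(r$icc, min(1, max(0, r$t00 / (r$t00 + r$sigma2 / r$nj))))
  expect_true(r$icc >= 0 && r$icc <= 1)
})

test_that("without between-subject variance the ICC collapses", {
  set.seed(66)
  subj <- rep(1:1000, each = 2)
  x <- rnorm(2000)
  expect_lte(icc_mixed(x, subj)$icc, 0.05)
  expect_error(icc_mixed(rep(1, 100), rep(1:10, each = 10)), "variance")
  expect_error(icc_mixed(rnorm(10), 1:10), "2 observations")
})

test_that("ICC increases monotonically in the between-subject variance", {
  set.seed(67)
  base <- rnorm(30)
  noise <- rnorm(1500)
  iccs <- sapply(c(0.5, 1, 2, 4), function(s) {
    subj <- rep(1:30, each = 50)
    x <- rep(base * s, each = 50) + noise
    icc_mixed(x, subj)$icc
  })
  expect_true(all(diff(iccs) > 0))
})

test_that("REML variance components match the balanced ANOVA closed form", {
  set.seed(68)
  k <- 12; nj <- 6
  subj <- rep(1:k, each = nj)
  x <- rep(rnorm(k, 0, 3), each = nj) + rnorm(k * nj, 0, 1.5)
  vc <- equigait:::vc_random_intercept(x, subj)
  aov_tab <- anova(lm(x ~ factor(subj)))
  msb <- aov_tab$`Mean Sq`[1]; msw <- aov_tab$`Mean Sq`[2]
  expect_equal(vc$sigma2, msw, tolerance = 1e-6)
  expect_equal(vc$t00, (msb - msw) / nj, tolerance = 1e-6)
})

test_that("paired-measurement modes select the intended ICC response", {
  set.seed(69)
  subj <- rep(1:10, each = 40)
  truth <- rep(rnorm(10, 20, 5), each = 40)
  a <- truth + rnorm(400, 0, 0.5)
  b <- truth + rnorm(400, 0, 0.5)
  pm <- paired_measurements(a, b, subject = subj)
  raw <- icc_mixed(pm, mode = "raw")
  dif <- icc_mixed(pm, mode = "difference")
  expect_equal(raw$mode, "raw")
  expect_equal(dif$mode, "difference")
  # strong between-horse spread: raw-response ICC near 1; the differences
  # carry no between-horse structure at all
  expect_gt(raw$icc, 0.95)
  expect_lt(dif$icc, 0.6)
})
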