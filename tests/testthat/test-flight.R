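test_that("ideal trajectory is exactly nominal; spacing follows v * t_int", {
  tr <- simulate_trajectory(500, v = 65 / 3.6, t_int = 0.0277,
                            sigma_att = 0, seed = 1)
  expect_true(all(tr$att == 0))
  expect_true(all(tr$pos[, 1] == 0))
  expect_true(all(tr$pos[, 3] == tr$h))
  expect_equal(length(tr$t), floor(500 / (65 / 3.6 * 0.0277)))
  spacing <- diff(tr$pos[, 2])
  expect_equal(spacing, rep(65 / 3.6 * 0.0277, length(spacing)))
  expect_equal(spacing[1], 0.5, tolerance = 1e-3)

  expect_error(simulate_trajectory(100, v = 0), class = "gyrospec_param_error")
  expect_error(simulate_trajectory(100, rho = 1), class = "gyrospec_param_error")
  expect_error(simulate_trajectory(100, sigma_att = -1),
               class = "gyrospec_param_error")
})

test_that("AR(1) attitude has the stated stationary spread", {
  tr <- simulate_trajectory(5100, sigma_att = gyrospec:::deg2rad(1),
                            rho = 0.95, seed = 42)  # ~1e4 lines
  expect_gte(length(tr$t), 1e4)
  for (j in 1:3) {
    expect_lt(abs(sd(tr$att[, j]) - gyrospec:::deg2rad(1)) /
                gyrospec:::deg2rad(1), 0.1)
    r1 <- cor(tr$att[-1, j], tr$att[-nrow(tr$att), j])
    expect_lt(abs(r1 - 0.95), 0.03)
  }
  expect_identical(tr$att,
                   simulate_trajectory(5100, sigma_att = gyrospec:::deg2rad(1),
                                       rho = 0.95, seed = 42)$att)
})

test_that("noise-free sensor streams reproduce the true states", {
  tr <- simulate_trajectory(200, sigma_att = gyrospec:::deg2rad(1), seed = 2)
  st <- simulate_sensors(tr, sigma_gps = 0, sigma_gyro = 0, sigma_bias = 0,
                         sigma_att_meas = 0, seed = 1)
  expect_equal(st$gps, gyrospec:::interp_cols(tr$t, tr$pos, st$t_gps))
  att_int <- apply(st$gyro, 2, function(g) {
    dts <- diff(st$t_imu)
    cumsum(c(0, g[-length(g)] * dts))
  })
  att_true <- gyrospec:::interp_cols(tr$t, tr$att, st$t_imu)
  expect_equal(sweep(att_int, 2, att_true[1, ], "+"), att_true,
               tolerance = 1e-10)
  expect_error(simulate_sensors(tr, sigma_gps = -1),
               class = "gyrospec_param_error")
  expect_error(simulate_sensors(tr, imu_rate = 1),
               class = "gyrospec_param_error")
})

test_that("GPS noise level and gyro bias random walk behave as specified", {
  tr <- simulate_trajectory(5100, sigma_att = 0, seed = 1)  # long line
  st <- simulate_sensors(tr, sigma_gps = 2, gps_rate = 10, seed = 9)
  err <- st$gps - gyrospec:::interp_cols(tr$t, tr$pos, st$t_gps)
  expect_gt(length(err) / 3, 1e3)
  expect_lt(abs(sd(err) - 2) / 2, 0.05)

  # bias-only dead-reckoned attitude error variance grows with time
  st2 <- simulate_sensors(tr, sigma_gps = 0, sigma_gyro = 0,
                          sigma_bias = 1e-3, sigma_att_meas = 0, seed = 4)
  dr <- dead_reckon(st2)
  e <- dr$att[, 1] - gyrospec:::interp_cols(tr$t, tr$att, dr$t)[, 1]
  n <- length(e)
  early <- mean(e[seq_len(n %/% 4)]^2)
  late <- mean(e[(3 * n %/% 4):n]^2)
  expect_gt(late, early)
})

test_that("zero-noise fusion reproduces the truth", {
  tr <- simulate_trajectory(200, sigma_att = gyrospec:::deg2rad(1), seed = 5)
  st <- simulate_sensors(tr, sigma_gps = 0, sigma_gyro = 0, sigma_bias = 0,
                         sigma_att_meas = 0, seed = 1)
  a <- kalman_fuse(st)
  expect_lt(max(abs(a$pos - tr$pos)), 1e-6)
  expect_lt(max(abs(a$att - tr$att)), 1e-9)
  expect_true(all(a$cov >= 0))  # variances non-negative
})

test_that("stationary noisy-GPS filtering beats raw measurements", {
  tr <- simulate_trajectory(3, v = 0.1, t_int = 0.1, sigma_att = 0, seed = 1)
  # near-stationary platform: estimate should average GPS noise down
  st <- simulate_sensors(tr, sigma_gps = 2, imu_rate = 20, seed = 11)
  a <- kalman_fuse(st)
  est_err <- sd(a$pos[, 1] - tr$pos[, 1])
  expect_lt(est_err, 2 * 0.5)  # well under the raw sigma
})

test_that("fusion dominates dead reckoning in expectation (20 seeds)", {
  win_att <- 0; win_pos <- 0
  att_f <- att_d <- pos_f <- pos_d <- numeric(0)
  for (s in 1:20) {
    tr <- simulate_trajectory(150, sigma_att = gyrospec:::deg2rad(1),
                              seed = 100 + s)
    st <- simulate_sensors(tr, imu_rate = 50, seed = 200 + s)
    a <- kalman_fuse(st)
    d <- dead_reckon(st)
    att_f <- c(att_f, rmse(a$att - tr$att))
    att_d <- c(att_d, rmse(d$att - tr$att))
    pos_f <- c(pos_f, rmse(a$pos - tr$pos))
    pos_d <- c(pos_d, rmse(d$pos - tr$pos))
  }
  expect_lt(mean(att_f), mean(att_d))
  expect_lt(mean(pos_f), mean(pos_d))
})

test_that("filter innovations are chi-square consistent at defaults", {
  tr <- simulate_trajectory(400, sigma_att = gyrospec:::deg2rad(1), seed = 31)
  st <- simulate_sensors(tr, seed = 32)
  a <- kalman_fuse(st)
  # NIS has df = 3; its mean over m updates should be near 3
  m <- length(a$nis)
  expect_gt(m, 100)
  expect_gt(mean(a$nis), 3 * (1 - 4 / sqrt(m)))
  expect_lt(mean(a$nis), 3 * (1 + 4 / sqrt(m)))
})

test_that("fusion is deterministic and rejects a bad initial covariance", {
  tr <- simulate_trajectory(100, sigma_att = gyrospec:::deg2rad(1), seed = 6)
  st <- simulate_sensors(tr, seed = 7)
  expect_identical(kalman_fuse(st)$pos, kalman_fuse(st)$pos)
  expect_error(kalman_fuse(st, init = list(x0 = numeric(12),
                                           P0 = diag(-1, 12))),
               class = "gyrospec_numeric_error")
})

test_that("pose CSV round trip", {
  tr <- simulate_trajectory(60, sigma_att = gyrospec:::deg2rad(0.5), seed = 8)
  p <- file.path(tempdir(), "pose.csv")
  write_pose_csv(tr, p)
  back <- read_pose_csv(p)
  expect_equal(back$pos, tr$pos, ignore_attr = TRUE)
  expect_equal(back$att, tr$att, ignore_attr = TRUE)
})
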