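#' Simulate an ultralight flight line
#'
#' Straight nominal track flown north (+y) at constant ground speed and
#' height. Ultralight platforms have low inertia, so roll, pitch and yaw
#' wander around zero; each angle follows an independent stationary
#' AR(1) process with standard deviation `sigma` and lag-1 correlation
#' `rho` at the line rate. One trajectory sample per acquired image
#' line; the number of lines is `floor(length_m / (v * t_int))`.
#'
#' @param length_m ground length of the line in m.
#' @param v ground speed in m/s (65 km/h is 18.06 m/s).
#' @param h flight height in m.
#' @param t_int sensor integration time per line in s.
#' @param sigma_att per-axis attitude standard deviation in rad
#'   (recycled to roll, pitch, yaw).
#' @param rho AR(1) lag-1 correlation, `|rho| < 1`.
#' @param x0,y0 map coordinates of the track start.
#' @param seed integer seed.
#' @return an object of class `trajectory`: per-line `t`, `pos`
#'   (n x 3, map x/y/z), `att` (n x 3, roll/pitch/yaw rad), plus `v`,
#'   `t_int`, `h`.
#' @export
simulate_trajectory <- function(length_m, v = 65 / 3.6, h = 300,
                                t_int = 0.0277,
                                sigma_att = deg2rad(1), rho = 0.95,
                                x0 = 0, y0 = 0, seed = 1L) {
  if (v <= 0 || h <= 0 || t_int <= 0) {
    stop_gyrospec("v, h and t_int must be > 0", "gyrospec_param_error")
  }
  if (abs(rho) >= 1) stop_gyrospec("|rho| must be < 1", "gyrospec_param_error")
  sigma_att <- rep_len(sigma_att, 3L)
  if (any(sigma_att < 0)) {
    stop_gyrospec("attitude sigma must be >= 0", "gyrospec_param_error")
  }
  n <- floor(length_m / (v * t_int))
  stopifnot(n >= 1)
  t <- (seq_len(n) - 1) * t_int
  pos <- cbind(x = rep(x0, n), y = y0 + v * t, z = rep(h, n))
  att <- with_seed(seed, {
    sapply(1:3, function(a) {
      s <- sigma_att[a]
      if (s == 0) return(rep(0, n))
      x <- numeric(n)
      x[1] <- stats::rnorm(1, 0, s)  # stationary init
      innov <- stats::rnorm(n - 1, 0, s * sqrt(1 - rho^2))
      for (k in seq_len(n - 1)) x[k + 1] <- rho * x[k] + innov[k]
      x
    })
  })
  att <- matrix(att, n, 3, dimnames = list(NULL, c("roll", "pitch", "yaw")))
  structure(list(t = t, pos = pos, att = att, v = v, t_int = t_int, h = h),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d lines, %.1f s @ %.1f m/s, h = %.0f m, att sd = %.2f/%.2f/%.2f deg\n",
              length(x$t), max(x$t), x$v, x$h,
              rad2deg(stats::sd(x$att[, 1])), rad2deg(stats::sd(x$att[, 2])),
              rad2deg(stats::sd(x$att[, 3]))))
  invisible(x)
}

interp_cols <- function(t_in, m, t_out) {
  sapply(seq_len(ncol(m)), function(j) {
    stats::approx(t_in, m[, j], xout = t_out, rule = 2)$y
  })
}

#' Simulate GPS/IMU measurement streams along a trajectory
#'
#' GPS positions are truth plus white Gaussian noise. Gyroscopes measure
#' true Euler-angle rates (small-angle regime) plus a slowly drifting
#' random-walk bias and white noise. An optional low-rate absolute
#' attitude reference (gravity-derived roll/pitch and course-derived
#' heading) makes attitude and bias observable; without it, attitude --
#' yaw in particular -- is unobservable by fusion and can only be
#' dead-reckoned.
#'
#' @param traj a [simulate_trajectory()] result (the truth).
#' @param sigma_gps GPS position noise, m.
#' @param sigma_gyro gyro white noise per sample, rad/s.
#' @param sigma_bias gyro bias random walk intensity, rad/s/sqrt(s).
#' @param gps_rate,imu_rate,att_rate sample rates, Hz. The IMU rate must
#'   be at least the line rate. Set `att_rate = 0` to disable the
#'   absolute attitude reference.
#' @param sigma_att_meas absolute attitude reference noise, rad.
#' @param seed integer seed.
#' @return object of class `sensor_streams`.
#' @export
simulate_sensors <- function(traj, sigma_gps = 2, sigma_gyro = 0.005,
                             sigma_bias = 1e-4, gps_rate = 20,
                             imu_rate = 100, att_rate = 10,
                             sigma_att_meas = deg2rad(0.1), seed = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (sigma_gps < 0 || sigma_gyro < 0 || sigma_bias < 0 || sigma_att_meas < 0) {
    stop_gyrospec("noise sigmas must be >= 0", "gyrospec_param_error")
  }
  if (imu_rate < 1 / traj$t_int) {
    stop_gyrospec("IMU rate must be >= the line rate", "gyrospec_param_error")
  }
  T_end <- max(traj$t)
  dt <- 1 / imu_rate
  # uniform grid covering the whole span, augmented with the line
  # timestamps so the piecewise-linear attitude truth has no kink
  # inside a sampling interval (strapdown integration then reconstructs
  # it exactly when noise-free)
  t_imu <- seq(0, by = dt, length.out = ceiling(T_end / dt) + 1L)
  t_imu <- sort(unique(round(c(t_imu, traj$t), 9)))
  dts <- diff(t_imu)
  att_true <- interp_cols(traj$t, traj$att, t_imu)
  # true Euler rates as forward increments over one sampling step
  rate_true <- apply(att_true, 2, function(a) {
    n <- length(a)
    if (n < 2) return(rep(0, n))
    c(diff(a) / dts, 0)
  })
  with_seed(seed, {
    step_sd <- sigma_bias * sqrt(c(0, dts))
    bias <- apply(matrix(stats::rnorm(length(t_imu) * 3), ncol = 3) * step_sd,
                  2, cumsum)
    gyro <- rate_true + bias +
      matrix(stats::rnorm(length(t_imu) * 3, 0, sigma_gyro), ncol = 3)
    t_gps <- seq(0, T_end, by = 1 / gps_rate)
    gps <- interp_cols(traj$t, traj$pos, t_gps) +
      matrix(stats::rnorm(length(t_gps) * 3, 0, sigma_gps), ncol = 3)
    if (att_rate > 0) {
      t_att <- seq(0, T_end, by = 1 / att_rate)
      att_meas <- interp_cols(traj$t, traj$att, t_att) +
        matrix(stats::rnorm(length(t_att) * 3, 0, sigma_att_meas), ncol = 3)
    } else {
      t_att <- numeric(0)
      att_meas <- matrix(0, 0, 3)
    }
    structure(
      list(t_imu = t_imu, gyro = gyro, t_gps = t_gps, gps = gps,
           t_att = t_att, att_meas = att_meas,
           sigma_gps = sigma_gps, sigma_gyro = sigma_gyro,
           sigma_bias = sigma_bias, sigma_att_meas = sigma_att_meas,
           imu_rate = imu_rate, line_t = traj$t, v = traj$v),
      class = "sensor_streams")
  })
}

#' Fuse GPS and IMU streams into a per-line AHRS solution
#'
#' Linear Kalman filter on the 12-dimensional state (position, velocity,
#' attitude, gyro bias), linearized about the nominal track: position
#' propagates at constant velocity, attitude integrates the bias-
#' corrected gyro. GPS fixes update position; the absolute attitude
#' reference updates attitude (making gyro bias observable). The
#' filtered state is resampled to the line timestamps by linear
#' interpolation.
#'
#' @param streams a [simulate_sensors()] result.
#' @param init optional list with `x0` (12-vector initial state) and
#'   `P0` (12 x 12 initial covariance). Defaults to the first GPS fix,
#'   zero attitude/bias and a broad diagonal covariance.
#' @param sigma_accel process noise on velocity, m/s^2/sqrt(s); small by
#'   default because the platform flies a nominally constant-velocity
#'   line.
#' @param smooth apply a Rauch-Tung-Striebel backward smoothing pass
#'   (default). Geocorrection is a post-flight batch problem, so the
#'   attitude/position solution may use future measurements; the
#'   forward-only estimate is what an online autopilot would see.
#' @return object of class `ahrs_solution`: per-line `t`, `pos`, `att`,
#'   `cov` (n x 12 state variances), `nis` (normalized innovation
#'   squared of each GPS update, df = 3) and `pose_source = "ahrs"`.
#' @export
kalman_fuse <- function(streams, init = NULL, sigma_accel = 0.02,
                        smooth = TRUE) {
  stopifnot(inherits(streams, "sensor_streams"))
  if (length(streams$t_imu) == 0) {
    stop_gyrospec("empty sensor streams", "gyrospec_param_error")
  }
  nI <- length(streams$t_imu)
  dts <- diff(streams$t_imu)
  ip <- 1:3; iv <- 4:6; ia <- 7:9; ib <- 10:12
  x <- numeric(12)
  if (is.null(init)) {
    x[ip] <- streams$gps[1, ]
    x[iv] <- c(0, streams$v, 0)
    P <- diag(c(rep(streams$sigma_gps^2 + 1, 3), rep(1, 3),
                rep(deg2rad(2)^2, 3), rep(1e-4, 3)))
  } else {
    x <- init$x0
    P <- init$P0
    if (any(!is.finite(P)) || any(diag(P) < 0) ||
        inherits(try(chol(P + diag(1e-12, 12)), silent = TRUE), "try-error")) {
      stop_gyrospec("initial covariance is not positive definite",
                    "gyrospec_numeric_error")
    }
  }
  mkF <- function(dtk) {
    F <- diag(12)
    F[cbind(ip, iv)] <- dtk
    F[cbind(ia, ib)] <- -dtk
    F
  }
  mkQ <- function(dtk) {
    diag(c(rep(1e-8 * dtk, 3), rep(sigma_accel^2 * dtk, 3),
           rep((streams$sigma_gyro * dtk)^2 + 1e-14, 3),
           rep(streams$sigma_bias^2 * dtk + 1e-16, 3)))
  }
  Rg <- diag(rep(max(streams$sigma_gps, 1e-6)^2, 3))
  Ra <- diag(rep(max(streams$sigma_att_meas, 1e-8)^2, 3))
  Hg <- matrix(0, 3, 12); Hg[cbind(1:3, ip)] <- 1
  Ha <- matrix(0, 3, 12); Ha[cbind(1:3, ia)] <- 1

  xs <- matrix(0, nI, 12)
  vs <- matrix(0, nI, 12)
  Pf <- if (smooth) array(0, c(12, 12, nI)) else NULL
  xp <- if (smooth) matrix(0, nI, 12) else NULL
  Pp <- if (smooth) array(0, c(12, 12, nI)) else NULL
  nis <- numeric(0)
  gi <- 1L; ai <- 1L
  nG <- length(streams$t_gps); nA <- length(streams$t_att)
  upd <- function(H, R, z) {
    S <- H %*% P %*% t(H) + R
    Sc <- try(chol(S), silent = TRUE)
    if (inherits(Sc, "try-error")) {
      stop_gyrospec("singular innovation covariance in Kalman update",
                    "gyrospec_numeric_error")
    }
    innov <- z - as.numeric(H %*% x)
    K <- P %*% t(H) %*% chol2inv(Sc)
    x <<- x + as.numeric(K %*% innov)
    P <<- (diag(12) - K %*% H) %*% P
    sum(backsolve(Sc, innov, transpose = TRUE)^2)  # NIS
  }
  for (k in seq_len(nI)) {
    if (k > 1) {
      dtk <- dts[k - 1]
      F <- mkF(dtk)
      u <- numeric(12)
      u[ia] <- streams$gyro[k - 1, ] * dtk
      x <- as.numeric(F %*% x) + u
      P <- F %*% P %*% t(F) + mkQ(dtk)
    }
    if (smooth) {
      xp[k, ] <- x
      Pp[, , k] <- P
    }
    tk <- streams$t_imu[k]
    while (gi <= nG && streams$t_gps[gi] <= tk + 1e-9) {
      nis <- c(nis, upd(Hg, Rg, streams$gps[gi, ]))
      gi <- gi + 1L
    }
    while (ai <= nA && streams$t_att[ai] <= tk + 1e-9) {
      upd(Ha, Ra, streams$att_meas[ai, ])
      ai <- ai + 1L
    }
    xs[k, ] <- x
    vs[k, ] <- diag(P)
    if (smooth) Pf[, , k] <- P
  }
  if (smooth && nI > 1) {
    # RTS backward pass: x_s[k] = x_f[k] + C (x_s[k+1] - x_p[k+1])
    for (k in (nI - 1):1) {
      F <- mkF(dts[k])
      C <- Pf[, , k] %*% t(F) %*% solve(Pp[, , k + 1] + diag(1e-12, 12))
      xs[k, ] <- xs[k, ] + as.numeric(C %*% (xs[k + 1, ] - xp[k + 1, ]))
      Ps <- Pf[, , k] + C %*% (Pf[, , k + 1] - Pp[, , k + 1]) %*% t(C)
      vs[k, ] <- pmax(diag(Ps), 0)
      Pf[, , k] <- Ps
    }
  }
  out_t <- streams$line_t
  S <- interp_cols(streams$t_imu, xs, out_t)
  V <- interp_cols(streams$t_imu, vs, out_t)
  structure(
    list(t = out_t, pos = S[, ip, drop = FALSE], att = S[, ia, drop = FALSE],
         vel = S[, iv, drop = FALSE], bias = S[, ib, drop = FALSE],
         cov = V, nis = nis, pose_source = "ahrs"),
    class = "ahrs_solution")
}

#' Dead-reckoned pose: raw GPS position, integrated gyro attitude
#'
#' The no-fusion baseline: position linearly interpolated from raw GPS
#' fixes, attitude integrated from the raw gyro with no bias estimate
#' (so it drifts).
#'
#' @param streams a [simulate_sensors()] result.
#' @param att0 initial attitude (rad).
#' @return object of class `ahrs_solution` with
#'   `pose_source = "dead_reckoning"`.
#' @export
dead_reckon <- function(streams, att0 = c(0, 0, 0)) {
  stopifnot(inherits(streams, "sensor_streams"))
  dt <- 1 / streams$imu_rate
  att <- apply(streams$gyro, 2, function(g) cumsum(c(0, g[-length(g)])) * dt)
  att <- sweep(att, 2, att0, "+")
  out_t <- streams$line_t
  structure(
    list(t = out_t,
         pos = interp_cols(streams$t_gps, streams$gps, out_t),
         att = interp_cols(streams$t_imu, att, out_t),
         cov = NULL, nis = NULL, pose_source = "dead_reckoning"),
    class = "ahrs_solution")
}

#' @export
print.ahrs_solution <- function(x, ...) {
  cat(sprintf("<ahrs_solution> %d lines, source = %s\n",
              length(x$t), x$pose_source))
  invisible(x)
}

#' Write a trajectory or AHRS solution to CSV
#'
#' Columns `t, x, y, z, roll, pitch, yaw` (radians).
#'
#' @param x a `trajectory` or `ahrs_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(x, path) {
  df <- data.frame(t = x$t, x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
                   roll = x$att[, 1], pitch = x$att[, 2], yaw = x$att[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose CSV written by [write_pose_csv()]
#'
#' @param path file path.
#' @return an `ahrs_solution`-classed pose table usable wherever a pose
#'   source is accepted.
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(
    list(t = df$t, pos = as.matrix(df[, c("x", "y", "z")]),
         att = as.matrix(df[, c("roll", "pitch", "yaw")]),
         cov = NULL, nis = NULL, pose_source = "file"),
    class = "ahrs_solution")
}
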