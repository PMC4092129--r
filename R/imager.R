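#' Pushbroom sensor model
#'
#' The sensor images one across-track line of `n_detectors` pixels per
#' integration period; the platform's forward motion supplies the
#' along-track dimension. Default geometry is back-derived from a 220 m
#' swath at 300 m height; the detector count is set so that the default
#' flight (0.5 m along-track at 65 km/h) lands in the 5-8 pixels/m^2
#' density regime.
#'
#' @param n_detectors across-track detector count.
#' @param fov full across-track field of view, rad.
#' @param n_bands number of spectral bands.
#' @param t_int integration time per line, s.
#' @return object of class `sensor_model`.
#' @export
sensor_model <- function(n_detectors = 640, fov = 2 * atan(110 / 300),
                         n_bands = 200, t_int = 0.0277) {
  stopifnot(n_detectors >= 2, fov > 0, fov < pi, n_bands >= 1, t_int > 0)
  structure(list(n_detectors = as.integer(n_detectors), fov = fov,
                 n_bands = as.integer(n_bands), t_int = t_int),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> %d detectors, FOV %.1f deg, %d bands, t_int %.4f s\n",
              x$n_detectors, rad2deg(x$fov), x$n_bands, x$t_int))
  invisible(x)
}

#' Swath width on flat ground
#'
#' @param sensor a [sensor_model].
#' @param h height above ground, m.
#' @return swath width in m (`2 h tan(FOV/2)`).
#' @export
swath_width <- function(sensor, h) 2 * h * tan(sensor$fov / 2)

# Body-to-NED rotation, aerospace order Rz(yaw) Ry(pitch) Rx(roll).
# Body axes: x forward (north when yaw = 0), y right (east), z down.
attitude_matrix <- function(roll, pitch, yaw) {
  cr <- cos(roll); sr <- sin(roll)
  cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  matrix(c(
    cy * cp, cy * sp * sr - sy * cr, cy * sp * cr + sy * sr,
    sy * cp, sy * sp * sr + cy * cr, sy * sp * cr - cy * sr,
    -sp,     cp * sr,                cp * cr), 3, 3, byrow = TRUE)
}

# across-track view angles of detector centers: extreme detectors sit at
# +/- FOV/2, so the swath spans exactly 2 h tan(FOV/2)
detector_angles <- function(sensor, d = seq_len(sensor$n_detectors)) {
  sensor$fov * ((d - 1) / (sensor$n_detectors - 1) - 0.5)
}

# unit ray directions in map ENU coordinates for across-track angles
# `alpha` under one pose; returns n x 3 matrix
ray_directions <- function(att, alpha) {
  R <- attitude_matrix(att[1], att[2], att[3])
  body <- rbind(0, sin(alpha), cos(alpha))   # z down, y right
  ned <- R %*% body
  cbind(x = ned[2, ], y = ned[1, ], z = -ned[3, ], deparse.level = 0)
}

#' Line of sight of one detector
#'
#' @param pos camera position `c(x, y, z)` in map coordinates (m).
#' @param att attitude `c(roll, pitch, yaw)` in rad.
#' @param detector detector index in `1..n_detectors`.
#' @param sensor a [sensor_model].
#' @return list with `origin` (position) and `direction` (unit vector,
#'   map ENU frame; nadir is `c(0, 0, -1)`).
#' @export
line_of_sight <- function(pos, att, detector, sensor) {
  if (detector < 1 || detector > sensor$n_detectors) {
    stop_gyrospec("detector index out of range", "gyrospec_param_error")
  }
  dir <- ray_directions(att, detector_angles(sensor, detector))[1, ]
  list(origin = as.numeric(pos), direction = as.numeric(dir))
}

#' Acquire a pushbroom cube over a scene
#'
#' Forward model of line-scan acquisition: for every (line, detector)
#' pair the ground footprint (across-track instantaneous field of view
#' times the along-track travel `v * t_int`) is point-sampled on the
#' fine grid, and the pixel spectrum is the area-weighted linear mixture
#' of the per-patch spectra falling inside the footprint, plus additive
#' Gaussian noise with standard deviation `mean(signal) / snr`.
#' Footprints use the true trajectory; geocorrection later uses the
#' estimated one.
#'
#' @param scene a [scene] with class and patch maps.
#' @param lib a [spectral_library].
#' @param traj a [simulate_trajectory()] result.
#' @param sensor a [sensor_model].
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param seed integer seed (patch spectrum draws + sensor noise).
#' @return object of class `pushbroom_cube`: `data` array
#'   `[lines, detectors, bands]` (`NA` where the footprint leaves the
#'   scene), `t`, `sensor`, `band_centers`, `traj`.
#' @export
acquire_cube <- function(scene, lib, traj, sensor = sensor_model(),
                         snr = 100, seed = 1L) {
  stopifnot(inherits(scene, "scene"), !is.null(scene$patch_map),
            inherits(lib, "spectral_library"), inherits(traj, "trajectory"))
  L <- length(traj$t); D <- sensor$n_detectors
  B <- length(lib$band_centers)
  pt <- scene$patch_table
  g <- scene$g_fine
  with_seed(seed, {
    # one spectrum per patch: endmember mixture at the patch condition
    # plus band-correlated noise
    spectra <- t(vapply(seq_len(nrow(pt)), function(i) {
      cl <- pt$class[i]
      base <- (1 - pt$condition[i]) * lib$vigorous[, cl] +
        pt$condition[i] * lib$stressed[, cl]
      s <- lib$sigma[[cl]]
      if (s > 0) base <- base + s * smooth_noise(B, lib$smooth_bands)
      pmin(pmax(base, 0), 1)
    }, numeric(B)))

    # detector boundary angles: half an IFOV beyond each center
    ifov <- sensor$fov / (D - 1)
    edges <- c(detector_angles(sensor) - ifov / 2,
               detector_angles(sensor, D) + ifov / 2)
    k_c <- max(1L, ceiling(traj$h * ifov / g))          # across samples
    k_a <- max(1L, ceiling(traj$v * traj$t_int / g))    # along samples
    S <- k_a * k_c
    u <- (seq_len(k_c) - 0.5) / k_c
    s_al <- ((seq_len(k_a) - 0.5) / k_a - 0.5) * traj$v * traj$t_int

    data <- array(NA_real_, dim = c(L, D, B))
    P <- nrow(pt)
    det_f <- factor(rep(seq_len(D), each = S), levels = seq_len(D))
    for (l in seq_len(L)) {
      ep <- project_rays(matrix(traj$pos[l, ], D + 1, 3, byrow = TRUE),
                         ray_directions(traj$att[l, ], edges), scene)
      # edge rays falling outside the scene poison only their own
      # detectors (NA footprints -> nodata pixels), not the whole line
      x0 <- ep[seq_len(D), 1]; y0 <- ep[seq_len(D), 2]
      dx <- ep[2:(D + 1), 1] - x0; dy <- ep[2:(D + 1), 2] - y0
      # sample grid: across offsets u within each detector footprint,
      # along offsets s_al along the track direction (map +y)
      px <- rep(x0, each = S) + rep(dx, each = S) * rep(rep(u, k_a), D)
      py <- rep(y0, each = S) + rep(dy, each = S) * rep(rep(u, k_a), D) +
        rep(rep(s_al, each = k_c), D)
      rc <- point_to_cell(scene, px, py)
      pid <- rep(NA_integer_, length(px))
      ok <- !is.na(rc[, 1])
      pid[ok] <- scene$patch_map[cbind(rc[ok, 1], rc[ok, 2])]
      cnt <- table(det_f[!is.na(pid)], factor(pid[!is.na(pid)], levels = seq_len(P)))
      n_in <- rowSums(cnt)
      good <- n_in == S     # any out-of-scene sample -> nodata pixel
      if (any(good)) {
        W <- unclass(cnt)[good, , drop = FALSE] / S
        px_spec <- W %*% spectra
        # pixel-level within-patch heterogeneity (band-correlated)
        if (lib$sigma_within > 0) {
          px_spec <- px_spec + lib$sigma_within *
            t(smooth_noise_mat(B, sum(good), lib$smooth_bands))
        }
        data[l, good, ] <- px_spec
      }
    }
    if (is.finite(snr)) {
      sig <- mean(data, na.rm = TRUE)
      data <- data + array(stats::rnorm(length(data), 0, sig / snr), dim(data))
    }
    structure(
      list(data = data, t = traj$t, sensor = sensor,
           band_centers = lib$band_centers, traj = traj,
           snr = snr, seed = seed),
      class = "pushbroom_cube")
  })
}

#' @export
print.pushbroom_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pushbroom_cube> %d lines x %d detectors x %d bands, %.1f%% nodata\n",
              d[1], d[2], d[3], 100 * mean(is.na(x$data[, , 1]))))
  invisible(x)
}

#' Ground pixel density of a configuration
#'
#' @param sensor a [sensor_model].
#' @param v ground speed m/s.
#' @param h height m.
#' @return pixels per square meter
#'   (`1 / (along_track_res * across_track_res)`).
#' @export
pixel_density <- function(sensor, v = 65 / 3.6, h = 300) {
  along <- v * sensor$t_int
  across <- swath_width(sensor, h) / sensor$n_detectors
  1 / (along * across)
}
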