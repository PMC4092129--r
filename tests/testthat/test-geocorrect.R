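test_that("ray-DTM intersection matches closed-form solutions", {
  sc <- generate_dtm(c(200, 200), "flat", 0, g_fine = 1, xmin = -100, ymin = -100)
  # nadir from 300 m over flat ground
  p <- intersect_dtm(c(0, 0, 300), c(0, 0, -1), sc)
  expect_equal(p, c(0, 0, 0), tolerance = 1e-3)

  # 5 degree tilt: x offset 300 tan(5 deg) = 26.2467 m
  d <- c(sin(gyrospec:::deg2rad(5)), 0, -cos(gyrospec:::deg2rad(5)))
  p5 <- intersect_dtm(c(0, 0, 300), d, sc)
  expect_equal(p5[1], 300 * tan(gyrospec:::deg2rad(5)), tolerance = 1e-2)
  expect_equal(p5[1], 26.2467, tolerance = 1e-2)

  # inclined plane z = a x + b y + c vs the analytic ray-plane solution
  a <- 0.2; b <- -0.1; cc <- 3
  X <- outer(rep(1, 200), seq(-99.5, 99.5))
  Y <- outer(seq(99.5, -99.5), rep(1, 200))
  sci <- gyrospec:::new_scene(a * X + b * Y + cc, 1, xmin = -100, ymin = -100)
  for (dir in list(c(0, 0, -1), c(0.1, 0.05, -1), c(-0.2, 0.1, -1))) {
    dir <- dir / sqrt(sum(dir^2))
    o <- c(5, -7, 300)
    s <- (a * o[1] + b * o[2] + cc - o[3]) / (dir[3] - a * dir[1] - b * dir[2])
    expect_equal(intersect_dtm(o, dir, sci), o + s * dir, tolerance = 1e-2)
  }

  # ray leaving the extent before intersecting
  expect_null(intersect_dtm(c(0, 0, 300), c(1, 0, -0.1), sc))
  expect_error(intersect_dtm(c(0, 0, 300), c(0, 0, 1), sc),
               class = "gyrospec_param_error")
})

test_that("vectorized projection agrees with the scalar intersector", {
  sc <- generate_dtm(c(120, 120), "smooth_random", 8, seed = 3, g_fine = 1,
                     xmin = -60, ymin = -60)
  set.seed(10)
  n <- 40
  origins <- cbind(runif(n, -20, 20), runif(n, -20, 20), 300)
  dirs <- cbind(runif(n, -0.1, 0.1), runif(n, -0.1, 0.1), -1)
  gp <- gyrospec:::project_rays(origins, dirs, sc)
  for (i in seq_len(n)) {
    ref <- intersect_dtm(origins[i, ], dirs[i, ], sc)
    expect_equal(gp[i, ], ref, tolerance = 5e-3,
                 ignore_attr = TRUE)
  }
})

make_ortho_fixture <- function(sigma_deg = 0, seed = 1, n_bands = 4) {
  lib <- flat_library(n_bands = n_bands, levels = c(0.2, 0.6))
  sc <- uniform_scene(400, n_classes = 2)
  tr <- test_traj(sc, sigma_deg = sigma_deg, seed = seed)
  sn <- test_sensor(n_detectors = 21, half_swath = 8, n_bands = n_bands)
  cube <- acquire_cube(sc, lib, tr, sn, snr = Inf, seed = 1)
  list(lib = lib, sc = sc, tr = tr, sn = sn, cube = cube)
}

test_that("ideal flight with true pose geolocates to a fraction of a pixel", {
  f <- make_ortho_fixture(sigma_deg = 0)
  gp <- project_cube(f$cube, f$tr, f$sc)
  # closed-form footprint centers for a nadir-looking ideal flight
  D <- f$sn$n_detectors
  alpha <- gyrospec:::detector_angles(f$sn)
  exp_x <- rep(f$tr$pos[1, 1], length(f$tr$t) * D) +
    rep(300 * tan(alpha), length(f$tr$t))
  exp_y <- rep(f$tr$pos[, 2], each = D)
  err <- sqrt((gp[, 1] - exp_x)^2 + (gp[, 2] - exp_y)^2)
  expect_lt(mean(err, na.rm = TRUE), 0.5 / 10)

  ortho <- parametric_geocorrect(f$cube, f$tr, f$sc, 0.5)
  expect_gt(mean(ortho$mask), 0.3)
  # geotransform round trip: cell centers map back to their own indices
  ex <- ortho$extent
  r <- 7; c <- 11
  x <- ex[["xmin"]] + (c - 0.5) * 0.5
  y <- ex[["ymax"]] - (r - 0.5) * 0.5
  expect_equal(floor((x - ex[["xmin"]]) / 0.5) + 1, c)
  expect_equal(floor((ex[["ymax"]] - y) / 0.5) + 1, r)
})

test_that("spectra pass through geocorrection bit-unchanged", {
  f <- make_ortho_fixture(sigma_deg = 1, seed = 4)
  ortho <- parametric_geocorrect(f$cube, f$tr, f$sc, 0.5)
  cube_vals <- unique(as.numeric(f$cube$data[, , 1]))
  ortho_vals <- unique(as.numeric(ortho$data[, , 1]))
  ortho_vals <- ortho_vals[!is.na(ortho_vals)]
  expect_true(all(ortho_vals %in% cube_vals))
  # provenance: every valid cell names a source cube pixel
  expect_true(all(!is.na(ortho$source_pixel[ortho$mask])))
  expect_true(all(is.na(ortho$source_pixel[!ortho$mask])))
})

test_that("true pose beats dead-reckoned pose after perturbed flight", {
  f <- make_ortho_fixture(sigma_deg = 1, seed = 5)
  st <- simulate_sensors(f$tr, seed = 6)
  ahrs <- kalman_fuse(st)
  dr <- dead_reckon(st)
  gp_true <- project_cube(f$cube, f$tr, f$sc)
  gp_ahrs <- project_cube(f$cube, ahrs, f$sc)
  gp_dr <- project_cube(f$cube, dr, f$sc)
  e_ahrs <- sqrt(rowSums((gp_ahrs[, 1:2] - gp_true[, 1:2])^2))
  e_dr <- sqrt(rowSums((gp_dr[, 1:2] - gp_true[, 1:2])^2))
  expect_lt(mean(e_ahrs, na.rm = TRUE), mean(e_dr, na.rm = TRUE))
})

test_that("empty overlap raises an explicit error", {
  f <- make_ortho_fixture()
  cube <- f$cube
  cube$data[] <- NA  # every pixel nodata
  expect_error(parametric_geocorrect(cube, f$tr, f$sc, 0.5),
               class = "gyrospec_empty_output_error")
})

test_that("GCP warp: identity, translation recovery and shear", {
  f <- make_ortho_fixture()
  ortho <- parametric_geocorrect(f$cube, f$tr, f$sc, 0.5)
  # aligned GCPs: identity warp, image unchanged
  g0 <- data.frame(x_img = c(2, 15, 3, 17), y_img = c(2, 3, 16, 18))
  g0$x_ref <- g0$x_img; g0$y_ref <- g0$y_img
  out0 <- gcp_residual_correct(ortho, g0, "affine")
  expect_equal(out0$data, ortho$data)
  expect_equal(out0$gcp$rms_after, 0, tolerance = 1e-9)

  # injected pure translation (+3, -2) recovered to machine precision
  g1 <- g0
  g1$x_img <- g1$x_ref - 3
  g1$y_img <- g1$y_ref + 2
  out1 <- gcp_residual_correct(ortho, g1, "affine")
  expect_equal(unname(out1$gcp$forward_x), c(3, 1, 0), tolerance = 1e-6)
  expect_equal(unname(out1$gcp$forward_y), c(-2, 0, 1), tolerance = 1e-6)
  expect_lt(out1$gcp$rms_after, 1e-6)
  expect_lt(out1$gcp$rms_after, out1$gcp$rms_before)

  # affine shear cannot be explained by translation alone
  g2 <- g0
  g2$x_img <- g2$x_ref + 0.2 * g2$y_ref
  out2 <- gcp_residual_correct(ortho, g2, "affine")
  expect_lt(out2$gcp$rms_after, 1e-6)
  best_translation <- sqrt(mean(
    (g2$x_ref - g2$x_img - mean(g2$x_ref - g2$x_img))^2 +
      (g2$y_ref - g2$y_img - mean(g2$y_ref - g2$y_img))^2))
  expect_gt(best_translation, 1e-3)

  expect_error(gcp_residual_correct(ortho, g0[1:2, ], "affine"),
               class = "gyrospec_underdetermined_error")
  expect_error(gcp_residual_correct(ortho, g0[c(1, 1, 2, 3), ], "affine"),
               class = "gyrospec_param_error")

  # polynomial model needs six points and also never worsens the fit
  g3 <- rbind(g0, data.frame(x_img = c(9, 12), y_img = c(9, 5),
                             x_ref = c(9, 12), y_ref = c(9, 5)))
  g3$x_img <- g3$x_img + 0.01 * g3$y_img^2 / 20
  out3 <- gcp_residual_correct(ortho, g3, "poly2")
  expect_lte(out3$gcp$rms_after, out3$gcp$rms_before + 1e-12)
  expect_error(gcp_residual_correct(ortho, g3[1:5, ], "poly2"),
               class = "gyrospec_underdetermined_error")
})

test_that("ortho ENVI output round trips with its map info", {
  f <- make_ortho_fixture()
  ortho <- parametric_geocorrect(f$cube, f$tr, f$sc, 0.5)
  p <- file.path(tempdir(), "ortho.bsq")
  write_ortho_envi(ortho, p)
  back <- read_envi(p)
  expect_equal(back$data, ortho$data, tolerance = 1e-6)
  expect_equal(as.numeric(back$map_info[4]), ortho$extent[["xmin"]])
})
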