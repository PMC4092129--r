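#' Default pipeline configuration
#'
#' Desk-scale defaults: a 60 m x 100 m scene on a 0.05 m fine grid,
#' a 65 km/h / 300 m flight with 1-degree AR(1) attitude wander, a
#' narrow-swath sensor cut down from the full 220 m swath geometry so
#' the whole simulation fits in memory (same 0.5 m along-track and
#' 5-8 px/m^2 density regime), AHRS-based geocorrection to a 0.5 m
#' grid, full-band SVM classification and a 100 + 250 pixel validation
#' sample at the 0.125 m^2 detection threshold.
#'
#' @param seed master seed; every stochastic stage gets a sub-seed
#'   derived from it by [derive_seed()].
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    scene = list(
      width_m = 60, length_m = 100, g_fine = 0.05,
      relief = "smooth_random", amplitude = 5,
      n_disc_patches = 16, disc_radius_range = c(1, 4),
      n_tendrils = 10, tendril_width = 0.2, block_size = 5,
      n_bands = 200, sigma_patch = 0.003, sigma_within = 0.006,
      smooth_bands = 10),
    flight = list(
      v = 65 / 3.6, h = 300, t_int = 0.0277,
      sigma_att_deg = 1, rho = 0.95,
      sigma_gps = 2, sigma_gyro = 0.005, sigma_bias = 1e-4,
      gps_rate = 20, imu_rate = 100, att_rate = 10,
      sigma_att_meas_deg = 0.1),
    sensor = list(
      n_detectors = 96, half_swath_m = 15, snr = 100),
    geocorrection = list(
      pixel_size = 0.5, pose_source = "ahrs"),
    classification = list(
      n_per_class = 80, mixed_fraction = 0.3,
      cost = c(1, 10, 100), gamma = NULL, folds = 5,
      standardize = FALSE),
    validation = list(
      n_target = 100, n_other = 250, threshold_fraction = 0.5))
}

#' Validate a pipeline configuration
#'
#' Schema check run before any stage: block presence, types and value
#' ranges. Unknown keys are rejected to catch typos.
#'
#' @param config nested configuration list.
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  need <- names(ref)
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop_gyrospec(paste("config missing blocks:", paste(miss, collapse = ", ")),
                  "gyrospec_config_error")
  }
  for (blk in setdiff(need, "seed")) {
    unknown <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(unknown)) {
      stop_gyrospec(sprintf("unknown keys in '%s': %s", blk,
                            paste(unknown, collapse = ", ")),
                    "gyrospec_config_error")
    }
  }
  ck <- function(cond, msg) if (!cond) stop_gyrospec(msg, "gyrospec_config_error")
  s <- config$scene; f <- config$flight
  ck(s$width_m > 0 && s$length_m > 0 && s$g_fine > 0, "scene dimensions must be positive")
  ck(f$v > 0 && f$h > 0 && f$t_int > 0, "flight v, h, t_int must be positive")
  ck(abs(f$rho) < 1, "flight rho must satisfy |rho| < 1")
  ck(config$sensor$n_detectors >= 2, "need at least 2 detectors")
  ck(config$geocorrection$pixel_size > 0, "pixel size must be positive")
  ck(config$geocorrection$pose_source %in% c("ahrs", "true", "dead_reckoning"),
     "pose_source must be ahrs, true or dead_reckoning")
  v <- config$validation
  ck(v$n_target > 0 && v$n_other > 0, "validation stratum sizes must be positive")
  ck(v$threshold_fraction > 0 && v$threshold_fraction <= 1,
     "threshold fraction must be in (0, 1]")
  invisible(config)
}

#' Read a pipeline configuration from JSON
#'
#' Values present in the file override [default_config()]; everything
#' else keeps its default.
#'
#' @param path JSON file path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Run the full simulation and detection pipeline
#'
#' Scene generation, flight and sensor simulation, AHRS fusion, cube
#' acquisition, geocorrection, classification and accuracy validation,
#' each stage seeded from the master seed. With `out_dir` set, all
#' intermediate artifacts are written (ENVI cubes, ASCII grids, CSVs,
#' JSON report) together with a provenance manifest; re-running the
#' same config byte-reproduces the report.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir optional output directory for artifacts.
#' @param gcps optional GCP data.frame passed to
#'   [gcp_residual_correct()] after parametric geocorrection.
#' @param verbose print stage progress.
#' @return list with `report` ([accuracy_metrics()] result),
#'   `error_matrix`, `scene`, `library`, `trajectory`, `ahrs`, `ortho`,
#'   `classified`, `reference`, `labels_train`, `labels_validate`,
#'   `config` and (if written) `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         gcps = NULL, verbose = TRUE) {
  validate_config(config)
  master <- config$seed
  manifest <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- character(0)
  emit <- function(path, stage, seed) {
    manifest[[length(manifest) + 1L]] <<- list(
      file = basename(path), stage = stage, seed = seed,
      md5 = unname(tools::md5sum(path)))
    artifacts <<- c(artifacts, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_gyrospec(sprintf(
        "pipeline stage '%s' failed: %s [artifacts so far: %s]",
        name, conditionMessage(e),
        if (length(artifacts)) paste(artifacts, collapse = ", ") else "none"),
        "gyrospec_stage_error")
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scene

  say("stage scene: %g x %g m @ %g m", sc$width_m, sc$length_m, sc$g_fine)
  seed_scene <- derive_seed(master, "scene")
  seed_patch <- derive_seed(master, "patches")
  scene <- stage("scene", {
    shp <- c(round(sc$length_m / sc$g_fine), round(sc$width_m / sc$g_fine))
    s <- generate_dtm(shp, sc$relief, sc$amplitude, seed = seed_scene,
                      g_fine = sc$g_fine)
    lib0 <- default_spectral_library(sc$n_bands, sigma = sc$sigma_patch,
                                     sigma_within = sc$sigma_within,
                                     smooth_bands = sc$smooth_bands)
    generate_patch_map(s, sc$n_disc_patches, sc$disc_radius_range,
                       sc$n_tendrils, sc$tendril_width,
                       background_classes = lib0$classes[-1],
                       target_class = lib0$classes[1],
                       block_size = sc$block_size, seed = seed_patch)
  })
  lib <- default_spectral_library(sc$n_bands, sigma = sc$sigma_patch,
                                     sigma_within = sc$sigma_within,
                                  smooth_bands = sc$smooth_bands)
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "dtm.asc")
    write_ascii_grid(scene$dtm, p, sc$g_fine)
    emit(p, "scene", seed_scene)
    p <- file.path(out_dir, "class_map.asc")
    write_ascii_grid(scene$class_map, p, sc$g_fine)
    emit(p, "scene", seed_patch)
    p <- file.path(out_dir, "spectral_library.csv")
    write_spectral_library_csv(lib, p)
    emit(p, "scene", seed_scene)
  }

  fl <- config$flight
  seed_flight <- derive_seed(master, "flight")
  seed_sensors <- derive_seed(master, "sensors")
  say("stage flight: %.0f m line at %.1f m/s, h = %.0f m", sc$length_m, fl$v, fl$h)
  traj <- stage("flight", simulate_trajectory(
    sc$length_m, v = fl$v, h = fl$h, t_int = fl$t_int,
    sigma_att = deg2rad(fl$sigma_att_deg), rho = fl$rho,
    x0 = sc$width_m / 2, y0 = 0, seed = seed_flight))
  streams <- stage("sensors", simulate_sensors(
    traj, sigma_gps = fl$sigma_gps, sigma_gyro = fl$sigma_gyro,
    sigma_bias = fl$sigma_bias, gps_rate = fl$gps_rate,
    imu_rate = fl$imu_rate, att_rate = fl$att_rate,
    sigma_att_meas = deg2rad(fl$sigma_att_meas_deg), seed = seed_sensors))
  ahrs <- stage("ahrs", kalman_fuse(streams))
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "trajectory.csv")
    write_pose_csv(traj, p); emit(p, "flight", seed_flight)
    p <- file.path(out_dir, "ahrs.csv")
    write_pose_csv(ahrs, p); emit(p, "ahrs", seed_sensors)
  }

  sn <- config$sensor
  sensor <- sensor_model(n_detectors = sn$n_detectors,
                         fov = 2 * atan(sn$half_swath_m / fl$h),
                         n_bands = sc$n_bands, t_int = fl$t_int)
  seed_cube <- derive_seed(master, "cube")
  say("stage acquire: %d lines x %d detectors x %d bands",
      length(traj$t), sensor$n_detectors, sensor$n_bands)
  cube <- stage("acquire", acquire_cube(scene, lib, traj, sensor,
                                        snr = sn$snr, seed = seed_cube))
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "cube.bil")
    write_envi(cube$data, p, "bil", wavelengths = lib$band_centers)
    emit(p, "acquire", seed_cube)
    emit(paste0(p, ".hdr"), "acquire", seed_cube)
  }

  gc_cfg <- config$geocorrection
  pose <- switch(gc_cfg$pose_source,
                 true = traj, ahrs = ahrs,
                 dead_reckoning = dead_reckon(streams))
  say("stage geocorrect: %s pose, %.2g m grid", gc_cfg$pose_source,
      gc_cfg$pixel_size)
  ortho <- stage("geocorrect",
                 parametric_geocorrect(cube, pose, scene, gc_cfg$pixel_size))
  if (!is.null(gcps)) {
    ortho <- stage("gcp", gcp_residual_correct(ortho, gcps))
  }
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "ortho.bsq")
    write_ortho_envi(ortho, p)
    emit(p, "geocorrect", master)
    emit(paste0(p, ".hdr"), "geocorrect", master)
  }

  coverage <- stage("reference", rasterize_coverage(
    scene, gc_cfg$pixel_size, target_class = scene$classes[1]))
  reference <- apply_detection_threshold(coverage,
                                         config$validation$threshold_fraction)

  cl <- config$classification
  seed_train <- derive_seed(master, "training")
  seed_svm <- derive_seed(master, "svm")
  say("stage classify: %d px/class, cv grid %d x %d", cl$n_per_class,
      length(cl$cost), max(1L, length(cl$gamma)))
  labels <- stage("training", select_training_pixels(
    ortho, coverage, scene, n_per_class = cl$n_per_class,
    mixed_fraction = cl$mixed_fraction,
    threshold_fraction = config$validation$threshold_fraction,
    seed = seed_train))
  clf <- stage("svm", train_svm(labels, ortho, cost = cl$cost,
                                gamma = cl$gamma, folds = cl$folds,
                                standardize = cl$standardize,
                                seed = seed_svm))
  cmap <- stage("predict", predict_map(clf, ortho))
  classified <- collapse_to_target(cmap, scene$classes[1])
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "training_labels.csv")
    write_labels_csv(labels, p); emit(p, "training", seed_train)
    p <- file.path(out_dir, "classified.asc")
    write_ascii_grid(cmap$map, p, gc_cfg$pixel_size)
    emit(p, "predict", seed_svm)
  }

  vd <- config$validation
  seed_val <- derive_seed(master, "validation")
  say("stage validate: %d + %d pixels", vd$n_target, vd$n_other)
  val <- stage("validate", sample_validation_pixels(
    classified, reference, n_target = vd$n_target, n_other = vd$n_other,
    exclude = labels, seed = seed_val))
  em <- stage("validate", build_error_matrix(val, classified, reference))
  report <- accuracy_metrics(em)
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "validation_labels.csv")
    write_labels_csv(val, p); emit(p, "validate", seed_val)
    p <- file.path(out_dir, "report.json")
    write_accuracy_json(report, p); emit(p, "validate", seed_val)
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  }
  say("overall accuracy %.1f%%, kappa %.3f", report$overall, report$kappa)
  list(report = report, error_matrix = em, scene = scene, library = lib,
       trajectory = traj, ahrs = ahrs, ortho = ortho, classifier = clf,
       classified = classified, classified_map = cmap,
       coverage = coverage, reference = reference,
       labels_train = labels, labels_validate = val,
       config = config,
       manifest = if (length(manifest)) manifest else NULL)
}

#' Command-line entry point
#'
#' Dispatches `gyrospec run --config cfg.json --out DIR [--seed N]` and
#' `gyrospec validate --classified MAP.asc --reference REF.asc
#' [--n-target N] [--n-other N] [--seed N] [--out report.json]`.
#' Installed as the `inst/cli/gyrospec` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
gyrospec_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (!length(i)) return(default)
    args[i[1] + 1]
  }
  if (!length(args)) {
    cat("usage: gyrospec <run|validate> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  if (cmd == "run") {
    cfg <- if (!is.null(opt("config"))) read_config(opt("config")) else default_config()
    if (!is.null(opt("seed"))) cfg$seed <- as.integer(opt("seed"))
    out <- opt("out", "gyrospec_run")
    res <- run_pipeline(cfg, out_dir = out)
    cat(format_accuracy_report(res$report), sep = "\n")
    return(invisible(0L))
  }
  if (cmd == "validate") {
    cl <- read_ascii_grid(opt("classified"))
    rf <- read_ascii_grid(opt("reference"))
    classified <- cl$m == 1
    reference <- rf$m == 1
    val <- sample_validation_pixels(
      classified, reference,
      n_target = as.integer(opt("n-target", "100")),
      n_other = as.integer(opt("n-other", "250")),
      seed = as.integer(opt("seed", "1")))
    rep <- accuracy_metrics(build_error_matrix(val, classified, reference))
    cat(format_accuracy_report(rep), sep = "\n")
    if (!is.null(opt("out"))) write_accuracy_json(rep, opt("out"))
    return(invisible(0L))
  }
  cat(sprintf("unknown command '%s'\n", cmd))
  invisible(1L)
}
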