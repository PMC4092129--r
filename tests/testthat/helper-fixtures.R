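# Shared fixtures, all built in code.

# Tiny two-class spectral library with constant spectra and no
# variability: mixing weights are exactly recoverable from any band.
flat_library <- function(n_bands = 8, levels = c(0.2, 0.6)) {
  wl <- seq(400, 900, length.out = n_bands)
  em <- sapply(levels, function(v) rep(v, n_bands))
  spectral_library(wl, em, em, classes = paste0("c", seq_along(levels)),
                   sigma = 0, sigma_within = 0, smooth_bands = 0)
}

# Scene with a hand-set class/patch map (one patch per class, flat DTM).
manual_scene <- function(class_map, g_fine = 0.05, dtm = NULL,
                         classes = NULL, conditions = NULL) {
  if (is.null(dtm)) dtm <- matrix(0, nrow(class_map), ncol(class_map))
  sc <- gyrospec:::new_scene(dtm, g_fine)
  ids <- sort(unique(as.integer(class_map)))
  if (is.null(classes)) classes <- paste0("c", seq_len(max(ids)))
  if (is.null(conditions)) conditions <- rep(0, max(ids))
  sc$class_map <- class_map
  sc$patch_map <- class_map  # one patch per class
  sc$classes <- classes
  sc$patch_table <- data.frame(id = seq_len(max(ids)),
                               class = classes[seq_len(max(ids))],
                               condition = conditions)
  sc
}

# Wide flat single-or-two-class scene centered under a nadir track.
uniform_scene <- function(size_cells = 400, g_fine = 0.05, n_classes = 1) {
  cm <- matrix(1L, size_cells, size_cells)
  if (n_classes == 2) cm[, seq_len(size_cells / 2)] <- 2L
  manual_scene(cm, g_fine = g_fine)
}

# Small sensor for fast acquisitions.
test_sensor <- function(n_detectors = 11, half_swath = 5, h = 300,
                        n_bands = 8, t_int = 0.0277) {
  sensor_model(n_detectors = n_detectors, fov = 2 * atan(half_swath / h),
               n_bands = n_bands, t_int = t_int)
}

# Short ideal or perturbed trajectory over a scene's center line.
test_traj <- function(scene, length_m = NULL, sigma_deg = 0, seed = 1,
                      v = 65 / 3.6, h = 300, t_int = 0.0277) {
  ex <- scene$extent
  if (is.null(length_m)) length_m <- ex[["ymax"]] - ex[["ymin"]]
  simulate_trajectory(length_m, v = v, h = h, t_int = t_int,
                      sigma_att = gyrospec:::deg2rad(sigma_deg), rho = 0.95,
                      x0 = (ex[["xmin"]] + ex[["xmax"]]) / 2,
                      y0 = ex[["ymin"]], seed = seed)
}

rmse <- function(e) sqrt(mean(e^2))

# Scaled-down pipeline config used by determinism/integration tests.
small_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$scene$width_m <- 30
  cfg$scene$length_m <- 40
  cfg$scene$n_bands <- 40
  cfg$scene$n_disc_patches <- 8
  cfg$scene$n_tendrils <- 4
  cfg$sensor$n_detectors <- 48
  cfg$sensor$half_swath_m <- 8
  cfg$classification$n_per_class <- 30
  cfg$classification$cost <- 10          # skip the CV grid for speed
  cfg$classification$gamma <- NULL
  cfg$validation$n_target <- 40
  cfg$validation$n_other <- 100
  cfg
}
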