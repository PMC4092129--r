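#' Spectral library with a two-endmember variability model
#'
#' A spectral library holds, for each terrain class, a "vigorous" and a
#' "stressed" reflectance endmember on a common wavelength grid, plus a
#' band-correlated noise level. Spectra for individual patches are drawn
#' by linear interpolation between the two endmembers at a `condition`
#' in `[0, 1]` (0 = vigorous, 1 = stressed) with smoothed Gaussian
#' perturbation, clipped to `[0, 1]`. This reproduces the qualitative
#' structure of field spectra of clonal succulent patches: strong
#' within-class variability along a vigour/water-stress gradient and
#' high between-class similarity.
#'
#' @param band_centers numeric vector of band-center wavelengths (nm),
#'   strictly increasing.
#' @param vigorous,stressed numeric matrices, one column per class and
#'   one row per band, reflectance in `[0, 1]`.
#' @param classes character vector of class names (column names).
#' @param sigma per-class standard deviation of the band-correlated
#'   patch-level perturbation (reflectance units); recycled to the
#'   number of classes. Kept small: it shifts a whole patch coherently.
#' @param sigma_within standard deviation of the band-correlated
#'   pixel-level perturbation applied during acquisition; models the
#'   tonal heterogeneity visible inside real patches and is the larger
#'   of the two variability terms.
#' @param smooth_bands correlation length of both perturbations, in
#'   bands.
#' @return an object of class `spectral_library`.
#' @export
spectral_library <- function(band_centers, vigorous, stressed, classes,
                             sigma = 0.003, sigma_within = 0.006,
                             smooth_bands = 10) {
  band_centers <- as.numeric(band_centers)
  if (any(diff(band_centers) <= 0)) {
    stop_gyrospec("band centers must be strictly increasing", "gyrospec_band_error")
  }
  vigorous <- as.matrix(vigorous)
  stressed <- as.matrix(stressed)
  stopifnot(nrow(vigorous) == length(band_centers),
            nrow(stressed) == length(band_centers),
            ncol(vigorous) == length(classes),
            ncol(stressed) == length(classes))
  if (any(vigorous < 0 | vigorous > 1) || any(stressed < 0 | stressed > 1)) {
    stop_gyrospec("endmember reflectance must lie in [0, 1]", "gyrospec_band_error")
  }
  colnames(vigorous) <- classes
  colnames(stressed) <- classes
  sigma <- rep_len(sigma, length(classes))
  names(sigma) <- classes
  structure(
    list(band_centers = band_centers, classes = classes,
         vigorous = vigorous, stressed = stressed,
         sigma = sigma, sigma_within = sigma_within,
         smooth_bands = smooth_bands),
    class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d bands (%.0f-%.0f nm), %d classes: %s\n",
              length(x$band_centers), min(x$band_centers), max(x$band_centers),
              length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Parametric vegetation-like reflectance: visible chlorophyll/carotenoid
# features plus a logistic red edge to a near-infrared plateau and a
# weak water feature near 970 nm. Purely phenomenological.
veg_spectrum <- function(wl, green_amp = 0.06, red_amp = 0.0, nir = 0.45,
                         edge = 712, edge_width = 16, base = 0.035,
                         water_dip = 0.05) {
  vis <- base +
    green_amp * exp(-((wl - 552) / 32)^2) +
    red_amp * exp(-((wl - 645) / 45)^2) -
    0.015 * exp(-((wl - 430) / 25)^2)
  s <- 1 / (1 + exp(-(wl - edge) / edge_width))
  r <- vis + (nir - vis) * s
  r <- r - water_dip * nir * exp(-((wl - 970) / 22)^2)
  pmin(pmax(r, 0), 1)
}

# Non-vegetated continuum (litter / bare ground style): slowly rising.
soil_spectrum <- function(wl, lo = 0.08, hi = 0.32) {
  t <- (wl - min(wl)) / diff(range(wl))
  lo + (hi - lo) * t^0.8
}

#' Default five-class spectral library
#'
#' Target succulent (a *Carpobrotus*-like iceplant) plus four background
#' classes typical of a Mediterranean coastal habitat: two sclerophyll
#' shrubs, a conifer whose stressed endmember is withered needles, and a
#' succulent halophyte whose reddish stressed form is the classic
#' false-positive source for iceplant mapping. Defaults put the target's
#' nearest background class (the halophyte) spectrally closer to the
#' stressed target than the target's own vigorous and stressed
#' endmembers are to each other.
#'
#' @param n_bands number of spectral bands (default 200).
#' @param range wavelength range in nm (default 380-1000).
#' @param sigma patch-level perturbation standard deviation.
#' @param sigma_within pixel-level perturbation standard deviation.
#' @param smooth_bands perturbation correlation length in bands.
#' @return a [spectral_library].
#' @export
default_spectral_library <- function(n_bands = 200, range = c(380, 1000),
                                     sigma = 0.003, sigma_within = 0.006,
                                     smooth_bands = 10) {
  wl <- seq(range[1], range[2], length.out = n_bands)
  classes <- c("target_succulent", "shrub_lentisc", "shrub_juniper",
               "conifer_pine", "succulent_halophyte")
  vig <- cbind(
    veg_spectrum(wl, green_amp = 0.075, nir = 0.52, edge = 710),
    veg_spectrum(wl, green_amp = 0.045, nir = 0.42, edge = 716),
    veg_spectrum(wl, green_amp = 0.035, nir = 0.34, edge = 720),
    veg_spectrum(wl, green_amp = 0.05, nir = 0.46, edge = 714),
    veg_spectrum(wl, green_amp = 0.058, nir = 0.46, edge = 706,
                 water_dip = 0.11))
  str <- cbind(
    # water-stressed iceplant: reddish, collapsed NIR plateau
    veg_spectrum(wl, green_amp = 0.03, red_amp = 0.09, nir = 0.30,
                 edge = 700, edge_width = 26, water_dip = 0.02),
    veg_spectrum(wl, green_amp = 0.035, nir = 0.36, edge = 714),
    0.5 * veg_spectrum(wl, green_amp = 0.03, nir = 0.30, edge = 720) +
      0.5 * soil_spectrum(wl),              # juniper litter
    0.35 * veg_spectrum(wl, green_amp = 0.04, nir = 0.40, edge = 716) +
      0.65 * soil_spectrum(wl, 0.1, 0.35),  # withered needles
    # reddish halophyte: closest background to the stressed target in
    # spectral angle, but with a consistently deeper 970 nm water
    # feature (higher leaf water content), which keeps pure pixels
    # separable while sub-pixel mixtures stay confusable
    veg_spectrum(wl, green_amp = 0.05, red_amp = 0.055, nir = 0.36,
                 edge = 707, edge_width = 20, water_dip = 0.10))
  spectral_library(wl, vig, str, classes, sigma = sigma,
                   sigma_within = sigma_within, smooth_bands = smooth_bands)
}

#' Draw a patch spectrum from a library
#'
#' Linear mixture `(1 - condition) * vigorous + condition * stressed`
#' plus smoothed Gaussian noise with the class's `sigma`, clipped to
#' `[0, 1]`.
#'
#' @param lib a [spectral_library].
#' @param class class name.
#' @param condition scalar in `[0, 1]`; 0 = vigorous endmember, 1 =
#'   stressed endmember.
#' @param seed integer RNG seed.
#' @param sigma optional override of the class noise level.
#' @return numeric reflectance vector, one value per band.
#' @export
draw_spectrum <- function(lib, class, condition = 0, seed = 1L, sigma = NULL) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!class %in% lib$classes) {
    stop_gyrospec(sprintf("unknown class '%s'", class), "gyrospec_lookup_error")
  }
  stopifnot(length(condition) == 1L, condition >= 0, condition <= 1)
  if (is.null(sigma)) sigma <- lib$sigma[[class]]
  base <- (1 - condition) * lib$vigorous[, class] +
    condition * lib$stressed[, class]
  if (sigma > 0) {
    noise <- with_seed(seed, smooth_noise(length(base), lib$smooth_bands))
    base <- base + sigma * noise
  }
  pmin(pmax(base, 0), 1)
}

# Band-correlated unit-variance noise: white Gaussian convolved with a
# Gaussian kernel, rescaled to unit marginal standard deviation.
smooth_noise <- function(n, smooth_bands) {
  if (smooth_bands <= 0) return(stats::rnorm(n))
  half <- ceiling(3 * smooth_bands)
  k <- exp(-0.5 * ((-half:half) / smooth_bands)^2)
  k <- k / sqrt(sum(k^2))  # unit output variance for white input
  w <- stats::rnorm(n + 2 * half)
  as.numeric(stats::convolve(w, rev(k), type = "filter"))
}

# matrix of independent band-correlated noise columns (bands x m)
smooth_noise_mat <- function(n, m, smooth_bands) {
  if (m == 0) return(matrix(0, n, 0))
  if (smooth_bands <= 0) return(matrix(stats::rnorm(n * m), n, m))
  half <- ceiling(3 * smooth_bands)
  k <- exp(-0.5 * ((-half:half) / smooth_bands)^2)
  k <- k / sqrt(sum(k^2))
  w <- matrix(stats::rnorm((n + 2 * half) * m), n + 2 * half, m)
  f <- stats::filter(w, k, method = "convolution", sides = 2)
  matrix(f[(half + 1):(half + n), ], n, m)
}

#' Spectral angle between two spectra
#'
#' @param a,b numeric reflectance vectors of equal length.
#' @return angle in radians.
#' @export
spectral_angle <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

#' Write a spectral library to CSV
#'
#' One `wavelength_nm` column plus `<class>.vigorous` and
#' `<class>.stressed` columns.
#'
#' @param lib a [spectral_library].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_library_csv <- function(lib, path) {
  df <- data.frame(wavelength_nm = lib$band_centers, check.names = FALSE)
  for (cl in lib$classes) {
    df[[paste0(cl, ".vigorous")]] <- lib$vigorous[, cl]
    df[[paste0(cl, ".stressed")]] <- lib$stressed[, cl]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral library written by [write_spectral_library_csv()]
#'
#' @param path CSV file path.
#' @param sigma,smooth_bands variability-model parameters (not stored in
#'   the CSV).
#' @return a [spectral_library].
#' @export
read_spectral_library_csv <- function(path, sigma = 0.012, smooth_bands = 10) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- setdiff(names(df), "wavelength_nm")
  classes <- unique(sub("\\.(vigorous|stressed)$", "", nm))
  vig <- sapply(classes, function(cl) df[[paste0(cl, ".vigorous")]])
  str <- sapply(classes, function(cl) df[[paste0(cl, ".stressed")]])
  spectral_library(df$wavelength_nm, vig, str, classes,
                   sigma = sigma, smooth_bands = smooth_bands)
}
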