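# bilinear DTM elevation at map points; NA outside the extent
dtm_elevation <- function(scene, x, y) {
  g <- scene$g_fine; ex <- scene$extent
  nr <- nrow(scene$dtm); nc <- ncol(scene$dtm)
  # continuous cell coordinates of (x, y) relative to cell centers
  cc <- (x - ex[["xmin"]]) / g + 0.5
  rr <- (ex[["ymax"]] - y) / g + 0.5
  out <- x < ex[["xmin"]] | x >= ex[["xmax"]] | y < ex[["ymin"]] | y >= ex[["ymax"]]
  cc <- pmin(pmax(cc, 1), nc)
  rr <- pmin(pmax(rr, 1), nr)
  c0 <- pmin(floor(cc), nc - 1); r0 <- pmin(floor(rr), nr - 1)
  fc <- cc - c0; fr <- rr - r0
  z <- (1 - fr) * (1 - fc) * scene$dtm[cbind(r0, c0)] +
    fr * (1 - fc) * scene$dtm[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * scene$dtm[cbind(r0, c0 + 1)] +
    fr * fc * scene$dtm[cbind(r0 + 1, c0 + 1)]
  z[out] <- NA_real_
  z
}

#' Intersect a view ray with the terrain model
#'
#' First intersection of a downward ray with the bilinearly interpolated
#' DTM surface: coarse ray marching with step equal to the fine cell
#' size, then bisection to 1e-3 m.
#'
#' @param origin ray origin `c(x, y, z)`.
#' @param direction ray direction (z component must be negative).
#' @param scene a [scene] providing the DTM.
#' @param tol bisection tolerance along the ray, m.
#' @return ground point `c(x, y, z)`, or `NULL` if the ray leaves the
#'   DTM extent before intersecting.
#' @export
intersect_dtm <- function(origin, direction, scene, tol = 1e-3) {
  if (direction[3] >= 0) {
    stop_gyrospec("ray must point downward", "gyrospec_param_error")
  }
  direction <- direction / sqrt(sum(direction^2))
  f <- function(s) {
    p <- origin + s * direction
    z <- dtm_elevation(scene, p[1], p[2])
    p[3] - z
  }
  zmax <- max(scene$dtm)
  # start just above the highest terrain the ray can reach
  s <- max(0, (origin[3] - zmax - 1) / (-direction[3]))
  fs <- f(s)
  if (is.na(fs) || fs < 0) return(NULL)
  step <- scene$g_fine
  s_max <- (origin[3] - min(scene$dtm) + 1) / (-direction[3])
  repeat {
    s2 <- s + step
    f2 <- f(s2)
    if (is.na(f2)) return(NULL)       # marched out of the extent
    if (f2 <= 0) break
    s <- s2
    if (s > s_max) return(NULL)
  }
  lo <- s; hi <- s2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.na(fm)) return(NULL)
    if (fm > 0) lo <- mid else hi <- mid
  }
  as.numeric(origin + ((lo + hi) / 2) * direction)
}

# Vectorized ray-DTM intersection by fixed-point iteration on the slant
# range (fast path used for whole-cube projection; near-nadir rays and
# moderate slopes). Falls back to the ray's flat-earth solution as the
# initial guess. Returns n x 3 ground points, NA rows when outside.
project_rays <- function(origins, dirs, scene, iter = 30, tol = 1e-4) {
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / nrm
  s <- (origins[, 3] - mean(scene$dtm)) / (-dirs[, 3])
  for (i in seq_len(iter)) {
    x <- origins[, 1] + s * dirs[, 1]
    y <- origins[, 2] + s * dirs[, 2]
    z <- dtm_elevation(scene, x, y)
    s_new <- (origins[, 3] - z) / (-dirs[, 3])
    conv <- !is.na(s_new) & abs(s_new - s) < tol
    s <- ifelse(is.na(s_new), s, s_new)
    if (all(conv | is.na(z))) break
  }
  x <- origins[, 1] + s * dirs[, 1]
  y <- origins[, 2] + s * dirs[, 2]
  z <- dtm_elevation(scene, x, y)
  bad <- is.na(z)
  cbind(x = ifelse(bad, NA_real_, x), y = ifelse(bad, NA_real_, y),
        z = z, deparse.level = 0)
}

# pose accessor: per-line position/attitude from a trajectory (truth)
# or an AHRS solution
pose_of <- function(pose, n_lines) {
  stopifnot(inherits(pose, "trajectory") || inherits(pose, "ahrs_solution"))
  if (nrow(pose$pos) < n_lines) {
    stop_gyrospec("pose does not cover all cube lines", "gyrospec_param_error")
  }
  list(pos = pose$pos, att = pose$att,
       source = if (inherits(pose, "trajectory")) "true" else pose$pose_source)
}

#' Project all cube pixels to ground coordinates
#'
#' Line-of-sight construction plus ray-DTM intersection for every
#' (line, detector) pixel under a given pose source.
#'
#' @param cube a [acquire_cube()] result.
#' @param pose a `trajectory` (true pose) or `ahrs_solution`.
#' @param scene the [scene] providing the DTM.
#' @return matrix `(lines * detectors) x 3` of ground points in
#'   line-major order (all detectors of line 1 first).
#' @export
project_cube <- function(cube, pose, scene) {
  L <- dim(cube$data)[1]; D <- dim(cube$data)[2]
  ps <- pose_of(pose, L)
  alpha <- detector_angles(cube$sensor)
  origins <- matrix(0, L * D, 3)
  dirs <- matrix(0, L * D, 3)
  for (l in seq_len(L)) {
    i <- (l - 1) * D + seq_len(D)
    origins[i, ] <- matrix(ps$pos[l, ], D, 3, byrow = TRUE)
    dirs[i, ] <- ray_directions(ps$att[l, ], alpha)
  }
  project_rays(origins, dirs, scene)
}

ortho_grid <- function(extent, pixel_size) {
  nc <- floor((extent[["xmax"]] - extent[["xmin"]]) / pixel_size + 1e-9)
  nr <- floor((extent[["ymax"]] - extent[["ymin"]]) / pixel_size + 1e-9)
  list(nrow = nr, ncol = nc,
       xmin = extent[["xmin"]], ymax = extent[["ymax"]])
}

#' Parametric geocorrection of a cube onto a map grid
#'
#' Every cube pixel is projected to the ground through its line of sight
#' and the DTM under the supplied pose source; the regular output grid
#' is then filled by nearest-neighbor gathering: each output cell takes
#' the spectrally unmodified spectrum of the nearest projected cube
#' pixel within one pixel's search radius, and is nodata otherwise.
#' Nearest-neighbor (not bilinear) resampling preserves spectral
#' fidelity for the downstream classifier.
#'
#' @param cube a [acquire_cube()] result.
#' @param pose a `trajectory` (true pose) or `ahrs_solution`.
#' @param scene the [scene] providing DTM and output extent.
#' @param pixel_size output pixel size, m.
#' @return object of class `ortho_image`: `data`
#'   `[rows, cols, bands]`, `mask` (TRUE = valid), `source_pixel`
#'   (matrix of originating cube-pixel indices), `pixel_size`, `extent`,
#'   `band_centers`, `provenance`.
#' @export
parametric_geocorrect <- function(cube, pose, scene, pixel_size = 0.5) {
  L <- dim(cube$data)[1]; D <- dim(cube$data)[2]; B <- dim(cube$data)[3]
  gp <- project_cube(cube, pose, scene)
  grid <- ortho_grid(scene$extent, pixel_size)
  nr <- grid$nrow; nc <- grid$ncol
  ok <- !is.na(gp[, 1]) & !is.na(cube$data[cbind(
    rep(seq_len(L), each = D), rep(seq_len(D), L), 1)])
  if (!any(ok)) {
    stop_gyrospec("no overlap between projected footprint and output grid",
                  "gyrospec_empty_output_error")
  }
  idx <- which(ok)
  px <- gp[idx, 1]; py <- gp[idx, 2]
  pc <- floor((px - grid$xmin) / pixel_size) + 1
  pr <- floor((grid$ymax - py) / pixel_size) + 1
  # candidate (cell, point) pairs over the 3x3 neighborhood, then keep
  # the closest candidate per cell within the 1-pixel search radius
  best_src <- integer(nr * nc)
  best_d <- rep(Inf, nr * nc)
  for (dr in -1:1) for (dc in -1:1) {
    r <- pr + dr; c <- pc + dc
    inb <- r >= 1 & r <= nr & c >= 1 & c <= nc
    if (!any(inb)) next
    cellx <- grid$xmin + (c[inb] - 0.5) * pixel_size
    celly <- grid$ymax - (r[inb] - 0.5) * pixel_size
    d2 <- (px[inb] - cellx)^2 + (py[inb] - celly)^2
    lin <- (c[inb] - 1) * nr + r[inb]
    keep <- d2 <= pixel_size^2
    if (!any(keep)) next
    lin <- lin[keep]; d2 <- d2[keep]; src <- idx[inb][keep]
    o <- order(lin, d2)
    lin <- lin[o]; d2 <- d2[o]; src <- src[o]
    first <- !duplicated(lin)
    lin <- lin[first]; d2 <- d2[first]; src <- src[first]
    better <- d2 < best_d[lin]
    best_d[lin[better]] <- d2[better]
    best_src[lin[better]] <- src[better]
  }
  mask <- matrix(best_src > 0, nr, nc)
  data <- array(NA_real_, dim = c(nr, nc, B))
  hit <- which(best_src > 0)
  if (length(hit)) {
    src <- best_src[hit]
    sl <- (src - 1) %/% D + 1
    sd <- (src - 1) %% D + 1
    # cube$data has dim [L, D, B]: element (l, d, b) sits at row
    # l + (d-1)*L of the flattened (L*D) x B matrix, while src indices
    # are line-major ((l-1)*D + d) -- translate between the two
    flat <- matrix(cube$data, L * D, B)
    lin_ld <- sl + (sd - 1) * L
    spectra <- flat[lin_ld, , drop = FALSE]
    for (b in seq_len(B)) {
      slice <- matrix(NA_real_, nr, nc)
      slice[hit] <- spectra[, b]
      data[, , b] <- slice
    }
  }
  src_mat <- matrix(NA_integer_, nr, nc)
  src_mat[hit] <- best_src[hit]
  structure(
    list(data = data, mask = mask, source_pixel = src_mat,
         pixel_size = pixel_size,
         extent = c(xmin = grid$xmin, xmax = grid$xmin + nc * pixel_size,
                    ymin = grid$ymax - nr * pixel_size, ymax = grid$ymax),
         band_centers = cube$band_centers,
         provenance = list(pose_source = pose_of(pose, L)$source,
                           lines = L, detectors = D)),
    class = "ortho_image")
}

#' @export
print.ortho_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ortho_image> %d x %d px @ %.2g m, %d bands, %.1f%% nodata (pose: %s)\n",
              d[1], d[2], x$pixel_size, d[3], 100 * mean(!x$mask),
              x$provenance$pose_source))
  invisible(x)
}

warp_design <- function(x, y, model) {
  switch(model,
         affine = cbind(1, x, y),
         poly2 = cbind(1, x, y, x^2, y^2, x * y))
}

#' Nonparametric GCP residual correction of an orthoimage
#'
#' Fits a least-squares warp (affine or second-order polynomial) from
#' ground-control-point pairs and applies it to the ortho grid by
#' nearest-neighbor resampling under the inverse mapping. Residual
#' attitude/position/calibration errors that survive parametric
#' geocorrection are removed this way.
#'
#' @param ortho an [parametric_geocorrect()] result.
#' @param gcps data.frame with columns `x_img, y_img` (position of the
#'   feature as geocoded) and `x_ref, y_ref` (true map position).
#' @param model `"affine"` (needs >= 3 GCPs) or `"poly2"` (>= 6).
#' @return the warped `ortho_image`, with a `gcp` field recording
#'   `rms_before` and `rms_after` (m) and the fitted coefficients.
#' @export
gcp_residual_correct <- function(ortho, gcps, model = c("affine", "poly2")) {
  model <- match.arg(model)
  need <- if (model == "affine") 3L else 6L
  gcps <- as.data.frame(gcps)
  stopifnot(all(c("x_img", "y_img", "x_ref", "y_ref") %in% names(gcps)))
  if (!all(is.finite(as.matrix(gcps)))) {
    stop_gyrospec("GCP coordinates must be finite", "gyrospec_param_error")
  }
  if (anyDuplicated(gcps[, c("x_img", "y_img")])) {
    stop_gyrospec("GCP image positions must be distinct", "gyrospec_param_error")
  }
  if (nrow(gcps) < need) {
    stop_gyrospec(sprintf("%s warp needs at least %d GCPs, got %d",
                          model, need, nrow(gcps)),
                  "gyrospec_underdetermined_error")
  }
  A_fwd <- warp_design(gcps$x_img, gcps$y_img, model)
  fit_x <- stats::lm.fit(A_fwd, gcps$x_ref)
  fit_y <- stats::lm.fit(A_fwd, gcps$y_ref)
  rms_before <- sqrt(mean((gcps$x_ref - gcps$x_img)^2 +
                            (gcps$y_ref - gcps$y_img)^2))
  rms_after <- sqrt(mean(fit_x$residuals^2 + fit_y$residuals^2))
  # inverse mapping (ref -> img) fitted on the swapped pairs, used to
  # pull spectra onto the corrected grid
  A_rev <- warp_design(gcps$x_ref, gcps$y_ref, model)
  inv_x <- stats::lm.fit(A_rev, gcps$x_img)$coefficients
  inv_y <- stats::lm.fit(A_rev, gcps$y_img)$coefficients
  nr <- dim(ortho$data)[1]; nc <- dim(ortho$data)[2]; B <- dim(ortho$data)[3]
  cx <- ortho$extent[["xmin"]] + (seq_len(nc) - 0.5) * ortho$pixel_size
  cy <- ortho$extent[["ymax"]] - (seq_len(nr) - 0.5) * ortho$pixel_size
  X <- matrix(cx, nr, nc, byrow = TRUE)
  Y <- matrix(cy, nr, nc)
  Ad <- warp_design(as.numeric(X), as.numeric(Y), model)
  sx <- Ad %*% inv_x
  sy <- Ad %*% inv_y
  sc <- floor((sx - ortho$extent[["xmin"]]) / ortho$pixel_size) + 1
  sr <- floor((ortho$extent[["ymax"]] - sy) / ortho$pixel_size) + 1
  inb <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- ortho
  lin_src <- ifelse(inb, (sc - 1) * nr + sr, NA_integer_)
  for (b in seq_len(B)) {
    slice <- matrix(NA_real_, nr, nc)
    slice[!is.na(lin_src)] <- ortho$data[, , b][lin_src[!is.na(lin_src)]]
    out$data[, , b] <- slice
  }
  m <- matrix(FALSE, nr, nc)
  m[!is.na(lin_src)] <- ortho$mask[lin_src[!is.na(lin_src)]]
  out$mask <- m & !is.na(out$data[, , 1])
  sp <- matrix(NA_integer_, nr, nc)
  sp[!is.na(lin_src)] <- ortho$source_pixel[lin_src[!is.na(lin_src)]]
  out$source_pixel <- sp
  out$gcp <- list(model = model, n = nrow(gcps),
                  rms_before = rms_before, rms_after = rms_after,
                  forward_x = fit_x$coefficients,
                  forward_y = fit_y$coefficients)
  out
}

#' Write an orthoimage to ENVI BSQ (plus an ASCII-grid band subset)
#'
#' @param ortho an `ortho_image`.
#' @param path output path for the ENVI binary.
#' @return `path`, invisibly.
#' @export
write_ortho_envi <- function(ortho, path) {
  write_envi(ortho$data, path, interleave = "bsq",
             wavelengths = ortho$band_centers,
             map_info = list(xmin = ortho$extent[["xmin"]],
                             ymax = ortho$extent[["ymax"]],
                             pixel_size = ortho$pixel_size),
             description = paste0("gyrospec ortho (",
                                  ortho$provenance$pose_source, " pose)"))
  invisible(path)
}
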