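#' Synthetic scene: terrain, classes and patches on a fine map grid
#'
#' A scene holds a digital terrain model (DTM), a crisp per-cell class
#' map and a per-cell patch-id map, all on a common fine grid (default
#' cell size 0.05 m so that a 0.5 m analysis pixel contains exactly 100
#' fine cells and 50% coverage is representable without discretization
#' ambiguity). Map coordinates are meters, x east / y north, cell-center
#' georeferencing, row 1 at maximum northing, half-open extent
#' `[xmin, xmax) x [ymin, ymax)`.
#'
#' @name scene
NULL

new_scene <- function(dtm, g_fine, xmin = 0, ymin = 0) {
  stopifnot(is.matrix(dtm), g_fine > 0)
  extent <- c(xmin = xmin, xmax = xmin + ncol(dtm) * g_fine,
              ymin = ymin, ymax = ymin + nrow(dtm) * g_fine)
  structure(
    list(dtm = dtm, g_fine = g_fine, extent = extent,
         class_map = NULL, patch_map = NULL, classes = NULL,
         patch_table = NULL),
    class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d x %d fine cells @ %.3g m (%.0f x %.0f m), z in [%.2f, %.2f] m\n",
              nrow(x$dtm), ncol(x$dtm), x$g_fine,
              x$extent["xmax"] - x$extent["xmin"],
              x$extent["ymax"] - x$extent["ymin"],
              min(x$dtm), max(x$dtm)))
  if (!is.null(x$class_map)) {
    tab <- table(factor(x$classes[x$class_map], levels = unique(x$classes)))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# map coordinates of fine-cell centers
cell_center_xy <- function(scene, row, col) {
  cbind(x = scene$extent["xmin"] + (col - 0.5) * scene$g_fine,
        y = scene$extent["ymax"] - (row - 0.5) * scene$g_fine,
        deparse.level = 0)
}

# fine-cell indices containing map points; NA outside the extent
point_to_cell <- function(scene, x, y) {
  col <- floor((x - scene$extent["xmin"]) / scene$g_fine) + 1
  row <- floor((scene$extent["ymax"] - y) / scene$g_fine) + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > ncol(scene$dtm) | row < 1 | row > nrow(scene$dtm)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col), deparse.level = 0)
}

#' Generate a digital terrain model
#'
#' @param shape integer `c(nrow, ncol)` of the fine grid.
#' @param relief one of `"flat"`, `"ramp"` (linear south-to-north rise)
#'   or `"smooth_random"` (band-limited Gaussian field).
#' @param amplitude total relief, max minus min elevation in meters.
#' @param seed integer seed (used by `smooth_random` only).
#' @param g_fine fine-grid cell size in meters.
#' @param xmin,ymin map coordinates of the lower-left extent corner.
#' @return a [scene] with `dtm` filled and no class map yet.
#' @export
generate_dtm <- function(shape, relief = c("flat", "ramp", "smooth_random"),
                         amplitude = 0, seed = 1L, g_fine = 0.05,
                         xmin = 0, ymin = 0) {
  relief <- match.arg(relief)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0)) {
    stop_gyrospec("shape must be two positive integers", "gyrospec_shape_error")
  }
  if (amplitude < 0) stop_gyrospec("amplitude must be >= 0", "gyrospec_param_error")
  nr <- shape[1]; nc <- shape[2]
  dtm <- switch(relief,
    flat = matrix(0, nr, nc),
    ramp = {
      # rises northward: row 1 (max northing) is highest
      z <- if (nr > 1) (nr - seq_len(nr)) / (nr - 1) else rep(0, nr)
      matrix(rep(amplitude * z, nc), nr, nc)
    },
    smooth_random = with_seed(seed, {
      # coarse white noise bilinearly upsampled -> smooth field
      cr <- max(2L, ceiling(nr / 16)); cc <- max(2L, ceiling(nc / 16))
      coarse <- matrix(stats::rnorm(cr * cc), cr, cc)
      ri <- seq(1, cr, length.out = nr); ci <- seq(1, cc, length.out = nc)
      r0 <- pmin(floor(ri), cr - 1); c0 <- pmin(floor(ci), cc - 1)
      fr <- ri - r0; fc <- ci - c0
      z <- outer(1 - fr, 1 - fc) * coarse[cbind(rep(r0, nc), rep(c0, each = nr))] +
        outer(fr, 1 - fc) * coarse[cbind(rep(r0 + 1, nc), rep(c0, each = nr))] +
        outer(1 - fr, fc) * coarse[cbind(rep(r0, nc), rep(c0 + 1, each = nr))] +
        outer(fr, fc) * coarse[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
      z <- matrix(z, nr, nc)
      if (diff(range(z)) > 0 && amplitude > 0) {
        z <- (z - min(z)) / diff(range(z)) * amplitude
      } else z <- z * 0
      z
    }))
  new_scene(dtm, g_fine, xmin = xmin, ymin = ymin)
}

#' Populate a scene with target patches over tiled background
#'
#' The target species is laid down as dense clonal disc patches plus
#' thin linear "tendril" polylines (lateral-shoot growth covering small
#' portions of pixels). Background classes tile the rest of the scene in
#' rectangular blocks; every block, disc and tendril is a patch with its
#' own id and a vigour `condition` drawn uniformly in `[0, 1]`.
#'
#' @param scene a [scene] from [generate_dtm()].
#' @param n_disc_patches number of clonal disc patches.
#' @param disc_radius_range numeric `c(min, max)` disc radius in m.
#' @param n_tendrils number of tendril polylines.
#' @param tendril_width tendril width in m.
#' @param background_classes character vector of background class names;
#'   must be non-empty.
#' @param target_class name of the target species class.
#' @param block_size background patch tile size in m.
#' @param seed integer seed.
#' @return the scene with `class_map`, `patch_map`, `classes` and
#'   `patch_table` filled.
#' @export
generate_patch_map <- function(scene, n_disc_patches = 12,
                               disc_radius_range = c(0.5, 3),
                               n_tendrils = 8, tendril_width = 0.2,
                               background_classes,
                               target_class = "target_succulent",
                               block_size = 5, seed = 1L) {
  stopifnot(inherits(scene, "scene"))
  if (length(background_classes) == 0) {
    stop_gyrospec("at least one background class is required",
                  "gyrospec_config_error")
  }
  if (tendril_width <= 0 || any(disc_radius_range <= 0)) {
    stop_gyrospec("radii and width must be > 0", "gyrospec_param_error")
  }
  nr <- nrow(scene$dtm); nc <- ncol(scene$dtm); g <- scene$g_fine
  classes <- c(target_class, background_classes)
  with_seed(seed, {
    # --- background tiling ---
    nbr <- ceiling(nr * g / block_size); nbc <- ceiling(nc * g / block_size)
    bg_idx <- seq_along(background_classes) + 1L
    block_class <- matrix(bg_idx[sample.int(length(bg_idx), nbr * nbc,
                                            replace = TRUE)], nbr, nbc)
    cells_per_block <- round(block_size / g)
    br <- pmin((seq_len(nr) - 1L) %/% cells_per_block + 1L, nbr)
    bc <- pmin((seq_len(nc) - 1L) %/% cells_per_block + 1L, nbc)
    class_map <- block_class[br, bc, drop = FALSE]
    block_id <- matrix(seq_len(nbr * nbc), nbr, nbc)
    patch_map <- block_id[br, bc, drop = FALSE]
    n_bg <- nbr * nbc
    patch_class <- as.integer(block_class)  # column-major matches block_id
    patch_cond <- stats::runif(n_bg)
    next_id <- n_bg
    xy <- cell_center_xy(scene, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))

    mark <- function(mask, id) {
      class_map[mask] <<- 1L
      patch_map[mask] <<- id
    }
    # --- clonal discs ---
    if (n_disc_patches > 0) for (i in seq_len(n_disc_patches)) {
      r <- stats::runif(1, disc_radius_range[1], disc_radius_range[2])
      cx <- stats::runif(1, scene$extent["xmin"] + r, scene$extent["xmax"] - r)
      cy <- stats::runif(1, scene$extent["ymin"] + r, scene$extent["ymax"] - r)
      mask <- matrix((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2 <= r^2, nr, nc)
      next_id <- next_id + 1L
      mark(mask, next_id)
      patch_class <- c(patch_class, 1L)
      patch_cond <- c(patch_cond, stats::runif(1))
    }
    # --- tendrils: short wandering polylines of stated width ---
    if (n_tendrils > 0) for (i in seq_len(n_tendrils)) {
      n_seg <- sample(2:4, 1)
      p0 <- c(stats::runif(1, scene$extent["xmin"] + 2, scene$extent["xmax"] - 2),
              stats::runif(1, scene$extent["ymin"] + 2, scene$extent["ymax"] - 2))
      ang <- stats::runif(1, 0, 2 * pi)
      mask <- matrix(FALSE, nr, nc)
      for (s in seq_len(n_seg)) {
        len <- stats::runif(1, 2, 6)
        p1 <- p0 + len * c(cos(ang), sin(ang))
        p1[1] <- min(max(p1[1], scene$extent["xmin"] + g), scene$extent["xmax"] - g)
        p1[2] <- min(max(p1[2], scene$extent["ymin"] + g), scene$extent["ymax"] - g)
        mask <- mask | segment_mask(scene, p0, p1, tendril_width / 2)
        p0 <- p1
        ang <- ang + stats::runif(1, -0.6, 0.6)
      }
      next_id <- next_id + 1L
      mark(mask, next_id)
      patch_class <- c(patch_class, 1L)
      patch_cond <- c(patch_cond, stats::runif(1))
    }
    scene$class_map <- class_map
    scene$patch_map <- patch_map
    scene$classes <- classes
    scene$patch_table <- data.frame(id = seq_len(next_id),
                                    class = classes[patch_class],
                                    condition = patch_cond)
    scene
  })
}

# fine cells whose centers lie within `halfwidth` of segment p0-p1
segment_mask <- function(scene, p0, p1, halfwidth) {
  nr <- nrow(scene$dtm); nc <- ncol(scene$dtm); g <- scene$g_fine
  ex <- scene$extent
  xlo <- min(p0[1], p1[1]) - halfwidth; xhi <- max(p0[1], p1[1]) + halfwidth
  ylo <- min(p0[2], p1[2]) - halfwidth; yhi <- max(p0[2], p1[2]) + halfwidth
  c0 <- max(1L, floor((xlo - ex["xmin"]) / g) + 1L)
  c1 <- min(nc, floor((xhi - ex["xmin"]) / g) + 1L)
  r0 <- max(1L, floor((ex["ymax"] - yhi) / g) + 1L)
  r1 <- min(nr, floor((ex["ymax"] - ylo) / g) + 1L)
  mask <- matrix(FALSE, nr, nc)
  if (c0 > c1 || r0 > r1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  cx <- ex["xmin"] + (cols - 0.5) * g
  cy <- ex["ymax"] - (rows - 0.5) * g
  d <- p1 - p0; L2 <- sum(d^2)
  X <- matrix(cx, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(cy, length(rows), length(cols))
  t <- if (L2 > 0) ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2]) / L2 else 0
  t <- pmin(pmax(t, 0), 1)
  dist2 <- (X - (p0[1] + t * d[1]))^2 + (Y - (p0[2] + t * d[2]))^2
  mask[rows, cols] <- dist2 <= halfwidth^2
  mask
}

#' Per-pixel target coverage at analysis resolution
#'
#' Aggregates the crisp fine-grid class map to the analysis grid,
#' reporting the area (m^2) of the target class within each pixel.
#'
#' @param scene a [scene] with a class map.
#' @param pixel_size analysis pixel size in m; must be an integer
#'   multiple of the fine cell size.
#' @param target_class target class name.
#' @return an object of class `coverage_map` with fields `coverage`
#'   (matrix, m^2), `pixel_size`, `pixel_area` and `extent`.
#' @export
rasterize_coverage <- function(scene, pixel_size = 0.5,
                               target_class = "target_succulent") {
  stopifnot(inherits(scene, "scene"), !is.null(scene$class_map))
  f <- pixel_size / scene$g_fine
  if (abs(f - round(f)) > 1e-9) {
    stop_gyrospec("pixel_size must be an integer multiple of the fine cell size",
                  "gyrospec_resolution_error")
  }
  f <- as.integer(round(f))
  ti <- match(target_class, scene$classes)
  if (is.na(ti)) stop_gyrospec("unknown target class", "gyrospec_lookup_error")
  m <- scene$class_map == ti
  nr <- nrow(m); nc <- ncol(m)
  NR <- nr %/% f; NC <- nc %/% f
  m <- m[seq_len(NR * f), seq_len(NC * f), drop = FALSE]
  # block sum by two rowsum passes
  cnt <- rowsum(m + 0, rep(seq_len(NR), each = f))
  cnt <- t(rowsum(t(cnt), rep(seq_len(NC), each = f)))
  structure(
    list(coverage = cnt * scene$g_fine^2,
         pixel_size = pixel_size, pixel_area = pixel_size^2,
         extent = scene$extent, target_class = target_class),
    class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %d x %d pixels @ %.2g m, target area %.2f m^2\n",
              nrow(x$coverage), ncol(x$coverage), x$pixel_size,
              sum(x$coverage)))
  invisible(x)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange used for the scene DTM, class maps and
#' classified maps (cell-center registration).
#'
#' @param m numeric matrix (row 1 = max northing).
#' @param path output path.
#' @param cellsize cell size in m.
#' @param xmin,ymin lower-left corner of the extent.
#' @param nodata nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize, xmin = 0, ymin = 0,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xmin),
    sprintf("yllcorner %.10g", ymin),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path file path.
#' @return list with `m` (matrix, `NA` for nodata), `cellsize`, `xmin`,
#'   `ymin`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- as.numeric(kv[, 2]); names(val) <- tolower(kv[, 1])
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA
  list(m = m, cellsize = val[["cellsize"]],
       xmin = val[["xllcorner"]], ymin = val[["yllcorner"]])
}
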