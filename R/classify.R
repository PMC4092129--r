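# ---- kernel SVM (RBF C-SVC), solved by SMO ------------------------------
#
# No SVM library is assumed: the dual problem
#   min 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
# is solved by sequential minimal optimization with maximal-violating-
# pair working-set selection. Deterministic for a fixed input order, as
# the convex problem has a unique optimum in the decision function.

rbf_kernel <- function(X, Z, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  exp(-gamma * pmax(d2, 0))
}

smo_fit <- function(K, y, C, tol = 1e-3, max_pass = 100000L) {
  n <- length(y)
  alpha <- numeric(n)
  f <- numeric(n)            # K %*% (alpha * y), kept incrementally
  for (it in seq_len(max_pass)) {
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    g <- y - f               # -y_i * grad_i
    m_up <- max(g[up]); m_lo <- min(g[lo])
    if (m_up - m_lo < tol) break
    i1 <- which(up)[which.max(g[up])]
    i2 <- which(lo)[which.min(g[lo])]
    y1 <- y[i1]; y2 <- y[i2]
    a1 <- alpha[i1]; a2 <- alpha[i2]
    if (y1 != y2) {
      L <- max(0, a2 - a1); H <- min(C, C + a2 - a1)
    } else {
      L <- max(0, a1 + a2 - C); H <- min(C, a1 + a2)
    }
    eta <- K[i1, i1] + K[i2, i2] - 2 * K[i1, i2]
    if (eta <= 1e-12) eta <- 1e-12
    # E1 - E2 = (f1 - y1) - (f2 - y2) = g2 - g1
    a2n <- min(max(a2 + y2 * ((f[i1] - y1) - (f[i2] - y2)) / eta, L), H)
    a1n <- a1 + y1 * y2 * (a2 - a2n)
    if (abs(a2n - a2) < 1e-14) break
    f <- f + (a1n - a1) * y1 * K[, i1] + (a2n - a2) * y2 * K[, i2]
    alpha[i1] <- a1n; alpha[i2] <- a2n
  }
  g <- y - f
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(g[free]) else {
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    (max(g[up]) + min(g[lo])) / 2
  }
  list(alpha = alpha, b = b)
}

# one-vs-rest machines on a precomputed kernel
svm_core_fit <- function(X, y_fac, C, gamma) {
  K <- rbf_kernel(X, X, gamma)
  lev <- levels(y_fac)
  machines <- lapply(lev, function(cl) {
    yy <- ifelse(y_fac == cl, 1, -1)
    fit <- smo_fit(K, yy, C)
    sv <- fit$alpha > 1e-8
    list(coef = (fit$alpha * yy)[sv], sv = which(sv), b = fit$b)
  })
  names(machines) <- lev
  list(machines = machines, X = X, levels = lev, C = C, gamma = gamma)
}

svm_core_decision <- function(core, Xnew, chunk = 4000L) {
  n <- nrow(Xnew)
  dec <- matrix(NA_real_, n, length(core$levels),
                dimnames = list(NULL, core$levels))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    Kn <- rbf_kernel(Xnew[s:e, , drop = FALSE], core$X, core$gamma)
    for (j in seq_along(core$machines)) {
      m <- core$machines[[j]]
      dec[s:e, j] <- Kn[, m$sv, drop = FALSE] %*% m$coef + m$b
    }
  }
  dec
}

svm_core_predict <- function(core, Xnew) {
  dec <- svm_core_decision(core, Xnew)
  if (length(core$levels) == 2L) {
    # binary: the two one-vs-rest machines are mirror images; use the first
    factor(ifelse(dec[, 1] >= 0, core$levels[1], core$levels[2]),
           levels = core$levels)
  } else {
    factor(core$levels[max.col(dec, ties.method = "first")],
           levels = core$levels)
  }
}

# ---- training pixel selection -------------------------------------------

# majority fine-grid class per analysis pixel
pixel_majority_class <- function(scene, pixel_size) {
  f <- as.integer(round(pixel_size / scene$g_fine))
  nr <- nrow(scene$class_map) %/% f
  nc <- ncol(scene$class_map) %/% f
  cm <- scene$class_map[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  K <- length(scene$classes)
  counts <- array(0L, dim = c(nr, nc, K))
  ri <- rep(seq_len(nr), each = f)
  ci <- rep(seq_len(nc), each = f)
  for (k in seq_len(K)) {
    blk <- rowsum((cm == k) + 0L, ri)
    counts[, , k] <- t(rowsum(t(blk), ci))
  }
  maj <- apply(counts, c(1, 2), which.max)
  matrix(as.integer(maj), nr, nc)
}

#' Select training pixels from a labeled window
#'
#' Emulates on-image ground truthing: within a labeling window, sample
#' `n_per_class` pixels per class, labeled by the detection-threshold
#' rule. For the target class a stated fraction are mixed pixels
#' (target coverage at least the detection threshold but below the full
#' pixel area); the rest are pure (full coverage). Background classes
#' are sampled from pixels below the threshold with that class in the
#' majority, and the same mixed fraction is drawn, where available,
#' from sub-threshold fringe pixels (0 < coverage < threshold) -- the
#' hard negatives that on-image labeling of whole areas naturally
#' includes.
#'
#' @param ortho an `ortho_image` (pixels must be valid there).
#' @param coverage a [rasterize_coverage()] result on the same grid.
#' @param scene the [scene] (for per-pixel majority classes).
#' @param window `c(row_min, row_max, col_min, col_max)` in ortho pixel
#'   indices; default the whole image.
#' @param n_per_class training pixels per class.
#' @param mixed_fraction fraction of target training pixels that are
#'   mixed (sub-pixel) rather than pure.
#' @param threshold_fraction coverage fraction defining presence
#'   (default 0.5 of the pixel area).
#' @param seed integer seed.
#' @return a `label_set` data.frame: `row`, `col`, `class`, `role`.
#' @export
select_training_pixels <- function(ortho, coverage, scene, window = NULL,
                                   n_per_class = 40, mixed_fraction = 0.3,
                                   threshold_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(ortho, "ortho_image"), inherits(coverage, "coverage_map"))
  nr <- nrow(coverage$coverage); nc <- ncol(coverage$coverage)
  if (is.null(window)) window <- c(1, nr, 1, nc)
  if (window[1] < 1 || window[2] > nr || window[3] < 1 || window[4] > nc) {
    stop_gyrospec("labeling window outside image", "gyrospec_param_error")
  }
  maj <- pixel_majority_class(scene, coverage$pixel_size)
  thr <- threshold_fraction * coverage$pixel_area
  inwin <- matrix(FALSE, nr, nc)
  inwin[window[1]:window[2], window[3]:window[4]] <- TRUE
  usable <- inwin & ortho$mask[seq_len(nr), seq_len(nc)]
  cov <- coverage$coverage
  target <- scene$classes[1]
  n_mixed <- round(mixed_fraction * n_per_class)
  n_pure <- n_per_class - n_mixed
  take <- function(mask, n, what) {
    idx <- which(mask)
    if (length(idx) < n) {
      stop_gyrospec(sprintf(
        "only %d candidate training pixels for %s (need %d)",
        length(idx), what, n), "gyrospec_shortfall_error")
    }
    sample(idx, n)
  }
  with_seed(seed, {
    sel <- c(
      take(usable & cov >= coverage$pixel_area - 1e-9, n_pure,
           paste(target, "(pure)")),
      if (n_mixed > 0) take(usable & cov >= thr & cov < coverage$pixel_area - 1e-9,
                            n_mixed, paste(target, "(mixed)")))
    lab <- rep(target, n_per_class)
    for (k in seq_along(scene$classes)[-1]) {
      cl <- scene$classes[k]
      fringe <- usable & cov > 0 & cov < thr & maj == k
      n_fringe <- min(round(mixed_fraction * n_per_class), sum(fringe))
      sk <- take(usable & cov == 0 & maj == k, n_per_class - n_fringe, cl)
      if (n_fringe > 0) sk <- c(sk, take(fringe, n_fringe, paste(cl, "(fringe)")))
      sel <- c(sel, sk)
      lab <- c(lab, rep(cl, n_per_class))
    }
    out <- data.frame(row = (sel - 1) %% nr + 1,
                      col = (sel - 1) %/% nr + 1,
                      class = lab, role = "train",
                      stringsAsFactors = FALSE)
    class(out) <- c("label_set", "data.frame")
    out
  })
}

#' Write/read a label set as CSV
#'
#' @param labels a `label_set`.
#' @param path file path.
#' @return `path` (write) or a `label_set` (read).
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("label_set", "data.frame")
  out
}

label_features <- function(ortho, labels) {
  nr <- dim(ortho$data)[1]; B <- dim(ortho$data)[3]
  lin <- (labels$col - 1) * nr + labels$row
  flat <- matrix(ortho$data, ncol = B)
  X <- flat[lin, , drop = FALSE]
  if (anyNA(X)) {
    stop_gyrospec("labeled pixels include nodata cells", "gyrospec_param_error")
  }
  X
}

#' Train an SVM classifier on labeled orthoimage pixels
#'
#' RBF-kernel C-SVC on the full spectral vector (all bands, no band
#' reduction), one-vs-rest for more than two classes. If `cost` or
#' `gamma` have length > 1, the pair is chosen by stratified k-fold
#' cross-validated accuracy over the grid (fixed seed, deterministic).
#'
#' @param labels a `label_set` with `role == "train"`.
#' @param ortho the `ortho_image` supplying spectra.
#' @param cost SVM cost parameter(s) C.
#' @param gamma RBF width(s); default `1 / n_bands` scaled by a small
#'   grid when tuning.
#' @param folds cross-validation folds for the grid search.
#' @param standardize per-band standardization of features (off by
#'   default; raw reflectances).
#' @param seed integer seed for fold assignment.
#' @return object of class `trained_classifier`.
#' @export
train_svm <- function(labels, ortho, cost = c(1, 10, 100), gamma = NULL,
                      folds = 5, standardize = FALSE, seed = 1L) {
  labels <- labels[labels$role == "train", , drop = FALSE]
  y <- factor(labels$class)
  if (nlevels(y) < 2L) {
    stop_gyrospec("training needs at least two classes",
                  "gyrospec_degenerate_training_error")
  }
  if (any(table(y) < 2L)) {
    stop_gyrospec("each class needs at least two training examples",
                  "gyrospec_degenerate_training_error")
  }
  X <- label_features(ortho, labels)
  ctr <- NULL; scl <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- pmax(apply(X, 2, stats::sd), 1e-12)
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  if (is.null(gamma)) {
    # median heuristic: gamma ~ 1 / median squared distance between
    # training spectra (1/n_bands is far too flat for reflectance data)
    sub <- unique(round(seq(1, nrow(X), length.out = min(200L, nrow(X)))))
    d2 <- stats::dist(X[sub, , drop = FALSE])^2
    g0 <- 1 / max(stats::median(d2), 1e-12)
    gamma <- if (length(cost) > 1) g0 * c(0.25, 1, 4) else g0
  }
  grid <- expand.grid(cost = cost, gamma = gamma)
  if (nrow(grid) > 1L) {
    fold_id <- with_seed(seed, {
      id <- integer(length(y))
      for (cl in levels(y)) {
        i <- which(y == cl)
        id[i] <- sample(rep_len(seq_len(folds), length(i)))
      }
      id
    })
    acc <- vapply(seq_len(nrow(grid)), function(gi) {
      hits <- 0L
      for (fd in seq_len(folds)) {
        tr <- fold_id != fd
        if (nlevels(droplevels(y[tr])) < nlevels(y)) return(0)
        core <- svm_core_fit(X[tr, , drop = FALSE], droplevels(y[tr]),
                             grid$cost[gi], grid$gamma[gi])
        pr <- svm_core_predict(core, X[!tr, , drop = FALSE])
        hits <- hits + sum(as.character(pr) == as.character(y[!tr]))
      }
      hits / length(y)
    }, numeric(1))
    best <- which.max(acc)
    grid_best <- grid[best, ]
  } else {
    grid_best <- grid[1, ]
    acc <- NA_real_
  }
  core <- svm_core_fit(X, y, grid_best$cost, grid_best$gamma)
  structure(
    list(core = core, classes = levels(y), n_bands = ncol(X),
         cost = grid_best$cost, gamma = grid_best$gamma,
         cv_accuracy = acc, center = ctr, scale = scl, seed = seed),
    class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> RBF SVM, %d bands, %d classes, C = %g, gamma = %g\n",
              x$n_bands, length(x$classes), x$cost, x$gamma))
  invisible(x)
}

#' Decision values of a trained classifier on a feature matrix
#'
#' @param clf a `trained_classifier`.
#' @param X numeric matrix, one spectrum per row.
#' @return matrix of one-vs-rest decision values (columns = classes).
#' @export
decision_values <- function(clf, X) {
  if (ncol(X) != clf$n_bands) {
    stop_gyrospec("feature dimension does not match classifier input",
                  "gyrospec_dimension_error")
  }
  if (!is.null(clf$center)) {
    X <- sweep(sweep(X, 2, clf$center), 2, clf$scale, "/")
  }
  svm_core_decision(clf$core, X)
}

#' Classify every valid pixel of an orthoimage
#'
#' @param clf a [train_svm()] result.
#' @param ortho an `ortho_image` with the same number of bands.
#' @return object of class `classified_map`: `map` (integer matrix of
#'   class codes, `NA` where unclassified / nodata), `classes`,
#'   `pixel_size`, `extent`.
#' @export
predict_map <- function(clf, ortho) {
  B <- dim(ortho$data)[3]
  if (B != clf$n_bands) {
    stop_gyrospec(sprintf("ortho has %d bands, classifier expects %d",
                          B, clf$n_bands), "gyrospec_dimension_error")
  }
  nr <- dim(ortho$data)[1]; nc <- dim(ortho$data)[2]
  flat <- matrix(ortho$data, ncol = B)
  valid <- which(as.logical(ortho$mask))
  map <- matrix(NA_integer_, nr, nc)
  if (length(valid)) {
    X <- flat[valid, , drop = FALSE]
    if (!is.null(clf$center)) {
      X <- sweep(sweep(X, 2, clf$center), 2, clf$scale, "/")
    }
    pr <- svm_core_predict(clf$core, X)
    map[valid] <- match(as.character(pr), clf$classes)
  }
  structure(
    list(map = map, classes = clf$classes, pixel_size = ortho$pixel_size,
         extent = ortho$extent),
    class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  cat(sprintf("<classified_map> %d x %d px, %d classes, %.1f%% unclassified\n",
              nrow(x$map), ncol(x$map), length(x$classes),
              100 * mean(is.na(x$map))))
  invisible(x)
}

#' Collapse a multiclass classified map to target / others
#'
#' @param cm a `classified_map`.
#' @param target_class name of the target class.
#' @return logical matrix, `TRUE` = classified as target, `NA` =
#'   unclassified.
#' @export
collapse_to_target <- function(cm, target_class) {
  ti <- match(target_class, cm$classes)
  if (is.na(ti)) stop_gyrospec("unknown target class", "gyrospec_lookup_error")
  cm$map == ti
}
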