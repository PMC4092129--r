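# minimal ortho_image wrapper around a feature matrix for SVM tests
matrix_ortho <- function(X, nr, nc) {
  B <- ncol(X)
  data <- array(NA_real_, c(nr, nc, B))
  for (b in seq_len(B)) data[, , b] <- matrix(X[, b], nr, nc)
  structure(list(data = data, mask = matrix(TRUE, nr, nc),
                 source_pixel = matrix(1L, nr, nc), pixel_size = 0.5,
                 extent = c(xmin = 0, xmax = nc * 0.5, ymin = 0, ymax = nr * 0.5),
                 band_centers = seq_len(B),
                 provenance = list(pose_source = "true")),
            class = "ortho_image")
}

label_all <- function(nr, nc, classes) {
  data.frame(row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr),
             class = classes, role = "train", stringsAsFactors = FALSE)
}

test_that("SVM separates linearly separable classes perfectly", {
  set.seed(1)
  X <- rbind(matrix(rnorm(60 * 4, 0), ncol = 4),
             matrix(rnorm(60 * 4, 4), ncol = 4))
  ortho <- matrix_ortho(X, 12, 10)
  labels <- label_all(12, 10, rep(c("a", "b"), each = 60))
  clf <- train_svm(labels, ortho, cost = 10, gamma = 0.3)
  cm <- predict_map(clf, ortho)
  expect_equal(clf$classes[cm$map[cbind(labels$row, labels$col)]],
               labels$class)
  expect_equal(clf$n_bands, 4)
})

test_that("training is deterministic: duplicate runs give identical decisions", {
  set.seed(2)
  X <- rbind(matrix(rnorm(50 * 6, 0), ncol = 6),
             matrix(rnorm(50 * 6, 1.5), ncol = 6))
  ortho <- matrix_ortho(X, 10, 10)
  labels <- label_all(10, 10, rep(c("a", "b"), each = 50))
  clf1 <- train_svm(labels, ortho, cost = c(1, 10), folds = 3, seed = 5)
  clf2 <- train_svm(labels, ortho, cost = c(1, 10), folds = 3, seed = 5)
  probe <- matrix(rnorm(40 * 6), ncol = 6)
  expect_lt(max(abs(decision_values(clf1, probe) -
                      decision_values(clf2, probe))), 1e-9)
  expect_equal(clf1$cost, clf2$cost)
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(40), ncol = 4)
  ortho <- matrix_ortho(X, 5, 2)
  one_class <- label_all(5, 2, rep("a", 10))
  expect_error(train_svm(one_class, ortho),
               class = "gyrospec_degenerate_training_error")
  tiny <- label_all(5, 2, c(rep("a", 9), "b"))
  expect_error(train_svm(tiny, ortho),
               class = "gyrospec_degenerate_training_error")
})

test_that("prediction rejects band mismatch and propagates nodata", {
  set.seed(3)
  X <- rbind(matrix(rnorm(30 * 4, 0), ncol = 4),
             matrix(rnorm(30 * 4, 3), ncol = 4))
  ortho <- matrix_ortho(X, 10, 6)
  labels <- label_all(10, 6, rep(c("a", "b"), each = 30))
  clf <- train_svm(labels, ortho, cost = 10, gamma = 0.3)
  bad <- matrix_ortho(X[, 1:3], 10, 6)
  expect_error(predict_map(clf, bad), class = "gyrospec_dimension_error")

  allna <- ortho
  allna$mask[] <- FALSE
  cm <- predict_map(clf, allna)
  expect_true(all(is.na(cm$map)))
})

test_that("multiclass + collapse equals a binary machine on separable data", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40 * 4, 0), ncol = 4),
             matrix(rnorm(40 * 4, 4), ncol = 4),
             matrix(rnorm(40 * 4, 8), ncol = 4))
  ortho <- matrix_ortho(X, 12, 10)
  multi <- label_all(12, 10, rep(c("target", "b1", "b2"), each = 40))
  clf_m <- train_svm(multi, ortho, cost = 10, gamma = 0.3)
  collapsed <- collapse_to_target(predict_map(clf_m, ortho), "target")

  binary <- multi
  binary$class <- ifelse(binary$class == "target", "target", "others")
  clf_b <- train_svm(binary, ortho, cost = 10, gamma = 0.3)
  bin_map <- collapse_to_target(predict_map(clf_b, ortho), "target")
  expect_equal(collapsed, bin_map)
})

test_that("training pixel selection honours the mixed fraction contract", {
  lib <- default_spectral_library(n_bands = 20)
  sc <- generate_dtm(c(600, 600), "flat", 0)   # 30 x 30 m
  sc <- generate_patch_map(sc, n_disc_patches = 6,
                           disc_radius_range = c(1.5, 3), n_tendrils = 4,
                           tendril_width = 0.2,
                           background_classes = lib$classes[-1], seed = 2)
  cov <- rasterize_coverage(sc, 0.5, target_class = sc$classes[1])
  fake_ortho <- matrix_ortho(matrix(0.5, nrow(cov$coverage) * ncol(cov$coverage),
                                    3), nrow(cov$coverage), ncol(cov$coverage))

  lab <- select_training_pixels(fake_ortho, cov, sc, n_per_class = 20,
                                mixed_fraction = 0.3, seed = 3)
  tgt <- lab[lab$class == sc$classes[1], ]
  expect_equal(nrow(tgt), 20)
  covs <- cov$coverage[cbind(tgt$row, tgt$col)]
  expect_equal(sum(covs >= cov$pixel_area - 1e-9), 14)  # 70% pure
  expect_equal(sum(covs >= 0.125 & covs < cov$pixel_area - 1e-9), 6)

  # mixed_fraction 0: all target pixels pure
  lab0 <- select_training_pixels(fake_ortho, cov, sc, n_per_class = 10,
                                 mixed_fraction = 0, seed = 4)
  tgt0 <- lab0[lab0$class == sc$classes[1], ]
  expect_true(all(cov$coverage[cbind(tgt0$row, tgt0$col)] >=
                    cov$pixel_area - 1e-9))

  # determinism and train/validate disjointness bookkeeping
  expect_identical(select_training_pixels(fake_ortho, cov, sc,
                                          n_per_class = 20, seed = 3),
                   lab <- select_training_pixels(fake_ortho, cov, sc,
                                                 n_per_class = 20, seed = 3))
  expect_true(all(lab$role == "train"))

  # a window with no target pixels produces a named shortfall error
  win <- c(1, 4, 1, 4)
  expect_error(select_training_pixels(fake_ortho, cov, sc, window = win,
                                      n_per_class = 20, seed = 5),
               "target")
  expect_error(select_training_pixels(fake_ortho, cov, sc, window = win,
                                      n_per_class = 20, seed = 5),
               class = "gyrospec_shortfall_error")
})

test_that("label CSV round trip", {
  lab <- data.frame(row = 1:3, col = 4:6, class = c("a", "b", "a"),
                    role = "train", stringsAsFactors = FALSE)
  class(lab) <- c("label_set", "data.frame")
  p <- file.path(tempdir(), "labels.csv")
  write_labels_csv(lab, p)
  expect_equal(as.data.frame(read_labels_csv(p)), as.data.frame(lab))
})
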