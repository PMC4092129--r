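# The three published 2x2 accuracy matrices used as golden tests
golden <- list(
  blackwood = list(m = rbind(c(93, 7), c(9, 241)),
                   users = c(93.0, 96.4), producers = c(91.2, 97.2),
                   overall = 95.4, kappa = 0.888),
  soursob = list(m = rbind(c(100, 0), c(3, 247)),
                 users = c(100, 98.8), producers = c(97.1, 100),
                 overall = 99.1, kappa = 0.979),
  iceplant = list(m = rbind(c(139, 11), c(4, 296)),
                  users = c(92.7, 98.7), producers = c(97.2, 96.4),
                  overall = 96.7, kappa = 0.924))

test_that("accuracy metrics reproduce every published matrix cell", {
  for (g in golden) {
    r <- accuracy_metrics(error_matrix(g$m))
    expect_equal(unname(r$users), g$users)
    expect_equal(unname(r$producers), g$producers)
    expect_equal(unname(r$overall), g$overall)
    expect_equal(cohens_kappa(error_matrix(g$m)), g$kappa)
    expect_equal(r$kappa, g$kappa)
  }
  # iceplant: producer's - user's gap of 4.54 points, computed unrounded
  r <- accuracy_metrics(error_matrix(golden$iceplant$m))
  expect_equal(round(r$producers_raw[1] - r$users_raw[1], 2), 4.54,
               ignore_attr = TRUE)
})

test_that("error matrix arithmetic identities hold", {
  for (g in golden) {
    m <- error_matrix(g$m)
    expect_equal(m$row_totals, rowSums(m$counts), ignore_attr = TRUE)
    expect_equal(m$col_totals, colSums(m$counts), ignore_attr = TRUE)
    expect_equal(m$n, sum(m$counts))
    r <- accuracy_metrics(m)
    # overall = column-weighted mean of producer's accuracies
    expect_equal(r$overall_raw,
                 sum(m$col_totals * r$producers_raw) / m$n,
                 ignore_attr = TRUE)
    # kappa never exceeds overall agreement (as proportions)
    expect_lte(r$kappa_raw, r$overall_raw / 100)
  }
  perfect <- accuracy_metrics(error_matrix(rbind(c(50, 0), c(0, 50))))
  expect_equal(unname(c(perfect$users, perfect$producers, perfect$overall)),
               rep(100, 5))
  expect_equal(perfect$kappa, 1)
})

test_that("class relabeling permutes accuracies, fixes overall and kappa", {
  m <- golden$blackwood$m
  r1 <- accuracy_metrics(error_matrix(m))
  r2 <- accuracy_metrics(error_matrix(m[2:1, 2:1]))
  expect_equal(unname(r2$users), unname(rev(r1$users)))
  expect_equal(unname(r2$producers), unname(rev(r1$producers)))
  expect_equal(r2$overall, r1$overall)
  expect_equal(r2$kappa_raw, r1$kappa_raw)
})

test_that("degenerate matrices report undefined metrics, not zero", {
  r <- accuracy_metrics(error_matrix(rbind(c(0, 0), c(10, 90))))
  expect_true(is.na(r$users[1]))   # empty classified-target row
  expect_false(is.na(r$users[2]))
  expect_true(is.na(cohens_kappa(error_matrix(rbind(c(100, 0), c(0, 0))))))
  expect_error(error_matrix(rbind(c(-1, 0), c(0, 1))),
               class = "gyrospec_param_error")
  expect_error(accuracy_metrics(error_matrix(matrix(0, 2, 2))),
               class = "gyrospec_param_error")
})

test_that("detection threshold is boundary-inclusive at 0.125 m^2", {
  cov <- structure(list(coverage = matrix(c(0, 0.1249999, 0.125, 0.2, 0.25, 0),
                                          2, 3),
                        pixel_size = 0.5, pixel_area = 0.25,
                        extent = c(xmin = 0, xmax = 1.5, ymin = 0, ymax = 1)),
                   class = "coverage_map")
  pres <- apply_detection_threshold(cov, 0.5)
  expect_identical(as.vector(pres), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(0.5 * cov$pixel_area, 0.125)
  expect_error(apply_detection_threshold(cov, 0),
               class = "gyrospec_param_error")
  expect_error(apply_detection_threshold(cov, 1.1),
               class = "gyrospec_param_error")
})

test_that("validation sampling is stratified, exclusive and deterministic", {
  set.seed(7)
  classified <- matrix(runif(40 * 40) < 0.3, 40, 40)
  reference <- classified
  reference[sample(1600, 200)] <- !reference[sample(1600, 200)]
  v1 <- sample_validation_pixels(classified, reference, 100, 250, seed = 2)
  v2 <- sample_validation_pixels(classified, reference, 100, 250, seed = 2)
  expect_identical(v1, v2)
  expect_equal(sum(v1$class == "target"), 100)
  expect_equal(sum(v1$class == "other"), 250)
  expect_equal(nrow(v1), 350)  # the published validation totals
  expect_true(all(classified[cbind(v1$row[v1$class == "target"],
                                   v1$col[v1$class == "target"])]))
  expect_false(any(duplicated(v1[, c("row", "col")])))

  # excluding every classified-target pixel starves the stratum
  excl <- which(classified, arr.ind = TRUE)
  excl <- data.frame(row = excl[, 1], col = excl[, 2],
                     class = "x", role = "train")
  expect_error(sample_validation_pixels(classified, reference, 10, 10,
                                        exclude = excl, seed = 1),
               class = "gyrospec_shortfall_error")

  # training pixels never reappear in the validation sample
  tr <- data.frame(row = v1$row[1:50], col = v1$col[1:50],
                   class = "x", role = "train")
  v3 <- sample_validation_pixels(classified, reference, 50, 50,
                                 exclude = tr, seed = 3)
  expect_equal(nrow(merge(v3, tr[, c("row", "col")])), 0)
})

test_that("build_error_matrix counts agreement cells correctly", {
  # construct maps yielding exactly the blackwood matrix
  classified <- matrix(FALSE, 20, 20)
  reference <- matrix(FALSE, 20, 20)
  idx <- seq_len(93 + 7 + 9 + 241)
  classified[idx[1:100]] <- TRUE              # 93 TP + 7 FP
  reference[idx[c(1:93, 101:109)]] <- TRUE    # 9 FN
  labels <- data.frame(row = (idx - 1) %% 20 + 1, col = (idx - 1) %/% 20 + 1,
                       class = "any", role = "validate")
  m <- build_error_matrix(labels, classified, reference)
  expect_equal(unname(m$counts), rbind(c(93, 7), c(9, 241)))

  all_agree <- build_error_matrix(labels, classified, classified)
  expect_equal(sum(diag(all_agree$counts)), 350)

  expect_error(build_error_matrix(labels[0, ], classified, reference),
               class = "gyrospec_param_error")
  nav <- classified; nav[1, 1] <- NA
  expect_error(build_error_matrix(labels, nav, reference),
               class = "gyrospec_integrity_error")
})

test_that("report formatting and JSON serialization carry all fields", {
  r <- accuracy_metrics(error_matrix(golden$blackwood$m))
  txt <- format_accuracy_report(r)
  expect_true(any(grepl("93.0", txt)))
  expect_true(any(grepl("0.888", txt)))
  p <- file.path(tempdir(), "report.json")
  write_accuracy_json(r, p)
  j <- jsonlite::fromJSON(p)
  expect_equal(j$overall_pct, 95.4)
  expect_equal(j$kappa, 0.888)
  expect_equal(j$counts, unname(golden$blackwood$m))
})
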