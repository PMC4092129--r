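#' Sub-pixel detection threshold
#'
#' A pixel counts as species presence when the target covers at least
#' `fraction` of the pixel area (boundary inclusive): at the default
#' 50% of a 0.5 m x 0.5 m pixel, presence means 0.125 m^2 or bigger.
#'
#' @param coverage a [rasterize_coverage()] result.
#' @param fraction coverage fraction in `(0, 1]`.
#' @return logical presence matrix.
#' @export
apply_detection_threshold <- function(coverage, fraction = 0.5) {
  stopifnot(inherits(coverage, "coverage_map"))
  if (fraction <= 0 || fraction > 1) {
    stop_gyrospec("threshold fraction must be in (0, 1]", "gyrospec_param_error")
  }
  coverage$coverage >= fraction * coverage$pixel_area
}

#' Stratified random validation sample
#'
#' Draws, uniformly at random and without replacement over the whole
#' image, `n_target` pixels classified as target presence and `n_other`
#' pixels classified as anything else, excluding training pixels (and
#' unclassified ones). Defaults follow the validation protocol:
#' circa 100 presence + 250 absence samples.
#'
#' @param classified logical matrix (`TRUE` = classified as target), as
#'   from [collapse_to_target()].
#' @param reference logical presence matrix, as from
#'   [apply_detection_threshold()].
#' @param n_target,n_other stratum sizes.
#' @param exclude optional `label_set` whose pixels are excluded.
#' @param seed integer seed.
#' @return a `label_set` with `role == "validate"` and columns
#'   `row, col, class` (class = `"target"` / `"other"` by
#'   classification stratum).
#' @export
sample_validation_pixels <- function(classified, reference, n_target = 100,
                                     n_other = 250, exclude = NULL,
                                     seed = 1L) {
  stopifnot(is.matrix(classified), all(dim(classified) == dim(reference)))
  excl <- matrix(FALSE, nrow(classified), ncol(classified))
  if (!is.null(exclude) && nrow(exclude)) {
    excl[cbind(exclude$row, exclude$col)] <- TRUE
  }
  eligible <- !is.na(classified) & !excl
  pick <- function(mask, n, what) {
    idx <- which(mask)
    if (length(idx) < n) {
      stop_gyrospec(sprintf(
        "stratum '%s' has %d eligible pixels, need %d",
        what, length(idx), n), "gyrospec_shortfall_error")
    }
    sample(idx, n)
  }
  with_seed(seed, {
    it <- pick(eligible & classified, n_target, "classified target")
    io <- pick(eligible & !classified, n_other, "classified other")
    nr <- nrow(classified)
    out <- data.frame(
      row = ((c(it, io) - 1) %% nr) + 1,
      col = ((c(it, io) - 1) %/% nr) + 1,
      class = rep(c("target", "other"), c(n_target, n_other)),
      role = "validate", stringsAsFactors = FALSE)
    class(out) <- c("label_set", "data.frame")
    out
  })
}

#' Construct a 2 x 2 error (confusion) matrix
#'
#' Rows are the classification (Target, Others), columns the ground
#' reference, following the standard accuracy-matrix layout.
#'
#' @param counts 2 x 2 numeric matrix `[[TP, FP], [FN, TN]]`.
#' @return object of class `error_matrix`.
#' @export
error_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_gyrospec("counts must be non-negative integers", "gyrospec_param_error")
  }
  dimnames(counts) <- list(classified = c("Target", "Others"),
                           reference = c("Target", "Others"))
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 n = sum(counts)),
            class = "error_matrix")
}

#' Error matrix from a validation sample
#'
#' @param labels a `label_set` from [sample_validation_pixels()].
#' @param classified logical matrix (`TRUE` = classified as target).
#' @param reference logical presence matrix.
#' @return an [error_matrix()].
#' @export
build_error_matrix <- function(labels, classified, reference) {
  if (is.null(labels) || nrow(labels) == 0) {
    stop_gyrospec("empty validation label set", "gyrospec_param_error")
  }
  ij <- cbind(labels$row, labels$col)
  cl <- classified[ij]
  rf <- reference[ij]
  if (anyNA(cl) || anyNA(rf)) {
    stop_gyrospec("validation pixel lacks classification or reference value",
                  "gyrospec_integrity_error")
  }
  error_matrix(rbind(c(sum(cl & rf), sum(cl & !rf)),
                     c(sum(!cl & rf), sum(!cl & !rf))))
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("<error_matrix>\n")
  m <- cbind(x$counts, `Row Total` = x$row_totals)
  m <- rbind(m, `Column Total` = c(x$col_totals, x$n))
  print(m)
  invisible(x)
}

#' Accuracy metrics of an error matrix
#'
#' User's accuracy per classified class (1 - commission error),
#' producer's accuracy per reference class (1 - omission error) and
#' overall accuracy, all in percent. Reported values are rounded
#' half-up to one decimal from unrounded intermediates; the unrounded
#' values are retained. Undefined ratios (zero row or column) are
#' reported as `NA`, not 0.
#'
#' @param m an [error_matrix()].
#' @return object of class `accuracy_report` with fields `users`,
#'   `producers`, `overall` (rounded, %), their `*_raw` counterparts,
#'   and `kappa` / `kappa_raw` (see [cohens_kappa()]).
#' @export
accuracy_metrics <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  if (m$n <= 0) stop_gyrospec("empty error matrix", "gyrospec_param_error")
  d <- diag(m$counts)
  users_raw <- 100 * ifelse(m$row_totals > 0, d / m$row_totals, NA_real_)
  prod_raw <- 100 * ifelse(m$col_totals > 0, d / m$col_totals, NA_real_)
  overall_raw <- 100 * sum(d) / m$n
  kr <- cohens_kappa(m, raw = TRUE)
  structure(
    list(users = round_half_up(users_raw, 1),
         producers = round_half_up(prod_raw, 1),
         overall = round_half_up(overall_raw, 1),
         users_raw = users_raw, producers_raw = prod_raw,
         overall_raw = overall_raw,
         kappa = trunc_digits(kr, 3), kappa_raw = kr,
         matrix = m),
    class = "accuracy_report")
}

#' Cohen's kappa of an error matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_o = sum(diag) / N` and `p_e = sum(row_i * col_i) / N^2`. The
#' reported value is truncated (not rounded) at three decimals, the
#' convention that reproduces published accuracy tables computed this
#' way; use `raw = TRUE` for the unrounded value. Degenerate marginals
#' (`p_e = 1`) give `NA`.
#'
#' @param m an [error_matrix()].
#' @param raw return the unrounded value.
#' @return kappa in `[-1, 1]`, or `NA` if undefined.
#' @export
cohens_kappa <- function(m, raw = FALSE) {
  stopifnot(inherits(m, "error_matrix"))
  if (m$n <= 0) stop_gyrospec("empty error matrix", "gyrospec_param_error")
  po <- sum(diag(m$counts)) / m$n
  pe <- sum(m$row_totals * m$col_totals) / m$n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  k <- (po - pe) / (1 - pe)
  if (raw) k else trunc_digits(k, 3)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(format_accuracy_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable accuracy table
#'
#' Mirrors the standard accuracy-matrix layout: counts with row/column
#' totals, user's and producer's accuracy per class, overall accuracy
#' and kappa.
#'
#' @param x an [accuracy_metrics()] result.
#' @return character vector of lines.
#' @export
format_accuracy_report <- function(x) {
  m <- x$matrix
  fmt_pct <- function(v) ifelse(is.na(v), "undef", sprintf("%.1f", v))
  c(sprintf("%-14s %8s %8s %10s %10s %12s", "Classification",
            "Target", "Others", "Row Total", "User's(%)", "Producer's(%)"),
    sprintf("%-14s %8d %8d %10d %10s %12s", "Target spp.",
            m$counts[1, 1], m$counts[1, 2], m$row_totals[1],
            fmt_pct(x$users[1]), fmt_pct(x$producers[1])),
    sprintf("%-14s %8d %8d %10d %10s %12s", "Others",
            m$counts[2, 1], m$counts[2, 2], m$row_totals[2],
            fmt_pct(x$users[2]), fmt_pct(x$producers[2])),
    sprintf("%-14s %8d %8d", "Column Total", m$col_totals[1], m$col_totals[2]),
    sprintf("Overall Accuracy (%%): %s   Kappa: %s",
            fmt_pct(x$overall),
            ifelse(is.na(x$kappa), "undef", sprintf("%.3f", x$kappa))))
}

#' Serialize an accuracy report to JSON
#'
#' @param x an [accuracy_metrics()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accuracy_json <- function(x, path) {
  jsonlite::write_json(
    list(counts = unclass(x$matrix$counts),
         users_pct = x$users, producers_pct = x$producers,
         overall_pct = x$overall, kappa = x$kappa,
         users_raw = x$users_raw, producers_raw = x$producers_raw,
         overall_raw = x$overall_raw, kappa_raw = x$kappa_raw),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
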