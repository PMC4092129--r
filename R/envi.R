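#' Write a hyperspectral cube in ENVI format
#'
#' Flat binary (IEEE float32, little-endian) plus a text `.hdr` sidecar.
#' Interleaves: `bil` (line-interleaved, the native pushbroom order) or
#' `bsq` (band-sequential, typical for orthoimages).
#'
#' @param data numeric 3-D array `[lines, samples, bands]`; `NA` values
#'   are written as the `data ignore value` -9999.
#' @param path output path for the binary file; the header is written
#'   to `paste0(path, ".hdr")`.
#' @param interleave `"bil"` or `"bsq"`.
#' @param wavelengths optional band-center wavelengths (nm) for the
#'   header.
#' @param map_info optional list with `xmin`, `ymax`, `pixel_size` used
#'   to emit an ENVI `map info` line (arbitrary local meter grid).
#' @param description header description string.
#' @return `path`, invisibly.
#' @export
write_envi <- function(data, path, interleave = c("bil", "bsq"),
                       wavelengths = NULL, map_info = NULL,
                       description = "gyrospec cube") {
  interleave <- match.arg(interleave)
  stopifnot(length(dim(data)) == 3)
  d <- dim(data)
  hdr <- c("ENVI",
           sprintf("description = {%s}", description),
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           "data ignore value = -9999")
  if (!is.null(map_info)) {
    hdr <- c(hdr, sprintf(
      "map info = {Arbitrary, 1.0, 1.0, %.10g, %.10g, %.10g, %.10g, units=Meters}",
      map_info$xmin, map_info$ymax, map_info$pixel_size, map_info$pixel_size))
  }
  if (!is.null(wavelengths)) {
    hdr <- c(hdr, "wavelength units = Nanometers",
             paste0("wavelength = {",
                    paste(sprintf("%.4f", wavelengths), collapse = ", "), "}"))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  v <- switch(interleave,
              bil = as.numeric(aperm(data, c(2, 3, 1))),
              bsq = as.numeric(aperm(data, c(2, 1, 3))))
  v[is.na(v)] <- -9999
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path), collapse = "\n")
  get1 <- function(key, numeric = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?m)^", key, "\\s*=\\s*([^\\n{]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    v <- trimws(m[2])
    if (numeric) as.numeric(v) else v
  }
  getset <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*\\{([^}]*)\\}"), txt))[[1]]
    if (length(m) < 2) return(NULL)
    trimws(strsplit(m[2], ",")[[1]])
  }
  list(samples = get1("samples"), lines = get1("lines"),
       bands = get1("bands"), data_type = get1("data type"),
       interleave = get1("interleave", numeric = FALSE),
       wavelengths = suppressWarnings(as.numeric(getset("wavelength"))),
       map_info = getset("map info"))
}

#' Read an ENVI cube written by [write_envi()]
#'
#' @param path binary file path (header at `paste0(path, ".hdr")`).
#' @return list with `data` (`[lines, samples, bands]` array, `NA` for
#'   ignore values), `wavelengths` and `map_info`.
#' @export
read_envi <- function(path) {
  h <- parse_envi_header(paste0(path, ".hdr"))
  if (is.null(h$samples) || h$data_type != 4) {
    stop_gyrospec("unsupported or malformed ENVI header", "gyrospec_io_error")
  }
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  data <- switch(tolower(h$interleave),
    bil = aperm(array(v, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bsq = aperm(array(v, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    stop_gyrospec("unsupported interleave", "gyrospec_io_error"))
  data[data == -9999] <- NA
  list(data = data, wavelengths = h$wavelengths, map_info = h$map_info)
}

#' Write a spectral library as an ENVI spectral library file
#'
#' One spectrum per line (`lines` = spectra, `samples` = bands), BIL
#' binary with a `spectra names` header entry.
#'
#' @param lib a [spectral_library].
#' @param path output path (header at `paste0(path, ".hdr")`).
#' @return `path`, invisibly.
#' @export
write_spectral_library_envi <- function(lib, path) {
  nm <- c(paste0(lib$classes, ".vigorous"), paste0(lib$classes, ".stressed"))
  spec <- t(cbind(lib$vigorous, lib$stressed))
  arr <- array(spec, dim = c(nrow(spec), ncol(spec), 1))
  write_envi(arr, path, interleave = "bil", wavelengths = lib$band_centers,
             description = "gyrospec spectral library")
  hdr <- readLines(paste0(path, ".hdr"))
  hdr[hdr == "file type = ENVI Standard"] <- "file type = ENVI Spectral Library"
  hdr <- c(hdr, paste0("spectra names = {", paste(nm, collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}
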