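#' Read / write photon decay histograms as two-column CSV
#'
#' Columns: `bin_center_ns`, `counts`.
#'
#' @param hist a [decay_histogram()].
#' @param path file path.
#' @return `write_decay_csv` returns `path` invisibly; `read_decay_csv`
#'   returns a [decay_histogram()].
#' @export
write_decay_csv <- function(hist, path) {
  assert_that(inherits(hist, "decay_histogram"), "`hist` must be a decay_histogram")
  utils::write.csv(data.frame(bin_center_ns = hist$bin_centers_ns,
                              counts = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  assert_that(all(c("bin_center_ns", "counts") %in% names(df)),
              "decay CSV needs columns bin_center_ns, counts")
  bw <- stats::median(diff(df$bin_center_ns))
  decay_histogram(df$counts, bin_width_ns = bw,
                  window_ns = bw * nrow(df))
}

#' Read / write FCS autocorrelation curves as two-column CSV
#'
#' Columns: `lag_s`, `G`; the mean intensity is stored as a
#' `# intensity_mean_Hz:` comment line when available.
#'
#' @param curve an [fcs_curve()].
#' @param path file path.
#' @return `write_acf_csv` returns `path` invisibly; `read_acf_csv` an
#'   [fcs_curve()].
#' @export
write_acf_csv <- function(curve, path) {
  assert_that(inherits(curve, "fcs_curve"), "`curve` must be an fcs_curve")
  con <- file(path, "w")
  on.exit(close(con))
  if (is.finite(curve$intensity_mean_Hz)) {
    writeLines(sprintf("# intensity_mean_Hz: %.10g", curve$intensity_mean_Hz), con)
  }
  utils::write.csv(data.frame(lag_s = curve$lags, G = curve$G),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
read_acf_csv <- function(path) {
  first <- readLines(path, n = 1L)
  intensity <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("intensity_mean_Hz:\\s*([-0-9.eE+]+)", first))[[1]]
    if (length(m) == 2L) intensity <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  assert_that(all(c("lag_s", "G") %in% names(df)),
              "ACF CSV needs columns lag_s, G")
  fcs_curve(df$lag_s, df$G, intensity_mean_Hz = intensity)
}

#' Read / write photon-count images as 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers (max 65535 counts/pixel).
#' TIFF carries no dwell-time metadata, so the pixel dwell time must be
#' supplied when reading (acquisition metadata is kept in the accompanying
#' JSON records).
#'
#' @param image a [count_image()].
#' @param path file path.
#' @param pixel_dwell_s dwell time in seconds to attach on reading
#'   (default 50e-6).
#' @return `write_count_tiff` returns `path` invisibly; `read_count_tiff` a
#'   [count_image()].
#' @export
write_count_tiff <- function(image, path) {
  assert_that(inherits(image, "count_image"), "`image` must be a count_image")
  assert_that(max(image$counts) <= 65535, "counts exceed 16-bit range")
  tiff::writeTIFF(image$counts / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_count_tiff
#' @export
read_count_tiff <- function(path, pixel_dwell_s = 50e-6) {
  img <- tiff::readTIFF(path)
  count_image(round(img * 65535), pixel_dwell_s = pixel_dwell_s)
}

#' Write an analysis record as JSON
#'
#' Serializes results or calibration records (e.g. `{V_eff, CPP, S, D_ref}`)
#' with unboxed scalars and full numeric precision.
#'
#' @param x a list (scalars and vectors; nested lists allowed).
#' @param path file path.
#' @return `path`, invisibly; `read_record_json` returns the list.
#' @export
write_record_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_record_json
#' @export
read_record_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
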