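#' Specification of a synthetic photon-counting confocal image
#'
#' The forward model for the expected photon count in a pixel holding local
#' concentration c (molar) is
#' `counts = c * N_A * V_eff * CPP * PT`:
#' molecules in the detection volume times molecular brightness times pixel
#' dwell time.
#'
#' @param concentration_field_uM numeric matrix of per-pixel concentrations in
#'   micromolar (>= 0). Its dimensions define the image shape.
#' @param cpp_Hz molecular brightness, counts per particle per second.
#' @param pixel_dwell_s pixel dwell time PT in seconds (default 50e-6).
#' @param v_eff_L effective detection volume in litres (e.g. 0.32e-15 for
#'   0.32 fL).
#' @param seed integer seed.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(concentration_field_uM, cpp_Hz,
                       pixel_dwell_s = 50e-6, v_eff_L, seed = NULL) {
  assert_that(is.matrix(concentration_field_uM) &&
                all(is.finite(concentration_field_uM)),
              "`concentration_field_uM` must be a finite numeric matrix")
  assert_that(all(concentration_field_uM >= 0), "concentrations must be >= 0")
  assert_positive(cpp_Hz, "cpp_Hz")
  assert_positive(pixel_dwell_s, "pixel_dwell_s")
  assert_positive(v_eff_L, "v_eff_L")
  structure(list(concentration_field_uM = concentration_field_uM,
                 cpp_Hz = cpp_Hz, pixel_dwell_s = pixel_dwell_s,
                 v_eff_L = v_eff_L, seed = seed),
            class = "image_spec")
}

#' Photon-count image constructor
#'
#' @param counts non-negative integer matrix of photon counts per pixel.
#' @param pixel_dwell_s pixel dwell time in seconds.
#' @param pixel_size_um pixel size in micrometres (optional metadata).
#' @param truth optional ground-truth list attached by the simulator.
#' @return object of class `count_image`.
#' @export
count_image <- function(counts, pixel_dwell_s, pixel_size_um = NA_real_,
                        truth = NULL) {
  assert_that(is.matrix(counts) && all(counts >= 0) && all(is.finite(counts)),
              "`counts` must be a finite non-negative matrix")
  storage.mode(counts) <- "double"
  assert_positive(pixel_dwell_s, "pixel_dwell_s")
  structure(list(counts = counts, pixel_dwell_s = pixel_dwell_s,
                 pixel_size_um = pixel_size_um, truth = truth),
            class = "count_image")
}

#' @export
print.count_image <- function(x, ...) {
  cat(sprintf("<count_image> %d x %d px, mean %.3g counts/px, dwell %.3g us\n",
              nrow(x$counts), ncol(x$counts), mean(x$counts),
              x$pixel_dwell_s * 1e6))
  invisible(x)
}

## expected counts/pixel of the forward model, c in uM
expected_counts_per_pixel <- function(c_uM, cpp_Hz, pixel_dwell_s, v_eff_L) {
  (c_uM * 1e-6) * N_AVOGADRO * v_eff_L * cpp_Hz * pixel_dwell_s
}

#' Simulate a photon-counting confocal image
#'
#' Per-pixel counts are Poisson distributed with mean
#' `c * N_A * V_eff * CPP * PT`. A warning is raised if the expected count
#' rate anywhere reaches the detector saturation regime (2 MHz).
#'
#' @param spec an [image_spec()].
#' @return a [count_image()] with the true concentration field in `$truth`.
#' @export
gen_attachment_image <- function(spec) {
  assert_that(inherits(spec, "image_spec"), "`spec` must be an image_spec")
  mu <- expected_counts_per_pixel(spec$concentration_field_uM, spec$cpp_Hz,
                                  spec$pixel_dwell_s, spec$v_eff_L)
  if (any(mu / spec$pixel_dwell_s >= DEFAULT_SATURATION_HZ)) {
    warning("expected count rate reaches the 2 MHz detector saturation regime")
  }
  counts <- with_seed(spec$seed, stats::rpois(length(mu), mu))
  counts <- matrix(counts, nrow = nrow(mu), ncol = ncol(mu))
  count_image(counts, spec$pixel_dwell_s,
              truth = list(concentration_field_uM = spec$concentration_field_uM,
                           cpp_Hz = spec$cpp_Hz,
                           v_eff_L = spec$v_eff_L,
                           expected_counts = mu,
                           seed = spec$seed))
}

#' Concentration field with a bright attachment band on a dim interior
#'
#' Convenience builder emulating a muscle attachment site: a vertical band of
#' high concentration over a dim interior and near-zero background margin.
#'
#' @param shape `c(rows, cols)`.
#' @param band_uM,interior_uM,background_uM concentrations of the band, the
#'   muscle interior and the outside background, in micromolar.
#' @param band_cols column indices of the band (default: middle fifth).
#' @param margin background margin width in pixels (default 8).
#' @return numeric matrix of concentrations (uM).
#' @export
attachment_field <- function(shape, band_uM, interior_uM, background_uM = 0,
                             band_cols = NULL, margin = 8L) {
  assert_that(length(shape) == 2L && all(shape >= 4), "shape must be >= 4 x 4")
  f <- matrix(background_uM, nrow = shape[1], ncol = shape[2])
  inner_r <- (margin + 1L):(shape[1] - margin)
  inner_c <- (margin + 1L):(shape[2] - margin)
  f[inner_r, inner_c] <- interior_uM
  if (is.null(band_cols)) {
    w <- max(2L, floor(shape[2] / 5))
    mid <- floor(shape[2] / 2)
    band_cols <- (mid - floor(w / 2)):(mid + floor(w / 2))
  }
  band_cols <- intersect(band_cols, inner_c)
  f[inner_r, band_cols] <- band_uM
  f
}

#' Simulate a dye dilution series of uniform images
#'
#' One uniform image per concentration, sharing the same brightness, dwell
#' time and detection volume — the synthetic counterpart of imaging a
#' ten-fold dye dilution series to verify detector linearity.
#'
#' @param concentrations_uM positive concentrations in micromolar.
#' @param shape image shape `c(rows, cols)` (default 64 x 64).
#' @param cpp_Hz,pixel_dwell_s,v_eff_L shared calibration parameters,
#'   as in [image_spec()].
#' @param seed integer seed; image i uses `seed + i` so replicates differ.
#' @return list of [count_image()] objects.
#' @export
gen_dilution_series <- function(concentrations_uM, shape = c(64L, 64L),
                                cpp_Hz, pixel_dwell_s = 50e-6, v_eff_L,
                                seed = NULL) {
  assert_that(length(concentrations_uM) >= 1L,
              "at least one concentration required")
  assert_that(all(concentrations_uM >= 0), "concentrations must be >= 0")
  lapply(seq_along(concentrations_uM), function(i) {
    field <- matrix(concentrations_uM[i], nrow = shape[1], ncol = shape[2])
    gen_attachment_image(image_spec(field, cpp_Hz = cpp_Hz,
                                    pixel_dwell_s = pixel_dwell_s,
                                    v_eff_L = v_eff_L,
                                    seed = if (is.null(seed)) NULL else seed + i))
  })
}
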