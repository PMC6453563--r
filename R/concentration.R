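#' Convert photon counts to molecule numbers per pixel
#'
#' `N(x,y) = I(x,y) / (CPP * PT)`: the photon count in a pixel divided by the
#' molecular brightness times the pixel dwell time gives the number of
#' molecules in the detection volume at that pixel (assuming monomers;
#' set `oligomer_factor` to the particle size otherwise). Pixels whose count
#' rate reaches the detector saturation threshold are set to `NA` and should
#' be excluded from downstream statistics.
#'
#' @param image a [count_image()].
#' @param cpp_Hz molecular brightness, Hz per molecule.
#' @param oligomer_factor molecules per diffusing particle (default 1,
#'   the monomer assumption).
#' @param saturation_Hz count-rate saturation threshold (default 2e6 Hz).
#' @return matrix of molecule numbers per pixel volume (NA where saturated),
#'   with attribute `n_saturated`.
#' @export
counts_to_molecules <- function(image, cpp_Hz, oligomer_factor = 1,
                                saturation_Hz = DEFAULT_SATURATION_HZ) {
  assert_that(inherits(image, "count_image"), "`image` must be a count_image")
  assert_positive(cpp_Hz, "cpp_Hz")
  assert_positive(oligomer_factor, "oligomer_factor")
  rate <- image$counts / image$pixel_dwell_s
  saturated <- rate >= saturation_Hz
  if (any(saturated)) {
    warning(sprintf("%d saturated pixel(s) (rate >= %.3g Hz) set to NA",
                    sum(saturated), saturation_Hz))
  }
  N <- image$counts / (cpp_Hz * image$pixel_dwell_s) * oligomer_factor
  N[saturated] <- NA_real_
  attr(N, "n_saturated") <- sum(saturated)
  N
}

#' Convert a molecule map to a molar concentration map
#'
#' `c(x,y) = N(x,y) / (N_A * V_eff)`, reported in micromolar.
#'
#' @param molecules matrix of molecule numbers per pixel volume.
#' @param v_eff_L effective detection volume in litres.
#' @return object of class `concentration_map`: `concentration_uM` (matrix),
#'   `molecules`, `v_eff_L`.
#' @export
molecules_to_concentration <- function(molecules, v_eff_L) {
  assert_positive(v_eff_L, "v_eff_L")
  assert_that(is.matrix(molecules), "`molecules` must be a matrix")
  c_uM <- molecules / (N_AVOGADRO * v_eff_L) * 1e6
  attr(c_uM, "n_saturated") <- NULL
  structure(list(concentration_uM = c_uM, molecules = molecules,
                 v_eff_L = v_eff_L,
                 n_saturated = attr(molecules, "n_saturated")),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  cat(sprintf("<concentration_map> %d x %d px, mean %.4g uM (V_eff = %.3g fL)\n",
              nrow(x$concentration_uM), ncol(x$concentration_uM),
              mean(x$concentration_uM, na.rm = TRUE), x$v_eff_L * 1e15))
  invisible(x)
}

#' Calibrate a count image to a concentration map
#'
#' Composition of [counts_to_molecules()] and
#' [molecules_to_concentration()].
#'
#' @inheritParams counts_to_molecules
#' @inheritParams molecules_to_concentration
#' @return a `concentration_map`.
#' @export
calibrate_image <- function(image, cpp_Hz, v_eff_L, oligomer_factor = 1,
                            saturation_Hz = DEFAULT_SATURATION_HZ) {
  molecules_to_concentration(
    counts_to_molecules(image, cpp_Hz, oligomer_factor, saturation_Hz),
    v_eff_L)
}

#' Mean concentration inside an attachment-site mask
#'
#' Arithmetic mean of the concentration over masked, non-saturated pixels;
#' one value per image (i.e. per pupa).
#'
#' @param conc a `concentration_map`.
#' @param mask a `region_mask` or logical matrix.
#' @return mean concentration in micromolar.
#' @export
mean_attachment_concentration <- function(conc, mask) {
  assert_that(inherits(conc, "concentration_map"),
              "`conc` must be a concentration_map")
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  assert_that(is.logical(m) && all(dim(m) == dim(conc$concentration_uM)),
              "mask dimensions must match the concentration map")
  assert_that(any(m), "mask is empty")
  mean(conc$concentration_uM[m], na.rm = TRUE)
}

#' Detector linearity check on a dilution series
#'
#' Regresses log10(mean counts) on log10(concentration) across a dilution
#' series; a slope of 1 over several decades demonstrates that photon counts
#' are proportional to fluorophore concentration, so bright attachment sites
#' and the dim muscle interior can be compared on one scale.
#'
#' @param series list of [count_image()] (one per concentration).
#' @param true_concentrations_uM the corresponding concentrations.
#' @param saturation_Hz images whose mean count rate exceeds this are
#'   excluded with a warning (default 2e6 Hz).
#' @return list with `slope`, `r_squared`, `intercept`, `n_used`,
#'   and the per-image `mean_counts`.
#' @export
linearity_check <- function(series, true_concentrations_uM,
                            saturation_Hz = DEFAULT_SATURATION_HZ) {
  assert_that(length(series) == length(true_concentrations_uM),
              "series and concentrations must have equal length")
  mean_counts <- vapply(series, function(im) mean(im$counts), numeric(1))
  rates <- vapply(series, function(im) mean(im$counts) / im$pixel_dwell_s,
                  numeric(1))
  ok <- mean_counts > 0 & true_concentrations_uM > 0
  if (any(rates >= saturation_Hz)) {
    warning(sprintf("excluding %d saturated image(s) from the linearity fit",
                    sum(rates >= saturation_Hz)))
    ok <- ok & rates < saturation_Hz
  }
  if (any(!ok & mean_counts <= 0)) {
    warning("excluding zero-mean image(s) from the linearity fit")
  }
  conc <- true_concentrations_uM[ok]
  assert_that(sum(ok) >= 3L && diff(range(log10(conc))) >= 2,
              "need >= 3 usable concentrations spanning >= 2 decades")
  fit <- stats::lm(log10(mean_counts[ok]) ~ log10(conc))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_used = sum(ok), mean_counts = mean_counts)
}
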