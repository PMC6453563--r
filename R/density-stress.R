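#' Membrane area inside the focal volume
#'
#' `total = single_plane_area * n_membranes * ruffle_factor`. At a
#' muscle-tendon attachment two membranes cross the focus (one from the
#' tendon, one from the muscle) and membrane ruffling roughly doubles the
#' area, so the default multipliers are 2 and 2. The single-plane area is an
#' input (0.63 um^2 for a 0.32 fL focus with axis ratio 5); see
#' [focal_cross_section()] for geometric helpers.
#'
#' @param single_plane_area_um2 membrane area of one flat membrane crossing
#'   the focus, um^2.
#' @param n_membranes number of membranes in the focus (default 2).
#' @param ruffle_factor area increase due to membrane ruffling (default 2).
#' @return total membrane area in um^2.
#' @export
membrane_area_in_focus <- function(single_plane_area_um2, n_membranes = 2,
                                   ruffle_factor = 2) {
  assert_positive(single_plane_area_um2, "single_plane_area_um2")
  assert_positive(n_membranes, "n_membranes")
  assert_positive(ruffle_factor, "ruffle_factor")
  single_plane_area_um2 * n_membranes * ruffle_factor
}

#' Central cross-section of an ellipsoidal focal volume
#'
#' Helper for exploring geometric conventions: given a focal volume and axis
#' ratio `S` (long axis = S times the short axes), returns the area of the
#' central axial ellipse `pi * a * c` under either the geometric-ellipsoid
#' convention (`V = 4/3 pi a^2 c`) or the Gaussian convention
#' (`V = pi^{3/2} w^2 z`). Neither convention reproduces the 0.63 um^2
#' single-plane value this stress estimate takes as input — the convention
#' behind that number cannot be reverse-engineered — so the value should be
#' supplied directly to [membrane_area_in_focus()].
#'
#' @param v_eff_L focal volume in litres.
#' @param S axis ratio (default 5).
#' @param convention `"ellipsoid"` or `"gaussian"`.
#' @return cross-section area in um^2.
#' @export
focal_cross_section <- function(v_eff_L, S = 5,
                                convention = c("ellipsoid", "gaussian")) {
  convention <- match.arg(convention)
  assert_positive(v_eff_L, "v_eff_L")
  assert_positive(S, "S")
  v_um3 <- v_eff_L * 1e15
  if (convention == "ellipsoid") {
    ## V = 4/3 pi a^2 (S a) -> a; area = pi a (S a)
    a <- (v_um3 / (4 / 3 * pi * S))^(1 / 3)
    pi * a * (S * a)
  } else {
    ## V = pi^{3/2} w^2 (S w) -> w; area = pi w (S w)
    w <- (v_um3 / (pi^1.5 * S))^(1 / 3)
    pi * w * (S * w)
  }
}

#' Surface density of molecules on the membrane
#'
#' @param molecules_in_focus number of molecules in the focal volume
#'   (e.g. the masked mean of a molecule map).
#' @param membrane_area_um2 membrane area in the focal volume, um^2.
#' @return density in molecules per um^2.
#' @export
surface_density <- function(molecules_in_focus, membrane_area_um2) {
  assert_nonneg(molecules_in_focus, "molecules_in_focus")
  assert_positive(membrane_area_um2, "membrane_area_um2")
  molecules_in_focus / membrane_area_um2
}

#' Tension-sensor estimate of tissue stress
#'
#' `stress = force_threshold * surface_density * engaged_fraction`, with
#' 1 pN/um^2 = 1 Pa, reported in kPa. This is a lower bound: each engaged
#' molecule is counted at the sensor's force threshold although it may bear
#' more.
#'
#' @param force_threshold_pN force threshold of the sensor module, pN
#'   (e.g. 7 pN for an HP-module sensor reporting 6-8 pN).
#' @param density_per_um2 surface density, molecules per um^2.
#' @param engaged_fraction fraction of mechanically engaged molecules
#'   in [0, 1].
#' @return object of class `stress_estimate`: `stress_kPa` plus the inputs.
#' @export
tissue_stress <- function(force_threshold_pN, density_per_um2, engaged_fraction) {
  assert_nonneg(force_threshold_pN, "force_threshold_pN")
  assert_nonneg(density_per_um2, "density_per_um2")
  assert_nonneg(engaged_fraction, "engaged_fraction")
  assert_that(engaged_fraction <= 1, "engaged_fraction must be <= 1")
  stress_Pa <- force_threshold_pN * density_per_um2 * engaged_fraction
  structure(list(stress_kPa = stress_Pa / 1000,
                 stress_Pa = stress_Pa,
                 force_threshold_pN = force_threshold_pN,
                 density_per_um2 = density_per_um2,
                 engaged_fraction = engaged_fraction),
            class = "stress_estimate")
}

#' @export
print.stress_estimate <- function(x, ...) {
  cat(sprintf("<stress_estimate> %.3g kPa = %g pN x %g /um^2 x %.3g engaged\n",
              x$stress_kPa, x$force_threshold_pN, x$density_per_um2,
              x$engaged_fraction))
  invisible(x)
}

#' Relative protein levels from masked mean intensities
#'
#' Computes per-image masked mean intensities and normalizes them to the
#' median of a reference group, optionally within experiment-day batches
#' (the reference median of each day is set to 1).
#'
#' @param images list of [count_image()].
#' @param masks list of `region_mask` (or logical matrices), same length.
#' @param group character vector of group labels per image.
#' @param reference_group label of the normalization group.
#' @param day optional character vector of experiment-day labels for
#'   per-day normalization.
#' @return data frame with columns `group`, `day`, `mean_intensity`,
#'   `relative_level`; images with an empty mask are dropped with a warning.
#' @export
relative_levels <- function(images, masks, group, reference_group, day = NULL) {
  assert_that(length(images) == length(masks) && length(images) == length(group),
              "images, masks and group must have equal length")
  if (is.null(day)) day <- rep("all", length(images))
  m_int <- mapply(function(im, mk) {
    m <- if (inherits(mk, "region_mask")) mk$mask else mk
    if (!any(m)) return(NA_real_)
    mean(im$counts[m])
  }, images, masks)
  if (any(is.na(m_int))) {
    warning(sprintf("dropping %d image(s) with empty masks", sum(is.na(m_int))))
  }
  df <- data.frame(group = group, day = day, mean_intensity = m_int)
  df <- df[!is.na(df$mean_intensity), , drop = FALSE]
  assert_that(any(df$group == reference_group),
              "reference group is empty after mask filtering")
  df$relative_level <- NA_real_
  for (d in unique(df$day)) {
    in_day <- df$day == d
    ref <- stats::median(df$mean_intensity[in_day & df$group == reference_group])
    assert_that(is.finite(ref) && ref > 0,
                sprintf("zero or missing reference median on day `%s`", d))
    df$relative_level[in_day] <- df$mean_intensity[in_day] / ref
  }
  df
}
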