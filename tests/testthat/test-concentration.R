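test_that("count-to-molecule calibration follows I/(CPP*PT)", {
  img <- count_image(matrix(70, 4, 4), pixel_dwell_s = 50e-6)
  N <- counts_to_molecules(img, cpp_Hz = 1400)
  expect_equal(N[1, 1], 1000)
  expect_true(all(counts_to_molecules(count_image(matrix(0, 4, 4), 50e-6),
                                      1400) == 0))
  # doubling CPP halves molecule numbers everywhere
  expect_equal(counts_to_molecules(img, 2800), N / 2, ignore_attr = TRUE)
})

test_that("saturated pixels are flagged and excluded", {
  counts <- matrix(10, 4, 4)
  counts[2, 2] <- 150           # 3 MHz at 50 us dwell
  img <- count_image(counts, pixel_dwell_s = 50e-6)
  expect_warning(N <- counts_to_molecules(img, 1400), "saturated")
  expect_true(is.na(N[2, 2]))
  expect_equal(attr(N, "n_saturated"), 1L)
})

test_that("molecule-to-concentration conversion uses Avogadro and V_eff", {
  N <- matrix(1000, 2, 2)
  cm <- molecules_to_concentration(N, v_eff_L = 0.32e-15)
  expect_equal(cm$concentration_uM[1, 1],
               1000 / (6.02214076e23 * 0.32e-15) * 1e6, tolerance = 1e-12)
  expect_equal(cm$concentration_uM[1, 1], 5.19, tolerance = 1e-3)
  expect_true(all(molecules_to_concentration(matrix(0, 2, 2),
                                             0.32e-15)$concentration_uM == 0))
})

test_that("calibration composition is exactly linear in counts", {
  img1 <- count_image(matrix(30, 8, 8), pixel_dwell_s = 50e-6)
  img3 <- count_image(matrix(90, 8, 8), pixel_dwell_s = 50e-6)
  c1 <- calibrate_image(img1, 1400, 0.32e-15)$concentration_uM
  c3 <- calibrate_image(img3, 1400, 0.32e-15)$concentration_uM
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
})

test_that("masked mean concentration averages the right pixels", {
  cm <- molecules_to_concentration(matrix(1000, 4, 4), 0.32e-15)
  mask <- matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4)
  cm$concentration_uM[!mask] <- 99
  expect_equal(mean_attachment_concentration(cm, mask), 5.19, tolerance = 1e-3)
  # half 20, half 40 -> 30
  cm2 <- molecules_to_concentration(matrix(1, 2, 2), 1)
  cm2$concentration_uM <- matrix(c(20, 20, 40, 40), 2, 2)
  expect_equal(mean_attachment_concentration(cm2, matrix(TRUE, 2, 2)), 30)
  expect_error(mean_attachment_concentration(cm2, matrix(FALSE, 2, 2)), "empty")
})

test_that("uniform-image round trip recovers the concentration within 2%", {
  field <- matrix(5, 64, 64)   # ~67 expected counts/px
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 1400,
                                         pixel_dwell_s = 50e-6,
                                         v_eff_L = 0.32e-15, seed = 31))
  cm <- calibrate_image(img, 1400, 0.32e-15)
  expect_equal(mean(cm$concentration_uM), 5, tolerance = 0.02)
})

test_that("band-image round trip recovers the attachment concentration", {
  field <- attachment_field(c(96, 96), band_uM = 30.9, interior_uM = 3,
                            background_uM = 0.1)
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 200,
                                         pixel_dwell_s = 50e-6,
                                         v_eff_L = 0.32e-15, seed = 32))
  cm <- calibrate_image(img, 200, 0.32e-15)
  mask <- build_mask(img)
  got <- mean_attachment_concentration(cm, mask)
  expect_equal(got, 30.9, tolerance = 0.03)
})

test_that("dilution series shows unit log-log slope over five decades", {
  conc <- 10^(-2:2)
  series <- gen_dilution_series(conc, shape = c(192L, 192L), cpp_Hz = 100,
                                v_eff_L = 0.32e-15, seed = 33)
  lin <- linearity_check(series, conc)
  expect_equal(lin$slope, 1.0, tolerance = 0.02)
  expect_gt(lin$r_squared, 0.999)
  expect_equal(lin$n_used, 5L)
})

test_that("linearity check drops saturated images and demands a usable span", {
  conc <- c(10^(-2:2), 1000)   # top image far beyond the 2 MHz cap
  series <- suppressWarnings(
    gen_dilution_series(conc, shape = c(128L, 128L), cpp_Hz = 100,
                        v_eff_L = 0.32e-15, seed = 34))
  expect_warning(lin <- linearity_check(series, conc), "saturated")
  expect_equal(lin$n_used, 5L)
  expect_equal(lin$slope, 1.0, tolerance = 0.03)
  two <- gen_dilution_series(c(5, 5), shape = c(16L, 16L), cpp_Hz = 100,
                             v_eff_L = 0.32e-15, seed = 35)
  expect_error(linearity_check(two, c(5, 5)), "decades|usable")
})

test_that("membrane area combines plane area, membrane count and ruffling", {
  expect_equal(membrane_area_in_focus(0.63, 2, 2), 2.52)
  expect_equal(round(membrane_area_in_focus(0.63, 2, 2), 1), 2.5)
  expect_equal(membrane_area_in_focus(0.63, 1, 1), 0.63)
  expect_equal(membrane_area_in_focus(1, 2, 2), 4)
})

test_that("surface density divides molecules by membrane area", {
  expect_equal(surface_density(1000, 2.5), 400)
  expect_equal(surface_density(0, 2.5), 0)
  expect_equal(surface_density(5750, 2.5), 2300)
})

test_that("stress estimate is multilinear with pN/um^2 = Pa", {
  expect_equal(tissue_stress(7, 400, 0.132)$stress_kPa, 0.3696)
  expect_equal(tissue_stress(7, 700, 0.096)$stress_kPa, 0.4704)
  expect_equal(tissue_stress(7, 0, 0.132)$stress_kPa, 0)
  s1 <- tissue_stress(1, 1, 1)
  expect_equal(s1$stress_Pa, 1)          # 1 pN/um^2 is exactly 1 Pa
  expect_equal(s1$stress_kPa, 1e-3)
  # multilinearity in each argument
  base <- tissue_stress(3, 500, 0.2)$stress_kPa
  expect_equal(tissue_stress(6, 500, 0.2)$stress_kPa, 2 * base)
  expect_equal(tissue_stress(3, 1000, 0.2)$stress_kPa, 2 * base)
  expect_equal(tissue_stress(3, 500, 0.4)$stress_kPa, 2 * base)
})

test_that("relative levels normalize to the reference median per day", {
  imgs <- lapply(c(100, 100, 50, 200), function(v)
    count_image(matrix(v, 8, 8), pixel_dwell_s = 50e-6))
  masks <- rep(list(matrix(TRUE, 8, 8)), 4)
  grp <- c("ref", "ref", "kd", "other")
  df <- relative_levels(imgs, masks, grp, reference_group = "ref")
  expect_equal(df$relative_level, c(1, 1, 0.5, 2))
  # empty mask drops the image with a warning
  masks[[3]] <- matrix(FALSE, 8, 8)
  expect_warning(df2 <- relative_levels(imgs, masks, grp, "ref"), "empty")
  expect_equal(nrow(df2), 3L)
})
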