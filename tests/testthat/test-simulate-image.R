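test_that("forward model gives the expected mean count per pixel", {
  # 5 uM, CPP 1400 Hz, PT 50 us, V_eff 0.32 fL -> 67.4 counts/px
  field <- matrix(5, 64, 64)
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 1400,
                                         pixel_dwell_s = 50e-6,
                                         v_eff_L = 0.32e-15, seed = 1))
  mu <- 5e-6 * 6.02214076e23 * 0.32e-15 * 1400 * 50e-6
  expect_equal(mu, 67.4, tolerance = 1e-3)
  expect_equal(img$truth$expected_counts[1, 1], mu, tolerance = 1e-9)
  expect_lt(abs(mean(img$counts) - mu), 4 * sqrt(mu / length(img$counts)))
})

test_that("zero concentration yields an all-zero image", {
  img <- gen_attachment_image(image_spec(matrix(0, 16, 16), cpp_Hz = 1400,
                                         v_eff_L = 0.32e-15, seed = 1))
  expect_true(all(img$counts == 0))
})

test_that("Poisson means scale linearly: band/interior ratio matches concentrations", {
  field <- attachment_field(c(64, 64), band_uM = 30, interior_uM = 3,
                            background_uM = 0)
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 200,
                                         v_eff_L = 0.32e-15, seed = 3))
  band <- img$counts[field == 30]
  interior <- img$counts[field == 3]
  expect_equal(mean(band) / mean(interior), 10, tolerance = 0.1)
})

test_that("negative concentrations are rejected", {
  expect_error(image_spec(matrix(-1, 4, 4), cpp_Hz = 1400, v_eff_L = 0.32e-15),
               ">= 0")
})

test_that("dilution series spans the expected decades and handles zeros", {
  conc <- c(1e-2, 1e-1, 1, 10, 100)
  series <- gen_dilution_series(conc, shape = c(32L, 32L), cpp_Hz = 100,
                                v_eff_L = 0.32e-15, seed = 7)
  expect_length(series, 5L)
  means <- vapply(series, function(im) mean(im$counts), numeric(1))
  expect_gt(log10(means[5] / max(means[1], 1e-6)), 3.5)
  z <- gen_dilution_series(0, shape = c(16L, 16L), cpp_Hz = 100,
                           v_eff_L = 0.32e-15, seed = 1)
  expect_true(all(z[[1]]$counts == 0))
  expect_error(gen_dilution_series(numeric(0), cpp_Hz = 100,
                                   v_eff_L = 0.32e-15),
               "at least one")
})

test_that("image generator warns at the detector saturation cap", {
  field <- matrix(200, 8, 8)   # 200 uM at 1400 Hz brightness: far above 2 MHz
  expect_warning(gen_attachment_image(image_spec(field, cpp_Hz = 1400,
                                                 v_eff_L = 0.32e-15, seed = 1)),
                 "2 MHz|saturation")
})
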