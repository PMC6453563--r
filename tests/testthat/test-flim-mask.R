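test_that("three-class thresholding recovers the bright band", {
  field <- attachment_field(c(96, 96), band_uM = 30, interior_uM = 3,
                            background_uM = 0.1)
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 200,
                                         v_eff_L = 0.32e-15, seed = 21))
  m <- build_mask(img)
  truth <- field == 30
  jaccard <- sum(m$mask & truth) / sum(m$mask | truth)
  expect_gte(jaccard, 0.95)
})

test_that("constant-intensity input raises a degenerate-threshold error", {
  expect_error(build_mask(matrix(7, 32, 32)), "degenerate|constant")
})

test_that("holes enclosed by the bright class are filled", {
  img <- matrix(10, 64, 64)
  img[20:44, 20:44] <- 1000
  img[30:34, 30:34] <- 10    # dark hole inside the bright region
  img[1:8, 1:8] <- 100       # mid class so three classes exist
  m <- build_mask(img)
  expect_true(all(m$mask[30:34, 30:34]))
})

test_that("masking is idempotent and deterministic", {
  field <- attachment_field(c(64, 64), 30, 3, 0.1)
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 200,
                                         v_eff_L = 0.32e-15, seed = 8))
  m1 <- build_mask(img)
  m2 <- build_mask(img)
  expect_identical(m1$mask, m2$mask)
  once <- apply_mask(img, m1)
  twice <- apply_mask(once, m1)
  expect_identical(once$counts, twice$counts)
})

test_that("polygon ROIs restrict the mask and bad ROIs are rejected", {
  field <- attachment_field(c(64, 64), 30, 3, 0.1)
  img <- gen_attachment_image(image_spec(field, cpp_Hz = 200,
                                         v_eff_L = 0.32e-15, seed = 9))
  # ROI covering only the left half
  roi <- cbind(c(1, 1, 64, 64), c(1, 32, 32, 1))
  m <- build_mask(img, roi)
  expect_true(all(which(m$mask, arr.ind = TRUE)[, "col"] <= 32))
  expect_error(build_mask(img, matrix(FALSE, 64, 64)), "empty")
  expect_error(build_mask(img, matrix(TRUE, 10, 10)), "dimensions")
})
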