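test_that("FRAP generator obeys its closed-form recovery", {
  # half of the mobile recovery is reached at t = ln2/k
  fc <- gen_frap_series(0.6, k = 0.1386, pre_bleach = 1000, post_bleach = 400,
                        duration_s = 100, dt_s = 5)
  i5 <- which(fc$times_s == 5)
  expect_equal(fc$bleach_trace[i5], 400 + 0.3 * 600, tolerance = 1e-3)
  # instantaneous full recovery jumps back to the pre-bleach level
  fast <- gen_frap_series(1, k = 1e4, pre_bleach = 1000, post_bleach = 400,
                          duration_s = 50, dt_s = 5)
  expect_equal(fast$bleach_trace[fast$times_s == 5], 1000, tolerance = 1e-6)
})

test_that("shared drift cancels in the bleach/control ratio", {
  drift <- gen_frap_series(0.6, 0.1, 1000, 400, 100, 5, drift = 0.01)
  clean <- gen_frap_series(0.6, 0.1, 1000, 400, 100, 5, drift = 0)
  # control decays ~1%/s
  expect_equal(drift$control_trace[length(drift$control_trace)] /
                 drift$control_trace[1],
               exp(-0.01 * diff(range(drift$times_s))), tolerance = 1e-9)
  ratio_d <- drift$bleach_trace / drift$control_trace
  ratio_c <- clean$bleach_trace / clean$control_trace
  expect_equal(ratio_d, ratio_c, tolerance = 1e-9)
})

test_that("FRAP generator rejects invalid inputs", {
  expect_error(gen_frap_series(0.5, 0.1, 1000, 400, 100, dt_s = 0), "dt_s")
  expect_error(gen_frap_series(0.5, 0.1, 400, 1000, 100, 5), "below")
  expect_error(gen_frap_series(1.5, 0.1, 1000, 400, 100, 5), "mobile_fraction")
})

test_that("kymograph edge moves at the prescribed rate", {
  ky <- gen_kymograph(v = 5, dt_s = 0.3, px_size_um = 0.5, n_frames = 10)
  d <- diff(ky$truth$edge_positions_um) / 0.5   # px per frame
  expect_equal(d, rep(3, 9), tolerance = 1e-9)
  static <- gen_kymograph(v = 0, dt_s = 0.3, px_size_um = 0.5, n_frames = 6,
                          noise_sd = 0)
  expect_true(all(apply(static$image, 2, function(col) diff(range(col)) == 0)))
})

test_that("kymograph generator is reproducible and warns when the edge exits", {
  a <- gen_kymograph(2, 0.3, 0.5, 20, noise_sd = 10, seed = 5)
  b <- gen_kymograph(2, 0.3, 0.5, 20, noise_sd = 10, seed = 5)
  expect_identical(a$image, b$image)
  expect_warning(gen_kymograph(50, 0.3, 0.5, 40, noise_sd = 0),
                 "field of view")
})
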