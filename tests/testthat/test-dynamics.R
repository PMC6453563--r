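test_that("FRAP normalization maps pre-bleach to 1 and first post frame to 0", {
  # plateau at 640 between post = 400 and pre = 1000 -> normalized 0.4
  times <- c(-2, -1, 0, 1, 2, 3, 4)
  curve <- list(times_s = times,
                bleach_trace = c(1000, 1000, 400, 550, 610, 635, 640),
                control_trace = rep(1000, 7), n_pre = 2L)
  nz <- normalize_frap(curve)
  expect_equal(nz$normalized[1], 0)
  expect_equal(nz$normalized[length(nz$normalized)], 0.4, tolerance = 1e-9)
})

test_that("FRAP normalization removes shared multiplicative drift", {
  fc <- gen_frap_series(0.6, 0.1, 1000, 400, 100, 5, drift = 0.01)
  clean <- gen_frap_series(0.6, 0.1, 1000, 400, 100, 5, drift = 0)
  expect_equal(normalize_frap(fc)$normalized,
               normalize_frap(clean)$normalized, tolerance = 1e-9)
  # no recovery + shared drift: trace stays at 0
  flat <- gen_frap_series(1e-9, 1, 1000, 400, 100, 5, drift = 0.01)
  flat$truth <- NULL
  expect_true(all(abs(normalize_frap(flat)$normalized) < 1e-6))
})

test_that("normalization rejects a trace without a bleach", {
  curve <- list(times_s = -4:10, bleach_trace = rep(1000, 15),
                control_trace = rep(1000, 15), n_pre = 4L)
  expect_error(normalize_frap(curve), "no bleach")
})

test_that("single-exponential FRAP fit recovers mobile fraction and half time", {
  fc <- gen_frap_series(0.6, k = 0.1386, pre_bleach = 1000, post_bleach = 400,
                        duration_s = 300, dt_s = 5)
  f <- fit_frap(normalize_frap(fc))
  expect_true(f$converged)
  expect_equal(f$mobile_fraction, 0.6, tolerance = 1e-4)
  expect_equal(f$half_time_s, 5.0, tolerance = 1e-3)
  expect_equal(f$half_time_s, log(2) / f$k_per_s, tolerance = 1e-12)
  # fully mobile pool with fast recovery and dense sampling
  fast <- gen_frap_series(1, 2, 1000, 300, 10, 0.2)
  ff <- fit_frap(normalize_frap(fast))
  expect_equal(ff$mobile_fraction, 1, tolerance = 1e-3)
})

test_that("kymograph tracking stays within one pixel of the true edge", {
  for (v in c(0, 0.5, 5)) {
    ky <- gen_kymograph(v, dt_s = 0.3, px_size_um = 0.5, n_frames = 30,
                        noise_sd = 20, seed = 100 + round(10 * v))
    tr <- track_kymograph(ky)
    err <- abs(tr$positions_um - ky$truth$edge_positions_um[seq_along(tr$positions_um)])
    expect_lt(max(err), 0.5)   # 1 px at 0.5 um/px
  }
})

test_that("a static edge yields zero net displacement", {
  ky <- gen_kymograph(0, 0.3, 0.5, 20, noise_sd = 5, seed = 6)
  tr <- track_kymograph(ky)
  expect_lt(abs(tr$positions_um[20] - tr$positions_um[1]), 0.25)
  expect_equal(recoil_velocity(tr, "single_plane"), 0, tolerance = 0.6)
})

test_that("cut frames beyond the kymograph are rejected", {
  ky <- gen_kymograph(1, 0.3, 0.5, 10, seed = 1)
  expect_error(track_kymograph(ky, cut_index = 40), "beyond")
})

test_that("recoil velocity conventions divide displacement by the right time base", {
  # single plane: displacement between first two post-cut frames over 0.3 s
  tr <- structure(list(times_s = seq(0, 1.5, by = 0.3),
                       positions_um = c(10, 10, 11.5, 13, 14.5, 16),
                       cut_index = 1L, dt_s = 0.3),
                  class = "recoil_track")
  expect_equal(recoil_velocity(tr, "single_plane"), 5.0)
  expect_equal(recoil_velocity(tr, "single_plane", baseline = "pre"), 0)
  # z stack: first post-cut position vs pre-cut over the 5.3 s stack time
  trz <- structure(list(times_s = c(0, 5.3, 10.6),
                        positions_um = c(0, 2.65, 5.3),
                        cut_index = 1L, dt_s = 5.3),
                   class = "recoil_track")
  expect_equal(recoil_velocity(trz, "z_stack"), 0.5)
  # zero displacement -> zero velocity
  tr0 <- structure(list(times_s = c(0, 0.3, 0.6), positions_um = rep(3, 3),
                        cut_index = 1L, dt_s = 0.3),
                   class = "recoil_track")
  expect_equal(recoil_velocity(tr0, "single_plane"), 0)
  # too few frames
  short <- structure(list(times_s = c(0, 0.3), positions_um = c(1, 2),
                          cut_index = 1L, dt_s = 0.3),
                     class = "recoil_track")
  expect_error(recoil_velocity(short, "single_plane"), "post-cut")
})

test_that("tracked recoil after a mid-movie cut matches the generating velocity", {
  ky <- gen_kymograph(5, 0.3, 0.5, 40, cut_frame = 10, noise_sd = 20, seed = 9)
  tr <- track_kymograph(ky)
  expect_equal(tr$cut_index, 11L)
  expect_equal(recoil_velocity(tr, "single_plane"), 5, tolerance = 0.34)
})
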