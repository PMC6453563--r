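test_that("noiseless exponential tails are fit exactly", {
  h <- noiseless_hist(amplitudes = 1e4, taus = 3.0)
  f <- fit_monoexponential_tail(h, tail_start = 0.5)
  expect_true(f$converged)
  expect_equal(f$tau_ns, 3.0, tolerance = 1e-6)
  # two points force the exponential: tau = 1/ln(c1/c2) over 1 ns
  expect_equal(1 / log(1000 / 716.53), 3.0, tolerance = 1e-4)
})

test_that("fitting a biexponential decay monoexponentially lands between the lifetimes", {
  for (fr in c(0.25, 0.5, 0.75)) {
    h <- mixture_hist(fr, photons = 1e6, seed = 30 + round(100 * fr))
    f <- fit_monoexponential_tail(h)
    expect_gt(f$tau_ns, 1.5)
    expect_lt(f$tau_ns, 3.0)
  }
})

test_that("an empty tail yields a non-converged fit rather than an error", {
  h <- decay_histogram(c(rep(1000, 20), rep(0, 136)), 0.08, 12.48)
  f <- fit_monoexponential_tail(h, tail_start = 5)
  expect_false(f$converged)
})

test_that("relative-error QC implements the 5% and 10% cut-offs", {
  mk <- function(re, conv = TRUE) structure(list(rel_error = re, converged = conv),
                                            class = "lifetime_fit")
  fits <- list(mk(0.04), mk(0.06))
  expect_length(suppressMessages(qc_filter(fits, 0.05)), 1L)
  expect_length(qc_filter(fits, 0.10), 2L)
  expect_length(suppressMessages(qc_filter(list(mk(0.01, conv = FALSE)), 0.05)), 0L)
  expect_length(qc_filter(list(), 0.05), 0L)
})

test_that("reference-lifetime calibration recovers both lifetimes", {
  donor <- lapply(1:3, function(i) mixture_hist(1, seed = 40 + i))
  ctrl <- lapply(1:3, function(i) mixture_hist(0.30, seed = 50 + i))
  cal <- calibrate_reference_lifetimes(donor, ctrl)
  expect_equal(cal$tau_noFRET_ns, 3.0, tolerance = 0.02 / 3)
  expect_equal(cal$tau_FRET_ns, 1.5, tolerance = 0.03 / 1.5)
})

test_that("a control without a FRET species makes tau_FRET unidentifiable", {
  donor <- list(mixture_hist(1, seed = 61))
  pure <- list(mixture_hist(1, seed = 62))    # no FRET component at all
  expect_error(calibrate_reference_lifetimes(donor, pure), "unidentifiable")
})

test_that("fixed-lifetime biexponential fit converts photon to molecule fractions", {
  # equal photon fractions with tau 3.0/1.5 -> molecule fraction of the FRET
  # species 2/3, i.e. f_raw(noFRET) = 1/3
  A <- c(1e4 / 3.0, 1e4 / 1.5)     # A_i tau_i equal -> p = 0.5/0.5
  h <- noiseless_hist(A, c(3.0, 1.5))
  f <- fit_biexponential_fixed(h, 3.0, 1.5, tail_start = 0.5)
  expect_equal(f$p_noFRET, 0.5, tolerance = 1e-6)
  expect_equal(f$f_raw, 1 / 3, tolerance = 1e-6)
  # photon/molecule duality: f_raw identical to the amplitude ratio
  expect_equal(f$f_raw, f$A[1] / sum(f$A), tolerance = 1e-12)
})

test_that("pure no-FRET input gives f_raw = 1 with the FRET amplitude clipped", {
  h <- mixture_hist(1, seed = 70)
  f <- suppressWarnings(fit_biexponential_fixed(h, 3.0, 1.5))
  expect_equal(f$f_raw, 1, tolerance = 5e-3)
})

test_that("biexponential fit recovers a 13.2% open fraction without bias", {
  d <- 0.25
  f_raw_true <- d + (1 - d) * 0.132
  est <- vapply(1:25, function(s) {
    h <- mixture_hist(f_raw_true, photons = 1e6, seed = 400 + s)
    fit_biexponential_fixed(h, 3.0, 1.5)$f_raw
  }, numeric(1))
  expect_lt(abs(mean(est) - f_raw_true), 0.01)
})
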