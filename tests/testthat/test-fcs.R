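test_that("autocorrelation model matches hand-evaluated amplitudes", {
  # G(0+) = 1/N
  expect_equal(acf_model("T-3D", list(N = 10, tau_diff = 5e-4, S = 5), 1e-12),
               0.1, tolerance = 1e-6)
  # at tau = tau_d with S = 5: 0.1 * 1/2 * (1 + 1/25)^(-1/2)
  expect_equal(acf_model("T-3D", list(N = 10, tau_diff = 5e-4, S = 5), 5e-4),
               0.1 * 0.5 / sqrt(1 + 1 / 25), tolerance = 1e-12)
  expect_equal(0.1 * 0.5 / sqrt(1.04), 0.04903, tolerance = 1e-4)
  # one dark state T = 0.2 raises the zero-lag limit by 1/(1-0.2)
  expect_equal(acf_model("T-3D", list(N = 10, tau_diff = 5e-4, T = 0.2,
                                      tau_trip = 1e-5, S = 5), 1e-12),
               0.125, tolerance = 1e-6)
})

test_that("zero-lag consistency G(0) (1-sum T) N = 1 holds for every model", {
  tiny <- 1e-14
  cases <- list(
    list(id = "T-3D", p = list(N = 7, tau_diff = 2e-4, T = 0.3,
                               tau_trip = 5e-6, S = 5)),
    list(id = "T-3D-3D", p = list(N = 13, tau_diff = c(3e-4, 4e-3),
                                  fractions = c(0.6, 0.4), T = 0.25,
                                  tau_trip = 8e-6, S = 5)),
    list(id = "T+T+3D+3D", p = list(N = 20, tau_diff = c(5e-4, 5e-3),
                                    fractions = c(0.8, 0.2), T = c(0.15, 0.1),
                                    tau_trip = c(1e-5, 4e-4), S = 5)))
  for (cs in cases) {
    G0 <- acf_model(cs$id, cs$p, tiny)
    Tsum <- sum(cs$p$T)
    expect_equal(G0 * (1 - Tsum) * cs$p$N, 1, tolerance = 1e-9)
  }
})

test_that("the model decays monotonically in lag time", {
  lags <- 10^seq(-6.5, 0, length.out = 200)
  grids <- expand.grid(N = c(5, 50), tau_d = c(1e-4, 2e-3), T1 = c(0, 0.3))
  for (i in seq_len(nrow(grids))) {
    g <- grids[i, ]
    G <- acf_model("T-3D", list(N = g$N, tau_diff = g$tau_d, T = g$T1,
                                tau_trip = 1e-5, S = 5), lags)
    expect_true(all(diff(G) < 0))
  }
})

test_that("detection volume matches the hand computation and its scaling law", {
  v <- detection_volume(414, 25e-6, S = 5)
  expect_equal(v$v_eff_fL, 5 * (4 * pi * 414 * 25e-6)^1.5, tolerance = 1e-12)
  expect_equal(v$v_eff_fL, 0.235, tolerance = 5e-3)
  expect_equal(v$v_eff_L, v$v_eff_fL * 1e-15, tolerance = 1e-12)
  # exact homogeneity of degree 3/2 in tau_diff
  v2 <- detection_volume(414, 50e-6, S = 5)
  expect_equal(v2$v_eff_fL / v$v_eff_fL, 2^1.5, tolerance = 1e-12)
  expect_equal(detection_volume(414, 75e-6)$v_eff_fL / v$v_eff_fL,
               3^1.5, tolerance = 1e-12)
})

test_that("noiseless curves are fit to within 1% on every parameter", {
  cv <- gen_fcs_curve(fcs_spec(20, data.frame(tau_diff_s = 5e-4, fraction = 1),
                               dark = data.frame(T = 0.15, tau_trip_s = 1e-5),
                               noise_sd = 0))
  f <- fit_acf(cv, "T-3D")
  expect_true(f$converged)
  expect_equal(f$N, 20, tolerance = 0.01)
  expect_equal(f$components$tau_diff_s[1], 5e-4, tolerance = 0.01)
  expect_equal(f$dark$T[1], 0.15, tolerance = 0.01)
  expect_equal(f$dark$tau_trip_s[1], 1e-5, tolerance = 0.01)
})

test_that("a spurious second diffusion component collapses to zero weight", {
  cv <- gen_fcs_curve(fcs_spec(20, data.frame(tau_diff_s = 5e-4, fraction = 1),
                               dark = data.frame(T = 0.15, tau_trip_s = 1e-5),
                               noise_sd = 0))
  f <- fit_acf(cv, "T-3D-3D")
  expect_true(f$converged)
  # either the second fraction vanishes or both components share tau_diff
  minor <- min(f$components$fraction)
  tau_spread <- diff(range(f$components$tau_diff_s)) / 5e-4
  expect_true(minor < 0.05 || tau_spread < 0.05)
  expect_equal(f$N, 20, tolerance = 0.02)
})

test_that("molecular brightness reduces to mean intensity per particle", {
  # <I> = 100 kHz, G0 = 0.02, T1+T2 = 0.3 -> 1400 Hz
  cpp <- cpp_with_global_dark_fractions(1e5, 0.02, 0.2, 0.1)
  expect_equal(cpp$cpp_Hz, 1400)
  expect_equal(cpp_with_global_dark_fractions(1e5, 0.02, 0, 0)$cpp_Hz, 2000)
  expect_error(cpp_with_global_dark_fractions(1e5, 0.02, 0.6, 0.5), "< 1")
  # from a fit: CPP = <I>/N whatever the dark fractions
  cv <- gen_fcs_curve(simple_fcs_spec(noise_sd = 0, N = 50, cpp = 700))
  f <- fit_acf(cv, "T-3D")
  res <- cpp_from_fit(fit = f)
  expect_equal(res$cpp_Hz, 50 * 700 / f$N, tolerance = 1e-9)
  expect_equal(res$cpp_Hz, 700, tolerance = 0.01)
  expect_equal(cpp_from_fit(0, f)$cpp_Hz, 0)
})

test_that("brightness ratio separates monomers from dimers", {
  expect_equal(brightness_ratio(c(1400, 1500), c(1400, 1500))$ratio, 1)
  expect_equal(brightness_ratio(2800, 1400)$ratio, 2)
  set.seed(5)
  mono <- rnorm(50, 1400, 100)
  dimer <- rnorm(50, 2800, 200)
  expect_equal(brightness_ratio(dimer, mono)$ratio, 2, tolerance = 0.1)
  expect_error(brightness_ratio(1400, 0), "zero")
})
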