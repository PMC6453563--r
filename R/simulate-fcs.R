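#' Specification of a synthetic FCS autocorrelation curve
#'
#' @param n_particles mean number of fluorescent particles in the detection
#'   volume (N).
#' @param diffusion data frame with columns `tau_diff_s` and `fraction`
#'   (amplitude fractions summing to 1); one or two rows.
#' @param dark data frame with columns `T` (fraction in [0,1), summing to < 1)
#'   and `tau_trip_s`; zero, one or two rows.
#' @param S axis ratio of the detection volume (default 5).
#' @param lags strictly increasing positive lag times in seconds. Default: 120
#'   points log-spaced between 1e-6 and 1 s.
#' @param noise_sd relative noise per lag: the generated curve is
#'   `G * (1 + noise_sd * Z)` with standard normal Z (default 0).
#' @param intensity_mean_Hz mean detected intensity, used downstream for
#'   molecular-brightness (CPP) computation (default `n_particles * 1000` Hz,
#'   i.e. a brightness of 1 kHz/molecule).
#' @param seed integer seed for reproducibility.
#' @return object of class `fcs_spec`.
#' @export
fcs_spec <- function(n_particles,
                     diffusion,
                     dark = NULL,
                     S = 5,
                     lags = NULL,
                     noise_sd = 0,
                     intensity_mean_Hz = NULL,
                     seed = NULL) {
  assert_positive(n_particles, "n_particles")
  diffusion <- as.data.frame(diffusion)
  assert_that(all(c("tau_diff_s", "fraction") %in% names(diffusion)),
              "`diffusion` needs columns tau_diff_s and fraction")
  assert_that(nrow(diffusion) %in% 1:2 && all(diffusion$tau_diff_s > 0),
              "one or two diffusion components with positive times required")
  assert_that(abs(sum(diffusion$fraction) - 1) < 1e-9,
              "diffusion fractions must sum to 1")
  if (!is.null(dark)) {
    dark <- as.data.frame(dark)
    assert_that(all(c("T", "tau_trip_s") %in% names(dark)),
                "`dark` needs columns T and tau_trip_s")
    assert_that(nrow(dark) <= 2L && all(dark$T >= 0) && all(dark$T < 1) &&
                  sum(dark$T) < 1 && all(dark$tau_trip_s > 0),
                "dark fractions must lie in [0,1), sum to < 1, with positive times")
  }
  if (is.null(lags)) lags <- 10^seq(-6, 0, length.out = 120)
  assert_that(length(lags) >= 1L && all(lags > 0) && all(diff(lags) > 0),
              "lags must be positive and strictly increasing")
  assert_nonneg(noise_sd, "noise_sd")
  if (is.null(intensity_mean_Hz)) intensity_mean_Hz <- n_particles * 1000
  assert_positive(intensity_mean_Hz, "intensity_mean_Hz")
  structure(list(n_particles = n_particles, diffusion = diffusion, dark = dark,
                 S = S, lags = lags, noise_sd = noise_sd,
                 intensity_mean_Hz = intensity_mean_Hz, seed = seed),
            class = "fcs_spec")
}

## model_id implied by the component / dark-state counts of a spec
fcs_spec_model_id <- function(spec) {
  n_comp <- nrow(spec$diffusion)
  n_dark <- if (is.null(spec$dark)) 0L else nrow(spec$dark)
  if (n_comp == 1L) "T-3D" else if (n_dark == 2L) "T+T+3D+3D" else "T-3D-3D"
}

fcs_spec_params <- function(spec) {
  list(N = spec$n_particles,
       tau_diff = spec$diffusion$tau_diff_s,
       fractions = spec$diffusion$fraction,
       T = if (is.null(spec$dark)) numeric(0) else spec$dark$T,
       tau_trip = if (is.null(spec$dark)) numeric(0) else spec$dark$tau_trip_s,
       S = spec$S)
}

#' Autocorrelation curve constructor
#'
#' @param lags lag times in seconds, strictly increasing.
#' @param G correlation amplitudes.
#' @param intensity_mean_Hz mean intensity of the underlying trace in Hz.
#' @param duration_s recording duration in seconds (metadata only).
#' @param truth optional ground-truth list attached by the simulator.
#' @return object of class `fcs_curve`.
#' @export
fcs_curve <- function(lags, G, intensity_mean_Hz = NA_real_, duration_s = NA_real_,
                      truth = NULL) {
  assert_that(length(lags) == length(G) && length(lags) >= 1L,
              "lags and G must have equal positive length")
  assert_that(all(lags > 0) && all(diff(lags) > 0),
              "lags must be positive and strictly increasing")
  assert_that(all(is.finite(G)), "G must be finite")
  structure(list(lags = as.numeric(lags), G = as.numeric(G),
                 intensity_mean_Hz = intensity_mean_Hz,
                 duration_s = duration_s, truth = truth),
            class = "fcs_curve")
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("<fcs_curve> %d lags [%.3g, %.3g] s, G(first) = %.4g\n",
              length(x$lags), min(x$lags), max(x$lags), x$G[1]))
  invisible(x)
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates the diffusion + dark-state model of [acf_model()] on the spec's
#' lag grid and applies multiplicative Gaussian noise with relative standard
#' deviation `noise_sd`. The generating parameters (including the implied
#' model id and the true molecular brightness `intensity_mean_Hz /
#' n_particles`) are attached as ground truth.
#'
#' @param spec an [fcs_spec()].
#' @return an [fcs_curve()].
#' @export
gen_fcs_curve <- function(spec) {
  assert_that(inherits(spec, "fcs_spec"), "`spec` must be an fcs_spec")
  model_id <- fcs_spec_model_id(spec)
  params <- fcs_spec_params(spec)
  G <- acf_model(model_id, params, spec$lags)
  if (spec$noise_sd > 0) {
    G <- with_seed(spec$seed,
                   G * (1 + spec$noise_sd * stats::rnorm(length(G))))
  }
  fcs_curve(spec$lags, G,
            intensity_mean_Hz = spec$intensity_mean_Hz,
            truth = list(model_id = model_id, params = params,
                         cpp_Hz = spec$intensity_mean_Hz / spec$n_particles,
                         noise_sd = spec$noise_sd, seed = spec$seed))
}
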