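#' Specification of a synthetic TCSPC donor decay
#'
#' Describes a mixture of exponentially decaying fluorescence species measured
#' by time-correlated single photon counting (TCSPC) within one laser period.
#' `components` gives, per species, its fluorescence lifetime (ns) and its
#' *molecule* fraction; the photon yield of each species is proportional to
#' `fraction * lifetime`, because FRET (a shorter lifetime) also quenches the
#' number of photons emitted in the donor channel.
#'
#' @param components data frame (or list coercible to one) with columns
#'   `lifetime_ns` (> 0) and `fraction` (molecule fractions summing to 1).
#' @param total_photons expected total photon count over the histogram.
#' @param window_ns laser period / histogram window in ns (default 12.5,
#'   i.e. an 80 MHz pulsed laser).
#' @param bin_width_ns histogram bin width in ns (default 0.08). The window
#'   must be an integer multiple of the bin width (156 bins for the defaults).
#' @param background_rate_per_bin expected uncorrelated background counts per
#'   bin (default 0).
#' @param irf_sigma_ns standard deviation of an optional Gaussian instrument
#'   response jitter in ns (default 0 = ideal delta IRF).
#' @param seed integer seed; the generator is bit-reproducible under a fixed
#'   seed.
#' @return an object of class `decay_spec`.
#' @export
decay_spec <- function(components,
                       total_photons,
                       window_ns = 12.5,
                       bin_width_ns = 0.08,
                       background_rate_per_bin = 0,
                       irf_sigma_ns = 0,
                       seed = NULL) {
  components <- as.data.frame(components)
  assert_that(all(c("lifetime_ns", "fraction") %in% names(components)),
              "`components` needs columns lifetime_ns and fraction")
  assert_that(nrow(components) >= 1L, "at least one decay component required")
  assert_that(all(components$lifetime_ns > 0), "lifetimes must be positive")
  assert_that(all(components$fraction >= 0), "fractions must be non-negative")
  assert_that(abs(sum(components$fraction) - 1) < 1e-9,
              "molecule fractions must sum to 1")
  assert_positive(total_photons, "total_photons")
  assert_positive(window_ns, "window_ns")
  assert_positive(bin_width_ns, "bin_width_ns")
  ## 12.5 ns at 0.08 ns binning gives 156 full bins; the trailing partial bin
  ## is dropped, so the effective histogram window is n_bins * bin_width
  n_bins <- floor(window_ns / bin_width_ns + 1e-9)
  assert_that(n_bins >= 10, "window must hold at least 10 bins")
  assert_nonneg(background_rate_per_bin, "background_rate_per_bin")
  assert_nonneg(irf_sigma_ns, "irf_sigma_ns")
  structure(list(components = components,
                 total_photons = total_photons,
                 window_ns = n_bins * bin_width_ns,
                 n_bins = n_bins,
                 bin_width_ns = bin_width_ns,
                 background_rate_per_bin = background_rate_per_bin,
                 irf_sigma_ns = irf_sigma_ns,
                 seed = seed),
            class = "decay_spec")
}

#' Photon decay histogram constructor
#'
#' @param counts non-negative integer photon counts per bin.
#' @param bin_width_ns bin width in ns.
#' @param window_ns full histogram window in ns; `length(counts)` must equal
#'   `window_ns / bin_width_ns`.
#' @param truth optional list of ground-truth parameters (attached by the
#'   simulator).
#' @return object of class `decay_histogram` with fields `bin_centers_ns`,
#'   `counts`, `bin_width_ns`, `window_ns`, `truth`.
#' @export
decay_histogram <- function(counts, bin_width_ns, window_ns, truth = NULL) {
  assert_positive(bin_width_ns, "bin_width_ns")
  assert_positive(window_ns, "window_ns")
  n_bins <- floor(window_ns / bin_width_ns + 1e-9)
  assert_that(length(counts) == n_bins,
              "length(counts) must equal floor(window_ns / bin_width_ns)")
  assert_that(all(counts >= 0), "counts must be non-negative")
  structure(list(bin_centers_ns = (seq_len(n_bins) - 0.5) * bin_width_ns,
                 counts = as.numeric(counts),
                 bin_width_ns = bin_width_ns,
                 window_ns = window_ns,
                 truth = truth),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins x %.3g ns, %.4g photons\n",
              length(x$counts), x$bin_width_ns, sum(x$counts)))
  invisible(x)
}

## Per-bin probabilities of an exponential decay truncated to [0, window]
truncated_exp_bin_probs <- function(tau, window, bin_width) {
  edges <- seq(0, window, by = bin_width)
  p <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)
  p / (1 - exp(-window / tau))
}

#' Mean arrival time of an exponential decay truncated to a finite window
#'
#' Closed form: `tau - window / (exp(window/tau) - 1)`.
#' @param tau_ns lifetime in ns
#' @param window_ns window length in ns
#' @return mean arrival time in ns
#' @export
truncated_exp_mean <- function(tau_ns, window_ns) {
  assert_positive(tau_ns, "tau_ns")
  assert_positive(window_ns, "window_ns")
  tau_ns - window_ns / (exp(window_ns / tau_ns) - 1)
}

#' Simulate a TCSPC photon decay histogram
#'
#' Photons are allocated to species proportionally to
#' `molecule_fraction * lifetime` (donor photon yield scales with the
#' lifetime), arrival times follow each species' exponential decay truncated
#' to the laser period, and per-bin counts are Poisson distributed around the
#' model expectation. With `irf_sigma_ns > 0` the expected decay is convolved
#' with a Gaussian instrument response (circularly within the window).
#'
#' @param spec a [decay_spec()].
#' @return a [decay_histogram()] with the generating parameters in `$truth`,
#'   including the per-species photon fractions.
#' @export
gen_decay_histogram <- function(spec) {
  assert_that(inherits(spec, "decay_spec"), "`spec` must be a decay_spec")
  comps <- spec$components
  n_bins <- spec$n_bins

  ## photon share of species i: f_i * tau_i / sum_j f_j * tau_j
  photon_w <- comps$fraction * comps$lifetime_ns
  photon_frac <- photon_w / sum(photon_w)

  mean_counts <- rep(spec$background_rate_per_bin, n_bins)
  for (i in seq_len(nrow(comps))) {
    p <- truncated_exp_bin_probs(comps$lifetime_ns[i], spec$window_ns,
                                 spec$bin_width_ns)
    mean_counts <- mean_counts + spec$total_photons * photon_frac[i] * p
  }

  if (spec$irf_sigma_ns > 0) {
    ## circular convolution with a discretized Gaussian IRF
    centers <- (seq_len(n_bins) - 0.5) * spec$bin_width_ns
    half <- spec$window_ns / 2
    lag <- ifelse(centers > half, centers - spec$window_ns, centers)
    kern <- exp(-lag^2 / (2 * spec$irf_sigma_ns^2))
    kern <- kern / sum(kern)
    mean_counts <- Re(stats::fft(stats::fft(mean_counts) * stats::fft(kern),
                                 inverse = TRUE)) / n_bins
    mean_counts[mean_counts < 0] <- 0
  }

  counts <- with_seed(spec$seed, stats::rpois(n_bins, mean_counts))
  decay_histogram(counts, spec$bin_width_ns, spec$window_ns,
                  truth = list(components = comps,
                               photon_fractions = photon_frac,
                               total_photons = spec$total_photons,
                               background_rate_per_bin = spec$background_rate_per_bin,
                               mean_counts = mean_counts,
                               seed = spec$seed))
}
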