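# shared fixture builders (all synthetic, generated at test time)

# decay histogram of a no-FRET/FRET mixture; frac_noFRET = 1 gives donor-only
mixture_hist <- function(frac_noFRET, photons = 1e6, seed = 1,
                         tau_noFRET = 3.0, tau_FRET = 1.5) {
  comps <- if (frac_noFRET >= 1) {
    data.frame(lifetime_ns = tau_noFRET, fraction = 1)
  } else {
    data.frame(lifetime_ns = c(tau_noFRET, tau_FRET),
               fraction = c(frac_noFRET, 1 - frac_noFRET))
  }
  gen_decay_histogram(decay_spec(comps, total_photons = photons, seed = seed))
}

# noiseless histogram: expected bin counts of a (bi)exponential, no Poisson draw
noiseless_hist <- function(amplitudes, taus, bin_width = 0.08, n_bins = 156) {
  t <- (seq_len(n_bins) - 0.5) * bin_width
  counts <- rep(0, n_bins)
  for (i in seq_along(taus)) counts <- counts + amplitudes[i] * exp(-t / taus[i])
  decay_histogram(counts, bin_width, n_bins * bin_width)
}

# single-component FCS spec used across FCS tests
simple_fcs_spec <- function(noise_sd = 0, seed = 1, N = 20, tau_d = 5e-4,
                            T1 = 0.15, tau_t = 1e-5, cpp = 1400) {
  fcs_spec(N, diffusion = data.frame(tau_diff_s = tau_d, fraction = 1),
           dark = data.frame(T = T1, tau_trip_s = tau_t),
           noise_sd = noise_sd, intensity_mean_Hz = cpp * N, seed = seed)
}
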