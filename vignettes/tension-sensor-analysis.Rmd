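---
title: "Models and methods: FLIM-FRET tension-sensor, FCS and concentration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: FLIM-FRET tension-sensor, FCS and concentration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `tensionfret`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the underlying experimental procedure leaves them open.

## 1. Donor decays and lifetime fitting

A TCSPC histogram collects donor photon arrival times relative to the laser
pulse, at 0.08 ns resolution within a 12.5 ns inter-pulse window. Since
12.5/0.08 is not an integer, the histogram holds the 156 complete bins and
the trailing partial bin is dropped; the effective window is 12.48 ns. The
decay of a mixture of species with lifetimes `tau_i` and molecule fractions
`f_i` is modeled as a sum of exponentials truncated to the window, with the
photon yield of each species proportional to `f_i * tau_i`: FRET shortens the
lifetime *and* proportionally quenches the number of donor photons, which is
the crux of the photon-to-molecule correction later on.

**Tail fitting.** `fit_monoexponential_tail()` fits `A exp(-t/tau)` (plus an
optional constant background, off by default since the measurements analyzed
here are background-poor) to all bins at or after `tail_start`. The default
`tail_start = "auto"` is the histogram peak + 0.5 ns: the procedure fits only
the decay tail, and this skips the rise / instrument-response region without
requiring the user to pick a time. A pure exponential keeps its shape under
truncation, so no truncation correction is needed in the fit itself.

Weights are Poissonian, `1/max(counts, 1)`, with one reweighting pass using
the model-predicted counts: weighting by the *observed* counts correlates the
weights with the noise and biases the lifetime low by a few tenths of a
percent at 1e5 photons, which the reweighting pass removes (verified by the
200-seed unbiasedness test in the suite).

The reported `rel_error` is the standard error of `tau` from the fit
covariance divided by `tau`. This is the quantity on which quality control
operates: `qc_filter()` keeps fits with `rel_error <= 0.05` by default
(`0.10` is the conventional relaxation for dim samples).

## 2. Engaged-fraction estimation

The analysis assumes every sensor decay is a two-lifetime mixture: open
(no FRET, `tau_noFRET`) and closed (FRET, `tau_FRET`).
`calibrate_reference_lifetimes()` pins these down in two steps: the median
monoexponential lifetime of donor-only samples gives `tau_noFRET` (the open
sensor's linker is long enough that its FRET is negligible), and a
biexponential fit of the zero-force control with `tau_noFRET` held fixed
gives `tau_FRET`. The control works for this because it contains both closed
sensors and sensors whose acceptor never matured (dark acceptors), i.e. both
lifetimes are present. If the fitted FRET photon share of a control histogram
falls below 1e-3 the FRET lifetime is unidentifiable there and the histogram
is dropped; if all are dropped, calibration errors out.

With both lifetimes fixed, `fit_biexponential_fixed()` is *linear* in the two
amplitudes and is solved by weighted linear least squares (same Poisson
weighting and reweighting pass as above). Negative amplitude solutions are
clipped at zero and flagged. Photon fractions are
`p_i = A_i tau_i / sum_j A_j tau_j`; molecule fractions divide out the
lifetime-proportional photon yield again, so the raw open fraction is exactly
the amplitude ratio `f_raw = A_1/(A_1 + A_2)`.

**Normalization.** The control's apparent open fraction measures the
dark-acceptor fraction `d`; a sensor population with engaged fraction `f`
among fluorescent-acceptor sensors shows `f_raw_TS = d + (1 - d) f`.
`engaged_fraction()` therefore inverts by subtract-and-rescale:
`f = (f_raw_TS - f_raw_C) / (1 - f_raw_C)`. A plain division normalization is
also implemented (`method = "divide"`) but is not the default, because it
does not return zero when sensor and control coincide. This was a genuinely
open choice; the mixture-inversion derivation above is why subtract-rescale
is the default.

## 3. Segmentation

`build_mask()` reproduces the masking procedure used for both FLIM and
concentration images: median filter (3 × 3), three-class multi-level Otsu
thresholding computed on the region of interest only, mask = brightest class,
holes filled. Multi-class Otsu is implemented in the package (exhaustive
search of two thresholds maximizing between-class variance on a 128-bin
histogram) since no installed package provides the multi-level variant;
median filtering and hole filling use EBImage. Degenerate inputs (constant
intensity, or fewer than three occupied intensity levels) raise an error
rather than returning an arbitrary mask.

A caveat the tests make visible: when the bright class is photon-poor
(roughly below ~30 counts per pixel), its Poisson spread rivals the
class separation and variance-based thresholding may split the bright class
itself, biasing masked means upward. The simulation conditions keep expected
band counts above ~50 per pixel, where the mask recovers the true region
with Jaccard overlap ≥ 0.95.

## 4. FCS models and calibration

`acf_model()` implements

G(τ) = 1/N · [Σ_i F_i (1+τ/τ_{d,i})⁻¹ (1+τ/(S²τ_{d,i}))^{-1/2}] ·
(1 − ΣT + Σ_k T_k e^{−τ/τ_{t,k}}) / (1 − ΣT)

for the three model variants used here: `T-3D` (calibration dye),
`T-3D-3D` (fast-diffusing free fluorophore, where flickering folds into the
diffusion terms) and `T+T+3D+3D` (the sensor protein, with triplet and
flickering dark states and a second, purely descriptive slow diffusion
term). The *additive* multi-dark-state form is used rather than a product of
single-state factors: it is the convention of the correlation-fitting
software this analysis models, and it is the form under which the zero-lag
identity `G(0) · N · (1 − T₁ − T₂) = 1` — and with it the brightness formula
`CPP = ⟨I⟩ G(0)(1 − T₁ − T₂) = ⟨I⟩/N` — holds exactly. For a single dark
state both forms coincide.

`fit_acf()` runs bounded Levenberg–Marquardt with the axis ratio fixed at
S = 5. Dark-state relaxation times are bounded in their photophysical
windows (triplet 1–20 μs, flickering 200–600 μs); the two-dark-state model is
fitted on lags above 1 μs only. Start values are reproducible heuristics:
`N` from the first-lag amplitude, `tau_d` from the half-decay lag, dark
fractions 0.1. Diffusion components are reported fastest-first; only the
first is physical. Fits are unweighted by default (per-lag sigmas can be
supplied); with the ~1–2 % multiplicative noise used in the simulations,
weighting made no practical difference to median recovery, and replicate
medians (three positions per pupa, as in the park-and-probe acquisition this
mirrors) are the robust summary used by the pipeline.

`detection_volume()` converts a calibration-dye diffusion time to
`V_eff = S (4π D τ_diff)^{3/2}` (D = 414 μm²/s for Rhodamine 6G). V_eff is
always a calibration *product*, never a hard-coded constant; the default
simulation uses a dye diffusion time of 30.74 μs, chosen so that V_eff is
0.32 fL, the worked value of the stress estimate.

## 5. Concentration, density, stress

`counts_to_molecules()` applies `N = I/(CPP · PT)` under the monomer
assumption (brightness ratio ≈ 1 against a monomeric reference; an
`oligomer_factor` is exposed for other cases). Pixels at or above the 2 MHz
detector-saturation rate (100 counts at the 50 μs default dwell) are set to
NA and counted, not silently kept. `molecules_to_concentration()` divides by
`N_A V_eff`. Both steps are exactly linear.

The membrane area in the focal volume is
`single_plane_area × n_membranes × ruffle_factor` with defaults 0.63 μm², 2
(muscle + tendon membrane) and 2 (ruffling). The 0.63 μm² single-plane area
is an *input*: neither the geometric-ellipsoid (`4/3 π a²c`) nor the Gaussian
(`π^{3/2} w² z`) volume convention reproduces it from a 0.32 fL focus via the
central-ellipse area (`focal_cross_section()` computes both, yielding ~0.97
and ~0.80 μm² respectively), so the originating convention is unknowable from
the stated numbers alone, and the value is taken as given. Stress is the exact
product `force threshold × density × engaged fraction` with 1 pN/μm² = 1 Pa;
it is a lower bound since engaged molecules are counted at threshold force.

## 6. FRAP and recoil

`normalize_frap()` double-normalizes: bleach/control (each scaled by its own
pre-bleach mean) removes shared acquisition photobleaching exactly for any
multiplicative drift; the affine rescale maps pre-bleach to 1 and the first
post-bleach frame to 0. `fit_frap()` fits `M (1 − e^{−kt})` to post-bleach
frames only. The pre-bleach frames serve only the normalization.

`track_kymograph()` locates the tissue edge per time row at the
maximum-magnitude intensity gradient with parabolic subpixel refinement
(the original procedure tracked manually; any consistent detector satisfying
the generator-truth recovery bound of 1 px is acceptable). Rows whose peak
gradient does not exceed 8× the row's median absolute gradient terminate the
track with a warning. `recoil_velocity()` implements both reported
conventions: single-plane initial velocity from the displacement between the
first and second post-cut frames over one 300 ms frame interval (reading the
"first 2 frames after the cut" as one interval between the two post-cut
frames; the pre-cut-baseline alternative is exposed via `baseline = "pre"`),
and z-stack average velocity over the first 5.3 s stack interval.

## 7. What the generators emulate — and what they do not

The generators produce: truncated-exponential mixture decays with Poisson
counts and lifetime-proportional photon allocation (optional Gaussian IRF,
default off — the analysis fits only the tail); analytic autocorrelation
curves with multiplicative Gaussian noise (no photon-trace simulation — the
analysis fits curves, not traces); Poisson count images from a concentration
field via the forward model `counts = c N_A V_eff CPP PT`; exponential FRAP
recovery with shared multiplicative bleaching drift; and kymographs with a
sigmoid edge moving at constant velocity. All are bit-reproducible under a
fixed seed and attach their ground truth.

Not modeled: detector dead time, afterpulsing and pile-up (count rates are
kept below the 2 MHz cap where these are negligible), IRF deconvolution,
optical PSF structure beyond the ellipsoidal focal volume, photon-by-photon
scanning, background in decay histograms (exposed as `background_rate_per_bin`,
default 0, since no background level is specified for the modeled
experiments). Passing the recovery tests therefore demonstrates correctness
of the estimators under the stated noise models, not robustness to every
artifact of real detectors.

## 8. Simulation conditions and problem sizes

The default pipeline configuration encodes one consistent study condition:
reference lifetimes 3.0/1.5 ns, dark-acceptor fraction 0.25, engaged fraction
0.132, 1e6 photons per histogram; sensor FCS with N = 20,
τ_diff = 0.5 ms (plus a 5 ms descriptive component, fraction 0.2), T₁ = 0.15
(10 μs), T₂ = 0.1 (400 μs), CPP = 1400 Hz; a 5.9 μM attachment band over a
0.6 μM interior imaged at 50 μs dwell in a 0.32 fL focus; FRAP with
M = 0.6, t½ = 5 s, 1 % noise, 0.1 %/s drift; recoil at 5 μm/s sampled at
0.3 s and 0.5 μm/px. Parameter-recovery tests use 96 × 96 to 192 × 192 px
images, 100-seed Monte-Carlo medians for engaged fraction, FCS and FRAP, and
200 seeds for lifetime unbiasedness; these sizes give Monte-Carlo standard
errors comfortably below the tolerances they are tested against while the
whole suite stays fast.

## 9. Known limitations

- The engaged-fraction model assumes exactly two lifetimes; partially
  stretched intermediate states would be folded into the two-state mixture.
- Multi-Otsu masking degrades at low counts (section 3) and assumes the
  attachment is the brightest of three intensity classes.
- The two-component/two-dark-state FCS model is weakly identified on single
  noisy curves; single-curve estimates can be off by ~10 % where replicate
  medians are accurate to a few percent. The pipeline always aggregates
  replicates.
- The stress estimate inherits every upstream assumption (monomer brightness,
  membrane-area convention, threshold-force counting) and is a lower bound,
  not a measurement of absolute tissue stress.
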