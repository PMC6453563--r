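# tensionfret

Quantitative analysis of molecular tension-sensor experiments at developing
muscle attachment sites, written for microscopists who need to turn raw
photon-counting data — TCSPC decay histograms, FCS autocorrelation curves,
photon-count confocal images, FRAP traces and ablation kymographs — into
physical quantities: FRET efficiencies, the fraction of mechanically engaged
sensor molecules, absolute protein concentrations and surface densities, and
a tissue-stress estimate in kPa.

Because raw in vivo microscopy data of this kind are rarely shareable, the
package ships synthetic-data generators for every input modality, each with
attached ground truth, so the entire pipeline is testable end to end.

## The analysis in brief

**FLIM-FRET.** A genetically encoded tension sensor places a FRET pair across
a calibrated peptide linker inside Talin; force opens the linker and abolishes
FRET. The donor decay histogram (0.08 ns bins over a 12.5 ns laser period) is
tail-fitted with a monoexponential, and the FRET efficiency is

> E = 1 − τ_DA / τ_D

with τ_DA the donor lifetime with acceptor and τ_D the donor-only lifetime.
The engaged fraction comes from biexponential fits with both lifetimes fixed
(τ_noFRET for open, τ_FRET for closed sensors): photon fractions
p_i = A_i τ_i / Σ A_j τ_j are converted to molecule fractions via
f ∝ p_i / τ_i (FRET also quenches donor photon yield), which reduces exactly
to the amplitude ratio A₁/(A₁+A₂). The zero-force control construct measures
the dark-acceptor fraction d, so the true engaged fraction is recovered as
f = (f_raw,TS − f_raw,C) / (1 − f_raw,C).

**FCS calibration.** Autocorrelation curves are fitted with triplet/dark-state
× 3D-diffusion models (one or two diffusing components, one or two dark
states). The detection volume follows from a calibration dye of known
diffusion coefficient,

> V_eff = S · (4π · D · τ_diff)^{3/2},

and the molecular brightness (counts per particle) is
CPP = ⟨I⟩ · G(0) · (1 − T₁ − T₂) = ⟨I⟩ / N.

**Concentration and stress.** Photon counts convert to molecules per pixel,
N(x,y) = I(x,y) / (CPP · PT), and to molar concentration
c(x,y) = N(x,y) / (N_A · V_eff). Attachment sites are segmented by 3-class
multi-Otsu thresholding of the median-filtered image (brightest class, holes
filled). Dividing molecules in focus by the membrane area in the focal volume
gives a surface density, and

> stress = force threshold × surface density × engaged fraction

with 1 pN/μm² = 1 Pa.

**Dynamics.** FRAP recovery is drift-corrected against a control region,
normalized to [0, 1], and fitted with M·(1 − e^{−kt}) for the mobile fraction
and half time t½ = ln 2 / k. Recoil after laser ablation is tracked in
kymographs by subpixel gradient detection, with the single-plane (first two
post-cut frames) and z-stack (first stack interval) velocity conventions.

## Worked example

```r
library(tensionfret)

# donor-only decay, 1e6 photons, tail fit
h_donor <- gen_decay_histogram(decay_spec(
  data.frame(lifetime_ns = 3.0, fraction = 1), total_photons = 1e6, seed = 1))
fit <- fit_monoexponential_tail(h_donor)
fit
#> <lifetime_fit> tau = 3.003 ns (rel. error 0.12%), converged

fret_efficiency(tau_DA = 2.4, tau_D = fit$tau_ns)
#> <fret_result> E = 0.2009 (tau_DA = 2.4 ns, tau_D = 3.003 ns)

# full synthetic pipeline: decays, FCS, image calibration, stress, dynamics
rec <- run_pipeline()
rec
#> <run_record> stages: simulate, flim, fcs, concmap, stress, dynamics | ...
#>   stress: 0.41 kPa (density 437.7 /um^2, engaged 0.134)

# stress arithmetic with reference inputs
tissue_stress(7, 400, 0.132)
#> <stress_estimate> 0.37 kPa = 7 pN x 400 /um^2 x 0.132 engaged
```

The lifetime fit recovers the generating 3.0 ns lifetime to 0.1%; the
pipeline's 0.41 kPa agrees with the forward-computed truth of its synthetic
conditions (a 5.9 μM attachment band, 13.2% engagement) within a few percent.

## Analysis workflow

The `analysis/` directory holds the pipeline as numbered narrative scripts,
each a thin driver over the package functions, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R             # synthetic inputs + ground truth
Rscript analysis/02_flim_engaged_fraction.R
Rscript analysis/03_fcs_calibration.R
Rscript analysis/04_concentration_maps.R
Rscript analysis/05_density_stress.R
Rscript analysis/06_dynamics.R
```

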