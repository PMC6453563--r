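#!/usr/bin/env Rscript

# Stage 3: FCS calibration. Fit the calibration-dye curves (triplet + 3D
# diffusion) to obtain the detection volume via the known diffusion
# coefficient, fit the sample curves (two components, two dark states) for
# particle number and dark fractions, and derive the molecular brightness
# (CPP). The calibration record feeds the concentration mapping stage.

suppressPackageStartupMessages(library(tensionfret))

sim_dir <- "results/sim"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")
cfg <- default_pipeline_config()

dye <- lapply(list.files(sim_dir, "^acf_dye", full.names = TRUE), read_acf_csv)
smp <- lapply(list.files(sim_dir, "^acf_sample", full.names = TRUE), read_acf_csv)

dye_fits <- lapply(dye, fit_acf, model_id = "T-3D", S = cfg$fcs$S)
tau_ref <- median(vapply(dye_fits, function(f) f$components$tau_diff_s[1],
                         numeric(1)))
vol <- detection_volume(cfg$fcs$D_ref_um2_s, tau_ref, cfg$fcs$S)
message(sprintf("dye diffusion time %.3g us -> V_eff = %.3g fL",
                tau_ref * 1e6, vol$v_eff_fL))

smp_fits <- lapply(smp, fit_acf, model_id = cfg$fcs$sample_model, S = cfg$fcs$S)
cpps <- lapply(smp_fits, function(f) cpp_from_fit(fit = f))
cpp <- median(vapply(cpps, `[[`, numeric(1), "cpp_Hz"))
N <- median(vapply(smp_fits, `[[`, numeric(1), "N"))
message(sprintf("sample: N = %.3g particles in focus, CPP = %.4g Hz/molecule",
                N, cpp))
message(sprintf("dark fractions: T1 = %.3f, T2 = %.3f",
                median(vapply(cpps, `[[`, numeric(1), "T1")),
                median(vapply(cpps, `[[`, numeric(1), "T2"))))

write_record_json(list(v_eff_L = vol$v_eff_L, cpp_Hz = cpp, N = N,
                       S = cfg$fcs$S, D_ref_um2_s = cfg$fcs$D_ref_um2_s,
                       tau_diff_ref_s = tau_ref),
                  "results/fcs_calibration.json")
message("wrote results/fcs_calibration.json")
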