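#!/usr/bin/env Rscript

# Stage 5: membrane density and tissue stress. Combine the molecules-in-focus
# estimate (stage 4) with the membrane area in the focal volume and the
# engaged fraction (stage 2):
#   stress = force threshold x surface density x engaged fraction.

suppressPackageStartupMessages(library(tensionfret))

flim_path <- "results/flim_results.csv"
conc_path <- "results/concentration.csv"
if (!file.exists(flim_path) || !file.exists(conc_path))
  stop("run analysis stages 02 and 04 first")
cfg <- default_pipeline_config()

flim <- read.csv(flim_path)
conc <- read.csv(conc_path)
getv <- function(df, q) df$value[df$quantity == q]

area <- membrane_area_in_focus(cfg$stress$single_plane_area_um2,
                               cfg$stress$n_membranes,
                               cfg$stress$ruffle_factor)
dens <- surface_density(getv(conc, "molecules_in_focus"), area)
st <- tissue_stress(cfg$stress$force_threshold_pN, dens,
                    getv(flim, "engaged_fraction"))
message(sprintf("membrane area in focus: %.2f um^2", area))
message(sprintf("surface density: %.0f molecules/um^2", dens))
message(sprintf("tissue stress: %.2f kPa (= %g pN x %.0f /um^2 x %.3f)",
                st$stress_kPa, st$force_threshold_pN, dens,
                st$engaged_fraction))

## reference stress arithmetic for comparison
ref <- rbind(
  data.frame(case = "20h_reference", stress_kPa = tissue_stress(7, 400, 0.132)$stress_kPa),
  data.frame(case = "24h_reference", stress_kPa = tissue_stress(7, 700, 0.096)$stress_kPa),
  data.frame(case = "synthetic_run", stress_kPa = st$stress_kPa))
write.csv(ref, "results/stress.csv", row.names = FALSE)
message("wrote results/stress.csv")
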