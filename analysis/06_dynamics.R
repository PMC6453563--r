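#!/usr/bin/env Rscript

# Stage 6: turnover and tension release. Fit the FRAP recovery for mobile
# fraction and half time, and track the ablation kymograph for the initial
# recoil velocity.

suppressPackageStartupMessages(library(tensionfret))

sim_dir <- "results/sim"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")
truth <- read_record_json(file.path(sim_dir, "truth.json"))

fr <- read.csv(file.path(sim_dir, "frap_trace.csv"))
curve <- list(times_s = fr$time_s, bleach_trace = fr$bleach,
              control_trace = fr$control, n_pre = truth$kymo$frap_n_pre)
fit <- fit_frap(normalize_frap(curve))
message(sprintf("FRAP: mobile fraction %.3f (truth %.3f), half time %.2f s (truth %.2f s)",
                fit$mobile_fraction, truth$frap$mobile_fraction,
                fit$half_time_s, truth$frap$half_time_s))

kymo <- list(image = as.matrix(read.csv(file.path(sim_dir, "kymograph.csv"))),
             dt_s = truth$kymo$dt_s, px_size_um = truth$kymo$px_size_um,
             cut_frame = truth$kymo$n_pre - 1)
track <- track_kymograph(kymo)
v <- recoil_velocity(track, "single_plane")
message(sprintf("initial recoil velocity %.2f um/s (truth %.2f um/s)",
                v, truth$kymo$v_um_s))

write.csv(data.frame(
  quantity = c("mobile_fraction", "half_time_s", "recoil_um_s"),
  value = c(fit$mobile_fraction, fit$half_time_s, v)),
  "results/dynamics.csv", row.names = FALSE)
message("wrote results/dynamics.csv")
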