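#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input of the analysis with known ground
# truth, and serialize them in the formats the downstream stages consume
# (decay histograms and FCS curves as CSV, the photon-count image as 16-bit
# TIFF, FRAP traces and the kymograph as CSV, truth as JSON).

suppressPackageStartupMessages(library(tensionfret))

cfg <- default_pipeline_config()
sim_dir <- "results/sim"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

sm <- cfg$simulate
d <- sm$dark_acceptor_fraction
f_raw_ts <- d + (1 - d) * sm$engaged_fraction
mk_hist <- function(frac_noFRET, s) {
  comps <- if (frac_noFRET >= 1) {
    data.frame(lifetime_ns = sm$tau_noFRET_ns, fraction = 1)
  } else {
    data.frame(lifetime_ns = c(sm$tau_noFRET_ns, sm$tau_FRET_ns),
               fraction = c(frac_noFRET, 1 - frac_noFRET))
  }
  gen_decay_histogram(decay_spec(comps, total_photons = sm$photons, seed = s))
}

message("simulating TCSPC decays (donor-only, zero-force control, tension sensor)")
for (i in seq_len(sm$n_donor))
  write_decay_csv(mk_hist(1, cfg$seed + 100 + i),
                  file.path(sim_dir, sprintf("decay_donor_%02d.csv", i)))
for (i in seq_len(sm$n_control))
  write_decay_csv(mk_hist(d, cfg$seed + 200 + i),
                  file.path(sim_dir, sprintf("decay_control_%02d.csv", i)))
for (i in seq_len(sm$n_ts))
  write_decay_csv(mk_hist(f_raw_ts, cfg$seed + 300 + i),
                  file.path(sim_dir, sprintf("decay_ts_%02d.csv", i)))

message("simulating FCS curves (calibration dye + sample, 3 positions each)")
rh <- sm$rhodamine
for (i in 1:3) {
  cv <- gen_fcs_curve(fcs_spec(rh$n_particles,
    data.frame(tau_diff_s = rh$tau_diff_s, fraction = 1),
    dark = data.frame(T = rh$T1, tau_trip_s = rh$tau_trip1_s),
    S = cfg$fcs$S, noise_sd = rh$noise_sd, seed = cfg$seed + 400 + i))
  write_acf_csv(cv, file.path(sim_dir, sprintf("acf_dye_%02d.csv", i)))
}
sf <- sm$sample_fcs
for (i in 1:3) {
  cv <- gen_fcs_curve(fcs_spec(sf$n_particles,
    data.frame(tau_diff_s = c(sf$tau_diff_s, sf$tau_diff2_s),
               fraction = c(sf$fraction1, 1 - sf$fraction1)),
    dark = data.frame(T = c(sf$T1, sf$T2),
                      tau_trip_s = c(sf$tau_trip1_s, sf$tau_trip2_s)),
    S = cfg$fcs$S, noise_sd = sf$noise_sd,
    intensity_mean_Hz = sf$cpp_Hz * sf$n_particles,
    seed = cfg$seed + 500 + i))
  write_acf_csv(cv, file.path(sim_dir, sprintf("acf_sample_%02d.csv", i)))
}

message("simulating the attachment-site photon-count image")
v_eff_true <- detection_volume(cfg$fcs$D_ref_um2_s, rh$tau_diff_s,
                               cfg$fcs$S)$v_eff_L
im <- sm$image
field <- attachment_field(im$shape, im$band_uM, im$interior_uM, im$background_uM)
img <- gen_attachment_image(image_spec(field, cpp_Hz = sf$cpp_Hz,
                                       pixel_dwell_s = cfg$imaging$pixel_dwell_s,
                                       v_eff_L = v_eff_true,
                                       seed = cfg$seed + 600))
write_count_tiff(img, file.path(sim_dir, "attachment_image.tif"))

message("simulating FRAP traces and the ablation kymograph")
fr <- sm$frap
fc <- gen_frap_series(fr$mobile_fraction, fr$k_per_s, fr$pre_bleach,
                      fr$post_bleach, fr$duration_s, fr$dt_s, fr$drift,
                      fr$noise_sd, seed = cfg$seed + 700)
write.csv(data.frame(time_s = fc$times_s, bleach = fc$bleach_trace,
                     control = fc$control_trace),
          file.path(sim_dir, "frap_trace.csv"), row.names = FALSE)
ky <- sm$kymo
kymo <- gen_kymograph(ky$v_um_s, ky$dt_s, ky$px_size_um, ky$n_frames,
                      cut_frame = ky$cut_frame, noise_sd = ky$noise_sd,
                      seed = cfg$seed + 800)
write.csv(kymo$image, file.path(sim_dir, "kymograph.csv"), row.names = FALSE)

write_record_json(list(
  engaged_fraction = sm$engaged_fraction,
  f_raw_ts = f_raw_ts,
  dark_acceptor_fraction = d,
  tau_noFRET_ns = sm$tau_noFRET_ns, tau_FRET_ns = sm$tau_FRET_ns,
  v_eff_L = v_eff_true, cpp_Hz = sf$cpp_Hz,
  band_uM = im$band_uM,
  frap = list(mobile_fraction = fr$mobile_fraction,
              half_time_s = log(2) / fr$k_per_s),
  kymo = list(v_um_s = ky$v_um_s, dt_s = ky$dt_s,
              px_size_um = ky$px_size_um, n_pre = ky$cut_frame + 1,
              frap_n_pre = 5),
  seed = cfg$seed), file.path(sim_dir, "truth.json"))

message("wrote synthetic inputs and ground truth to ", sim_dir)
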