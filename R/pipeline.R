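#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its default. Units are encoded
#' in the field names (`_ns`, `_s`, `_uM`, `_pN`, `_um2`, `_Hz`, `_L`).
#' The simulation block describes a 20 h APF-like muscle attachment:
#' tension-sensor decays with reference lifetimes 3.0 / 1.5 ns, a
#' dark-acceptor fraction of 0.25, an engaged fraction of 0.132, an
#' attachment band at 5.9 uM over a dim interior, a molecular brightness of
#' 1400 Hz and a 0.32 fL detection volume.
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "flim", "fcs", "concmap", "stress", "dynamics"),
    flim = list(
      tail_start = "auto",
      max_rel_error = 0.05,
      normalization = "subtract_rescale"
    ),
    fcs = list(
      S = 5,
      D_ref_um2_s = 414,          # Rhodamine 6G, for V_eff calibration
      sample_model = "T+T+3D+3D"
    ),
    imaging = list(
      pixel_dwell_s = 50e-6,
      saturation_Hz = 2e6
    ),
    stress = list(
      force_threshold_pN = 7,     # HP sensor module, reports 6-8 pN
      single_plane_area_um2 = 0.63,
      n_membranes = 2,
      ruffle_factor = 2
    ),
    simulate = list(
      tau_noFRET_ns = 3.0,
      tau_FRET_ns = 1.5,
      dark_acceptor_fraction = 0.25,
      engaged_fraction = 0.132,
      photons = 1e6,
      n_donor = 3L, n_control = 3L, n_ts = 3L,
      rhodamine = list(n_particles = 5, tau_diff_s = 3.074e-5,
                       T1 = 0.15, tau_trip1_s = 5e-6, noise_sd = 0.01),
      sample_fcs = list(n_particles = 20, tau_diff_s = 5e-4, fraction1 = 0.8,
                        tau_diff2_s = 5e-3, T1 = 0.15, tau_trip1_s = 1e-5,
                        T2 = 0.1, tau_trip2_s = 4e-4, cpp_Hz = 1400,
                        noise_sd = 0.01),
      image = list(shape = c(96L, 96L), band_uM = 5.9, interior_uM = 0.6,
                   background_uM = 0.05),
      frap = list(mobile_fraction = 0.6, k_per_s = 0.1386, pre_bleach = 1000,
                  post_bleach = 400, duration_s = 300, dt_s = 5,
                  drift = 0.001, noise_sd = 0.01),
      kymo = list(v_um_s = 5, dt_s = 0.3, px_size_um = 0.5, n_frames = 40L,
                  cut_frame = 10L, noise_sd = 20)
    )
  )
}

## recursive merge of user values over defaults; unknown keys rejected
merge_config <- function(user, defaults, path = "") {
  assert_that(is.list(user), sprintf("config section `%s` must be a mapping", path))
  unknown <- setdiff(names(user), names(defaults))
  assert_that(length(unknown) == 0L,
              sprintf("unknown config key%s: %s",
                      if (length(unknown) > 1L) "s" else "",
                      paste0(path, unknown, collapse = ", ")))
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_config(user[[nm]], defaults[[nm]],
                                paste0(path, nm, "/"))
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) file, validates it against the schema of
#' [default_pipeline_config()] (unknown keys are an error) and fills in
#' defaults. Quantities given as strings with units (e.g. `"7 pN"`,
#' `"50 us"`) are converted to the internal numeric representation.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- default_pipeline_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(user, defaults)
  cfg$stress$force_threshold_pN <-
    parse_quantity(cfg$stress$force_threshold_pN, "pN", "force_threshold_pN")
  if (is.character(cfg$imaging$pixel_dwell_s)) {
    cfg$imaging$pixel_dwell_s <-
      parse_quantity(cfg$imaging$pixel_dwell_s, c("us", "μs"),
                     "pixel_dwell_s") * 1e-6
  }
  if (!identical(cfg$flim$tail_start, "auto")) {
    cfg$flim$tail_start <- parse_quantity(cfg$flim$tail_start, "ns", "tail_start")
  }
  assert_that(all(cfg$stages %in% default_pipeline_config()$stages),
              "unknown stage name in `stages`")
  cfg
}

## simulate every input of the pipeline from the config's study conditions
simulate_stage <- function(cfg) {
  sm <- cfg$simulate
  seed <- cfg$seed
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
  donor <- lapply(seq_len(sm$n_donor), function(i) mk_hist(1, seed + 100 + i))
  control <- lapply(seq_len(sm$n_control), function(i) mk_hist(d, seed + 200 + i))
  ts <- lapply(seq_len(sm$n_ts), function(i) mk_hist(f_raw_ts, seed + 300 + i))

  ## FCS at 3 positions each (park-and-probe), kept as replicate curves
  rh <- sm$rhodamine
  rhod_curves <- lapply(1:3, function(i) gen_fcs_curve(fcs_spec(
    rh$n_particles,
    diffusion = data.frame(tau_diff_s = rh$tau_diff_s, fraction = 1),
    dark = data.frame(T = rh$T1, tau_trip_s = rh$tau_trip1_s),
    S = cfg$fcs$S, noise_sd = rh$noise_sd, seed = seed + 400 + i)))

  sf <- sm$sample_fcs
  sample_curves <- lapply(1:3, function(i) gen_fcs_curve(fcs_spec(
    sf$n_particles,
    diffusion = data.frame(tau_diff_s = c(sf$tau_diff_s, sf$tau_diff2_s),
                           fraction = c(sf$fraction1, 1 - sf$fraction1)),
    dark = data.frame(T = c(sf$T1, sf$T2),
                      tau_trip_s = c(sf$tau_trip1_s, sf$tau_trip2_s)),
    S = cfg$fcs$S, noise_sd = sf$noise_sd,
    intensity_mean_Hz = sf$cpp_Hz * sf$n_particles, seed = seed + 500 + i)))

  v_eff_true <- detection_volume(cfg$fcs$D_ref_um2_s, rh$tau_diff_s,
                                 cfg$fcs$S)$v_eff_L
  im <- sm$image
  field <- attachment_field(im$shape, im$band_uM, im$interior_uM,
                            im$background_uM)
  image <- gen_attachment_image(image_spec(field, cpp_Hz = sf$cpp_Hz,
                                           pixel_dwell_s = cfg$imaging$pixel_dwell_s,
                                           v_eff_L = v_eff_true,
                                           seed = seed + 600))
  fr <- sm$frap
  frap <- gen_frap_series(fr$mobile_fraction, fr$k_per_s, fr$pre_bleach,
                          fr$post_bleach, fr$duration_s, fr$dt_s, fr$drift,
                          fr$noise_sd, seed = seed + 700)
  ky <- sm$kymo
  kymo <- gen_kymograph(ky$v_um_s, ky$dt_s, ky$px_size_um, ky$n_frames,
                        cut_frame = ky$cut_frame, noise_sd = ky$noise_sd,
                        seed = seed + 800)
  list(donor = donor, control = control, ts = ts,
       rhodamine_curves = rhod_curves, sample_curves = sample_curves,
       image = image, frap = frap, kymo = kymo,
       truth = list(engaged_fraction = sm$engaged_fraction,
                    f_raw_ts = f_raw_ts, dark_acceptor_fraction = d,
                    v_eff_L = v_eff_true, cpp_Hz = sf$cpp_Hz,
                    band_uM = im$band_uM))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in order on synthetic inputs generated from
#' the config's study conditions: simulate, FLIM engaged-fraction analysis,
#' FCS calibration (detection volume and molecular brightness),
#' concentration mapping, density/stress estimation, and FRAP/recoil
#' dynamics. The run record is fully determined by the config (including its
#' seed); warnings raised by any stage are captured in the record.
#'
#' @param config a config list from [read_pipeline_config()] /
#'   [default_pipeline_config()].
#' @return object of class `run_record`: `config`, `config_hash`, `results`
#'   (one entry per executed stage), `truth` (generating values), `warnings`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  warnings_log <- character(0)
  record_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  results <- list()
  sim <- NULL
  withCallingHandlers({
    for (stage in config$stages) {
      if (stage == "simulate") {
        sim <- simulate_stage(config)
        results$simulate <- list(n_histograms = length(sim$donor) +
                                   length(sim$control) + length(sim$ts))
      } else {
        assert_that(!is.null(sim), sprintf("stage `%s` needs the simulate stage", stage))
      }
      if (stage == "flim") {
        cal <- calibrate_reference_lifetimes(sim$donor, sim$control,
                                             tail_start = config$flim$tail_start)
        biexp_ts <- lapply(sim$ts, fit_biexponential_fixed,
                           tau_noFRET = cal$tau_noFRET_ns,
                           tau_FRET = cal$tau_FRET_ns,
                           tail_start = config$flim$tail_start)
        biexp_c <- lapply(sim$control, fit_biexponential_fixed,
                          tau_noFRET = cal$tau_noFRET_ns,
                          tau_FRET = cal$tau_FRET_ns,
                          tail_start = config$flim$tail_start)
        f_ts <- stats::median(vapply(biexp_ts, `[[`, numeric(1), "f_raw"))
        f_c <- stats::median(vapply(biexp_c, `[[`, numeric(1), "f_raw"))
        eng <- engaged_fraction(f_ts, f_c, method = config$flim$normalization)
        ## donor-lifetime QC and FRET efficiency of the closed state
        donor_fits <- qc_filter(cal$donor_fits, config$flim$max_rel_error)
        results$flim <- list(tau_noFRET_ns = cal$tau_noFRET_ns,
                             tau_FRET_ns = cal$tau_FRET_ns,
                             fret_E_closed = fret_efficiency(cal$tau_FRET_ns,
                                                            cal$tau_noFRET_ns)$efficiency,
                             f_raw_TS = f_ts, f_raw_control = f_c,
                             engaged_fraction = eng$f_engaged,
                             n_donor_pass_qc = length(donor_fits))
      }
      if (stage == "fcs") {
        ## per-position fits, summarized by medians (one value per pupa)
        rfits <- lapply(sim$rhodamine_curves, fit_acf, model_id = "T-3D",
                        S = config$fcs$S)
        tau_ref <- stats::median(vapply(rfits, function(f)
          f$components$tau_diff_s[1], numeric(1)))
        vol <- detection_volume(config$fcs$D_ref_um2_s, tau_ref, config$fcs$S)
        sfits <- lapply(sim$sample_curves, fit_acf,
                        model_id = config$fcs$sample_model, S = config$fcs$S)
        cpps <- lapply(sfits, function(f) cpp_from_fit(fit = f))
        results$fcs <- list(
          v_eff_L = vol$v_eff_L,
          tau_diff_ref_s = tau_ref,
          N = stats::median(vapply(sfits, `[[`, numeric(1), "N")),
          cpp_Hz = stats::median(vapply(cpps, `[[`, numeric(1), "cpp_Hz")),
          T1 = stats::median(vapply(cpps, `[[`, numeric(1), "T1")),
          T2 = stats::median(vapply(cpps, `[[`, numeric(1), "T2")))
      }
      if (stage == "concmap") {
        assert_that(!is.null(results$fcs),
                    "concmap stage needs the fcs calibration (cpp_Hz, v_eff_L)")
        mol <- counts_to_molecules(sim$image, results$fcs$cpp_Hz,
                                   saturation_Hz = config$imaging$saturation_Hz)
        conc <- molecules_to_concentration(mol, results$fcs$v_eff_L)
        mask <- build_mask(sim$image)
        results$concmap <- list(
          mean_attachment_uM = mean_attachment_concentration(conc, mask),
          molecules_in_focus = mean(mol[mask$mask], na.rm = TRUE),
          n_mask_px = mask$n_pixels,
          n_saturated = attr(mol, "n_saturated"))
      }
      if (stage == "stress") {
        assert_that(!is.null(results$concmap) && !is.null(results$flim),
                    "stress stage needs the concmap and flim stages")
        area <- membrane_area_in_focus(config$stress$single_plane_area_um2,
                                       config$stress$n_membranes,
                                       config$stress$ruffle_factor)
        dens <- surface_density(results$concmap$molecules_in_focus, area)
        st <- tissue_stress(config$stress$force_threshold_pN, dens,
                            results$flim$engaged_fraction)
        results$stress <- list(membrane_area_um2 = area,
                               density_per_um2 = dens,
                               stress_kPa = st$stress_kPa)
      }
      if (stage == "dynamics") {
        ffit <- fit_frap(normalize_frap(sim$frap))
        track <- track_kymograph(sim$kymo)
        results$dynamics <- list(mobile_fraction = ffit$mobile_fraction,
                                 half_time_s = ffit$half_time_s,
                                 recoil_um_s = recoil_velocity(track, "single_plane"))
      }
    }
  }, warning = record_warning)

  structure(list(config = config,
                 config_hash = rlang::hash(config),
                 results = results,
                 truth = if (is.null(sim)) NULL else sim$truth,
                 warnings = warnings_log),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> stages: %s | hash %s | %d warning(s)\n",
              paste(names(x$results), collapse = ", "),
              substr(x$config_hash, 1, 8), length(x$warnings)))
  if (!is.null(x$results$stress)) {
    cat(sprintf("  stress: %.3g kPa (density %.4g /um^2, engaged %.3g)\n",
                x$results$stress$stress_kPa, x$results$stress$density_per_um2,
                x$results$flim$engaged_fraction))
  }
  invisible(x)
}
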