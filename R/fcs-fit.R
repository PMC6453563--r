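## parameter vector layout per model for the least-squares engine
fcs_param_layout <- function(model_id) {
  switch(model_id,
         "T-3D" = c("N", "tau_d1", "T1", "taut1"),
         "T-3D-3D" = c("N", "tau_d1", "tau_d2", "F1", "T1", "taut1"),
         "T+T+3D+3D" = c("N", "tau_d1", "tau_d2", "F1", "T1", "taut1",
                         "T2", "taut2"))
}

fcs_params_from_vector <- function(model_id, p, S) {
  p <- as.list(p)
  if (model_id == "T-3D") {
    list(N = p$N, tau_diff = p$tau_d1, fractions = 1,
         T = p$T1, tau_trip = p$taut1, S = S)
  } else {
    Tk <- p$T1
    tt <- p$taut1
    if (model_id == "T+T+3D+3D") {
      Tk <- c(Tk, p$T2)
      tt <- c(tt, p$taut2)
    }
    list(N = p$N, tau_diff = c(p$tau_d1, p$tau_d2),
         fractions = c(p$F1, 1 - p$F1), T = Tk, tau_trip = tt, S = S)
  }
}

#' Fit an FCS autocorrelation curve
#'
#' Nonlinear least squares of [acf_model()] against a measured (or simulated)
#' autocorrelation curve, with the axis ratio `S` held fixed (default 5).
#' Dark-state relaxation times are bounded in their photophysically assigned
#' windows: triplet transitions 1-20 us, photochemical flickering 200-600 us.
#' For the two-component two-dark-state model the fit is restricted to lags
#' above 1 us.
#'
#' @param curve an [fcs_curve()].
#' @param model_id `"T-3D"`, `"T-3D-3D"` or `"T+T+3D+3D"`.
#' @param S fixed axis ratio (default 5).
#' @param weights optional per-lag sigma values; default unweighted.
#' @param min_lag_s discard lags below this before fitting; default 1e-6 for
#'   `"T+T+3D+3D"`, 0 otherwise.
#' @param init optional named list overriding the automatic start values.
#' @return object of class `fcs_fit`: `model_id`, `N`, `components`
#'   (data frame `tau_diff_s`, `fraction`), `dark` (data frame `T`,
#'   `tau_trip_s`), `S`, `residual_rms`, `converged`,
#'   `intensity_mean_Hz` (copied from the curve).
#' @export
fit_acf <- function(curve, model_id = c("T-3D", "T-3D-3D", "T+T+3D+3D"),
                    S = 5, weights = NULL, min_lag_s = NULL, init = NULL) {
  assert_that(inherits(curve, "fcs_curve"), "`curve` must be an fcs_curve")
  model_id <- match.arg(model_id)
  if (is.null(min_lag_s)) min_lag_s <- if (model_id == "T+T+3D+3D") 1e-6 else 0
  sel <- curve$lags > min_lag_s
  lags <- curve$lags[sel]
  G <- curve$G[sel]
  assert_that(length(lags) >= 20L, "need >= 20 lag points to fit")
  sig <- if (is.null(weights)) rep(1, length(G)) else weights[sel]

  ## start values: N from the first-lag amplitude, tau_d from the half-decay lag
  G1 <- max(G[1], 1e-6)
  half_idx <- which(G <= G1 / 2)[1]
  tau_half <- if (is.na(half_idx)) stats::median(lags) else lags[half_idx]
  start <- list(N = 1 / G1, tau_d1 = tau_half, tau_d2 = 10 * tau_half,
                F1 = 0.7, T1 = 0.1, taut1 = 5e-6, T2 = 0.1, taut2 = 4e-4)
  if (!is.null(init)) start[names(init)] <- init
  layout <- fcs_param_layout(model_id)
  p0 <- unlist(start[layout])

  bounds <- list(N = c(1e-3, Inf), tau_d1 = c(1e-7, 10), tau_d2 = c(1e-7, 100),
                 F1 = c(0, 1), T1 = c(0, 0.8), taut1 = c(1e-6, 2e-5),
                 T2 = c(0, 0.8), taut2 = c(2e-4, 6e-4))
  lower <- vapply(layout, function(n) bounds[[n]][1], numeric(1))
  upper <- vapply(layout, function(n) bounds[[n]][2], numeric(1))

  residual <- function(p) {
    params <- fcs_params_from_vector(model_id, stats::setNames(p, layout), S)
    if (sum(params$T) >= 1) return(rep(1e6, length(G)))
    (acf_model(model_id, params, lags) - G) / sig
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = residual,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p_hat <- if (is.null(fit)) stats::setNames(rep(NA_real_, length(layout)), layout)
           else stats::setNames(fit$par, layout)
  params <- if (all(is.finite(p_hat))) fcs_params_from_vector(model_id, p_hat, S)
            else NULL

  ## order diffusion components: the first (faster) time is the physical one
  comps <- dark <- NULL
  if (!is.null(params)) {
    ord <- order(params$tau_diff)
    comps <- data.frame(tau_diff_s = params$tau_diff[ord],
                        fraction = params$fractions[ord])
    dark <- if (length(params$T))
      data.frame(T = params$T, tau_trip_s = params$tau_trip)
    else data.frame(T = numeric(0), tau_trip_s = numeric(0))
  }
  structure(list(model_id = model_id,
                 N = if (is.null(params)) NA_real_ else params$N,
                 components = comps, dark = dark, S = S,
                 residual_rms = if (converged) sqrt(mean(fit$fvec^2)) else NA_real_,
                 converged = converged,
                 intensity_mean_Hz = curve$intensity_mean_Hz),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit %s> N = %.4g, tau_diff = %s s, sum(T) = %.3g, %s\n",
              x$model_id, x$N,
              paste(signif(x$components$tau_diff_s, 3), collapse = "/"),
              sum(x$dark$T),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Molecular brightness (counts per particle) from an FCS fit
#'
#' `CPP = <I> * G(0) * (1 - T1 - T2)`, where `G(0)` is the full-model
#' zero-lag amplitude `1 / (N * (1 - T1 - T2))`; the dark-state factors
#' cancel, so CPP equals `<I> / N`, the mean intensity per fluorescent
#' particle.
#'
#' @param intensity_mean_Hz mean detected intensity in Hz; if `NULL`, taken
#'   from the fit's attached curve metadata.
#' @param fit an `fcs_fit`.
#' @return object of class `cpp_result`: `cpp_Hz`, `intensity_mean_Hz`,
#'   `G0`, `T1`, `T2`.
#' @export
cpp_from_fit <- function(intensity_mean_Hz = NULL, fit) {
  assert_that(inherits(fit, "fcs_fit"), "`fit` must be an fcs_fit")
  assert_that(isTRUE(fit$converged), "fit did not converge")
  if (is.null(intensity_mean_Hz)) intensity_mean_Hz <- fit$intensity_mean_Hz
  assert_nonneg(intensity_mean_Hz, "intensity_mean_Hz")
  Tk <- fit$dark$T
  T1 <- if (length(Tk) >= 1) Tk[1] else 0
  T2 <- if (length(Tk) >= 2) Tk[2] else 0
  assert_that(T1 + T2 < 1, "total dark fraction must be below 1")
  G0 <- 1 / (fit$N * (1 - T1 - T2))
  assert_that(is.finite(G0) && G0 > 0, "zero-lag amplitude must be positive")
  structure(list(cpp_Hz = intensity_mean_Hz * G0 * (1 - T1 - T2),
                 intensity_mean_Hz = intensity_mean_Hz,
                 G0 = G0, T1 = T1, T2 = T2),
            class = "cpp_result")
}

#' @export
print.cpp_result <- function(x, ...) {
  cat(sprintf("<cpp_result> CPP = %.4g Hz/molecule (<I> = %.4g Hz, G0 = %.4g)\n",
              x$cpp_Hz, x$intensity_mean_Hz, x$G0))
  invisible(x)
}

#' Molecular brightness with globally averaged dark fractions
#'
#' For samples whose own fit cannot separate dark-state kinetics from
#' diffusion (fast-diffusing free fluorophore), the dark fractions are
#' borrowed as averages from matched measurements at the same excitation
#' power: `CPP = <I> * <G(0)> * (1 - <T1> - <T2>)`.
#'
#' @param intensity_mean_Hz mean intensity, Hz.
#' @param G0 fitted zero-lag amplitude of the sample's own (simplified) model.
#' @param T1_avg,T2_avg averaged dark fractions from the matched measurements.
#' @return a `cpp_result`.
#' @export
cpp_with_global_dark_fractions <- function(intensity_mean_Hz, G0, T1_avg, T2_avg) {
  assert_nonneg(intensity_mean_Hz, "intensity_mean_Hz")
  assert_positive(G0, "G0")
  assert_nonneg(T1_avg, "T1_avg")
  assert_nonneg(T2_avg, "T2_avg")
  assert_that(T1_avg + T2_avg < 1, "averaged dark fractions must sum to < 1")
  structure(list(cpp_Hz = intensity_mean_Hz * G0 * (1 - T1_avg - T2_avg),
                 intensity_mean_Hz = intensity_mean_Hz,
                 G0 = G0, T1 = T1_avg, T2 = T2_avg),
            class = "cpp_result")
}

#' Brightness ratio between a sample and a monomeric reference
#'
#' Ratio of median molecular brightness values; a ratio near 1 indicates a
#' monomeric sample, near 2 a dimer.
#'
#' @param cpp_sample numeric CPP values (Hz) of the sample.
#' @param cpp_reference CPP values of the monomeric reference.
#' @return list with `ratio`, `median_sample`, `median_reference`,
#'   `iqr_sample`, `iqr_reference`, `n_sample`, `n_reference`.
#' @export
brightness_ratio <- function(cpp_sample, cpp_reference) {
  assert_that(length(cpp_sample) >= 1L && length(cpp_reference) >= 1L,
              "both CPP lists must be non-empty")
  ms <- stats::median(as.numeric(cpp_sample))
  mr <- stats::median(as.numeric(cpp_reference))
  assert_that(mr != 0, "reference median brightness is zero")
  list(ratio = ms / mr, median_sample = ms, median_reference = mr,
       iqr_sample = stats::IQR(as.numeric(cpp_sample)),
       iqr_reference = stats::IQR(as.numeric(cpp_reference)),
       n_sample = length(cpp_sample), n_reference = length(cpp_reference))
}
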