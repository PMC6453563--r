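#' FCS autocorrelation model function
#'
#' Evaluates the confocal FCS autocorrelation
#' \deqn{G(\tau) = \frac{1}{N}\,
#'   \Big[\sum_i F_i\,(1+\tau/\tau_{d,i})^{-1}(1+\tau/(S^2\tau_{d,i}))^{-1/2}\Big]
#'   \cdot \frac{1-\sum_k T_k + \sum_k T_k e^{-\tau/\tau_{t,k}}}{1-\sum_k T_k}}
#' for an ellipsoidal detection volume with axis ratio `S`, one or two 3D
#' diffusing components with amplitude fractions `F_i`, and zero, one or two
#' non-fluorescent dark states (triplet / photochemical flickering) with
#' fractions `T_k` and relaxation times. The dark-state term uses the additive
#' multi-state convention, so the zero-lag amplitude satisfies
#' `G(0) * N * (1 - sum(T)) = 1` exactly.
#'
#' Supported `model_id`s: `"T-3D"` (one diffusing component, one dark state),
#' `"T-3D-3D"` (two diffusing components, one dark state) and `"T+T+3D+3D"`
#' (two diffusing components, two dark states).
#'
#' @param model_id one of `"T-3D"`, `"T-3D-3D"`, `"T+T+3D+3D"`.
#' @param params named list: `N` (> 0), `tau_diff` (s; length 1 or 2),
#'   `fractions` (diffusion amplitude fractions summing to 1; defaults to
#'   `1` / `c(0.5, 0.5)`), `T` (dark-state fractions, each in [0, 1) and
#'   summing to < 1; may be empty), `tau_trip` (s, same length as `T`),
#'   `S` (axis ratio, default 5).
#' @param lags lag times in seconds (positive).
#' @return numeric vector of G values.
#' @export
acf_model <- function(model_id, params, lags) {
  model_id <- match.arg(model_id, c("T-3D", "T-3D-3D", "T+T+3D+3D"))
  assert_that(length(lags) >= 1L && all(lags > 0) && all(is.finite(lags)),
              "`lags` must be positive and finite")
  n_comp <- if (model_id == "T-3D") 1L else 2L
  n_dark <- if (model_id == "T+T+3D+3D") 2L else 1L

  N <- params$N
  assert_positive(N, "N")
  tau_d <- params$tau_diff
  assert_that(length(tau_d) == n_comp && all(tau_d > 0),
              sprintf("model %s needs %d positive tau_diff value(s)", model_id, n_comp))
  F <- params$fractions
  if (is.null(F)) F <- rep(1 / n_comp, n_comp)
  assert_that(length(F) == n_comp && all(F >= 0) && abs(sum(F) - 1) < 1e-9,
              "diffusion fractions must be non-negative and sum to 1")
  Tk <- params$T
  if (is.null(Tk)) Tk <- numeric(0)
  assert_that(length(Tk) <= n_dark, sprintf("model %s allows at most %d dark state(s)",
                                            model_id, n_dark))
  tau_t <- params$tau_trip
  if (is.null(tau_t)) tau_t <- numeric(0)
  assert_that(length(tau_t) == length(Tk), "T and tau_trip lengths must match")
  assert_that(all(Tk >= 0) && all(Tk < 1) && sum(Tk) < 1,
              "dark fractions must each lie in [0,1) and sum to < 1")
  assert_that(all(tau_t > 0) || length(tau_t) == 0L, "tau_trip must be positive")
  S <- if (is.null(params$S)) 5 else params$S
  assert_positive(S, "S")

  diff_sum <- rep(0, length(lags))
  for (i in seq_len(n_comp)) {
    diff_sum <- diff_sum + F[i] / ((1 + lags / tau_d[i]) *
                                     sqrt(1 + lags / (S^2 * tau_d[i])))
  }
  dark <- 1
  if (length(Tk) > 0) {
    Tsum <- sum(Tk)
    num <- 1 - Tsum
    for (k in seq_along(Tk)) num <- num + Tk[k] * exp(-lags / tau_t[k])
    dark <- num / (1 - Tsum)
  }
  diff_sum * dark / N
}

#' Effective confocal detection volume from a calibration diffusion time
#'
#' `V_eff = S * (4 * pi * D * tau_diff)^{3/2}` with D in um^2/s and tau_diff
#' in seconds; the result (um^3) is returned in litres (1 um^3 = 1 fL =
#' 1e-15 L). Calibration is typically done with a free dye of known diffusion
#' coefficient (e.g. Rhodamine 6G, D = 414 um^2/s).
#'
#' @param D diffusion coefficient of the calibration dye, um^2/s.
#' @param tau_diff measured diffusion time, s.
#' @param S axis ratio of the detection volume (default 5).
#' @return object of class `detection_volume`: list with `v_eff_L`,
#'   `v_eff_fL`, `D_um2_s`, `tau_diff_s`, `S`.
#' @export
detection_volume <- function(D, tau_diff, S = 5) {
  assert_positive(D, "D")
  assert_positive(tau_diff, "tau_diff")
  assert_positive(S, "S")
  v_um3 <- S * (4 * pi * D * tau_diff)^1.5
  structure(list(v_eff_L = v_um3 * 1e-15,
                 v_eff_fL = v_um3,
                 D_um2_s = D,
                 tau_diff_s = tau_diff,
                 S = S),
            class = "detection_volume")
}

#' @export
print.detection_volume <- function(x, ...) {
  cat(sprintf("<detection_volume> V_eff = %.4g fL (D = %g um^2/s, tau_diff = %.3g us, S = %g)\n",
              x$v_eff_fL, x$D_um2_s, x$tau_diff_s * 1e6, x$S))
  invisible(x)
}
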