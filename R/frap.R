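#' Normalize a FRAP curve
#'
#' Double normalization: the bleached-region trace is divided by the control
#' trace (each first scaled by its own pre-bleach mean) to remove shared
#' acquisition photobleaching, then affinely rescaled so that the pre-bleach
#' level maps to 1 and the first post-bleach frame to 0.
#'
#' @param curve a `frap_curve` (see [gen_frap_series()]) or a list with
#'   `times_s`, `bleach_trace`, `control_trace`, `n_pre`.
#' @return list with `times_s` (post-bleach only, starting at 0),
#'   `normalized` (post-bleach normalized trace), `pre_bleach_level`,
#'   `first_post_level` (on the drift-corrected scale).
#' @export
normalize_frap <- function(curve) {
  req <- c("times_s", "bleach_trace", "control_trace", "n_pre")
  assert_that(all(req %in% names(curve)), "curve lacks required fields")
  assert_that(all(curve$control_trace > 0), "control trace must be strictly positive")
  n_pre <- curve$n_pre
  assert_that(n_pre >= 1L && length(curve$times_s) > n_pre + 2L,
              "need pre-bleach frames and >= 3 post-bleach frames")
  pre_idx <- seq_len(n_pre)
  b_pre <- mean(curve$bleach_trace[pre_idx])
  c_pre <- mean(curve$control_trace[pre_idx])
  corrected <- (curve$bleach_trace / b_pre) / (curve$control_trace / c_pre)
  post_idx <- (n_pre + 1L):length(curve$times_s)
  pre_level <- mean(corrected[pre_idx])    # = 1 by construction
  first_post <- corrected[post_idx[1]]
  assert_that(first_post < pre_level,
              "no bleach detected: first post-bleach frame is not below pre-bleach")
  normalized <- (corrected[post_idx] - first_post) / (pre_level - first_post)
  list(times_s = curve$times_s[post_idx],
       normalized = normalized,
       pre_bleach_level = pre_level,
       first_post_level = first_post)
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of `M * (1 - exp(-k t))` to a normalized post-bleach
#' trace, giving the mobile fraction `M` and the recovery half time
#' `t_1/2 = ln 2 / k`.
#'
#' @param normalized output of [normalize_frap()] (list with `times_s` and
#'   `normalized`).
#' @return object of class `frap_fit`: `mobile_fraction`, `k_per_s`,
#'   `half_time_s`, `converged`.
#' @export
fit_frap <- function(normalized) {
  assert_that(all(c("times_s", "normalized") %in% names(normalized)),
              "`normalized` must come from normalize_frap()")
  t <- normalized$times_s
  y <- normalized$normalized
  assert_that(length(t) >= 10L, "need >= 10 post-bleach points")
  plateau <- mean(y[t >= stats::quantile(t, 0.75)])
  M0 <- min(max(plateau, 0.05), 1)
  ## crude rate start: time to reach half the plateau
  half_idx <- which(y >= M0 / 2)[1]
  k0 <- if (is.na(half_idx) || t[half_idx] <= 0) 1 / max(t) else log(2) / t[half_idx]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ M * (1 - exp(-k * t)),
                      data = data.frame(t = t, y = y),
                      start = list(M = M0, k = k0),
                      lower = c(0, 1e-6), upper = c(1.5, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(mobile_fraction = NA_real_, k_per_s = NA_real_,
                          half_time_s = NA_real_, converged = FALSE),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(mobile_fraction = unname(cf["M"]),
                 k_per_s = unname(cf["k"]),
                 half_time_s = log(2) / unname(cf["k"]),
                 converged = TRUE),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile fraction = %.3g, half time = %.3g s\n",
              x$mobile_fraction, x$half_time_s))
  invisible(x)
}
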