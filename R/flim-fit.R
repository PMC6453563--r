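## resolve the tail-start time: "auto" = histogram peak + 0.5 ns, skipping the
## rise / instrument-response region
resolve_tail_start <- function(hist, tail_start) {
  if (identical(tail_start, "auto")) {
    hist$bin_centers_ns[which.max(hist$counts)] + 0.5
  } else {
    assert_nonneg(tail_start, "tail_start")
    tail_start
  }
}

lifetime_fit <- function(tau = NA_real_, amplitude = NA_real_,
                         background = 0, rel_error = NA_real_,
                         tail_start = NA_real_, converged = FALSE) {
  structure(list(tau_ns = tau, amplitude = amplitude, background = background,
                 rel_error = rel_error, tail_start_ns = tail_start,
                 converged = converged),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit> tau = %.4g ns (rel. error %.2g%%), %s\n",
              x$tau_ns, 100 * x$rel_error,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Monoexponential tail fit of a photon decay histogram
#'
#' Weighted least-squares fit of `A * exp(-t / tau)` (optionally plus a
#' constant background) to all bins at or after `tail_start`. Weights are
#' `1 / max(count, 1)`, the Poisson variance estimate for photon-counting
#' data. The relative error is the standard error of `tau` from the fit
#' covariance divided by `tau`, the quantity used for quality filtering.
#'
#' @param hist a [decay_histogram()].
#' @param tail_start start of the fitted tail in ns, or `"auto"`
#'   (histogram peak + 0.5 ns).
#' @param fit_background also fit a constant background per bin
#'   (default `FALSE`).
#' @return a `lifetime_fit`: `tau_ns`, `amplitude` (at t = 0), `background`,
#'   `rel_error`, `tail_start_ns`, `converged`.
#' @export
fit_monoexponential_tail <- function(hist, tail_start = "auto",
                                     fit_background = FALSE) {
  assert_that(inherits(hist, "decay_histogram"), "`hist` must be a decay_histogram")
  t0 <- resolve_tail_start(hist, tail_start)
  sel <- hist$bin_centers_ns >= t0
  assert_that(sum(sel) >= 10L, "need >= 10 bins after tail_start")
  t <- hist$bin_centers_ns[sel]
  y <- hist$counts[sel]
  if (sum(y) <= 0) return(lifetime_fit(tail_start = t0, converged = FALSE))
  w <- 1 / pmax(y, 1)

  ## log-linear start values on positive counts
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ t[pos])
  tau0 <- unname(-1 / stats::coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  A0 <- unname(exp(stats::coef(lf)[1]))
  if (!is.finite(A0) || A0 <= 0) A0 <- max(y)

  df <- data.frame(t = t, y = y)
  do_fit <- function(w) tryCatch({
    if (fit_background) {
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + b, data = df, weights = w,
                        start = list(A = A0, tau = tau0, b = 0),
                        lower = c(0, 1e-3, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df, weights = w,
                        start = list(A = A0, tau = tau0),
                        lower = c(0, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  fit <- do_fit(w)
  if (is.null(fit)) return(lifetime_fit(tail_start = t0, converged = FALSE))
  ## one reweighting pass with model-predicted variances: weighting by the
  ## observed counts themselves correlates weights with noise and biases tau
  ## low at moderate photon numbers
  refit <- do_fit(1 / pmax(stats::fitted(fit), 1))
  if (!is.null(refit)) fit <- refit

  cf <- summary(fit)$coefficients
  tau <- cf["tau", "Estimate"]
  rel <- cf["tau", "Std. Error"] / tau
  at_bound <- tau <= 1.5e-3
  lifetime_fit(tau = tau, amplitude = cf["A", "Estimate"],
               background = if (fit_background) cf["b", "Estimate"] else 0,
               rel_error = rel, tail_start = t0,
               converged = is.finite(tau) && is.finite(rel) && !at_bound)
}

#' Quality-filter lifetime fits by relative error
#'
#' Keeps only converged fits whose relative lifetime error is at or below the
#' cut-off (5% by default; 10% is used for dim samples). The number of
#' excluded fits is reported via `message()`.
#'
#' @param fits list of `lifetime_fit` (or `biexp_fit`) objects.
#' @param max_rel_error relative-error cut-off (default 0.05).
#' @return the retained sublist.
#' @export
qc_filter <- function(fits, max_rel_error = 0.05) {
  assert_positive(max_rel_error, "max_rel_error")
  keep <- vapply(fits, function(f) {
    isTRUE(f$converged) && is.finite(f$rel_error) && f$rel_error <= max_rel_error
  }, logical(1))
  if (any(!keep)) {
    message(sprintf("qc_filter: excluded %d of %d fits (rel_error > %g or not converged)",
                    sum(!keep), length(fits), max_rel_error))
  }
  fits[keep]
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, with `tau_DA` the donor lifetime in presence of
#' the acceptor and `tau_D` the donor-only lifetime.
#'
#' @param tau_DA donor lifetime with acceptor, ns.
#' @param tau_D donor-only lifetime, ns.
#' @return object of class `fret_result`: `efficiency`, `tau_DA_ns`,
#'   `tau_D_ns`.
#' @export
fret_efficiency <- function(tau_DA, tau_D) {
  assert_positive(tau_DA, "tau_DA")
  assert_positive(tau_D, "tau_D")
  structure(list(efficiency = 1 - tau_DA / tau_D,
                 tau_DA_ns = tau_DA, tau_D_ns = tau_D),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("<fret_result> E = %.4g (tau_DA = %.4g ns, tau_D = %.4g ns)\n",
              x$efficiency, x$tau_DA_ns, x$tau_D_ns))
  invisible(x)
}

## weighted linear solve of counts ~ A1*x1 + A2*x2 with non-negative
## amplitudes; returns c(A1, A2) and a clipped flag
solve_two_amplitudes <- function(y, x1, x2, w) {
  X <- cbind(x1, x2)
  XtW <- t(X * w)
  M <- XtW %*% X
  b <- XtW %*% y
  A <- tryCatch(as.numeric(solve(M, b)), error = function(e) c(NA_real_, NA_real_))
  clipped <- FALSE
  if (any(!is.finite(A))) return(list(A = c(NA_real_, NA_real_), clipped = TRUE))
  if (any(A < 0)) {
    clipped <- TRUE
    ## refit the other component alone
    if (A[1] < 0) {
      A <- c(0, sum(w * x2 * y) / sum(w * x2^2))
    } else {
      A <- c(sum(w * x1 * y) / sum(w * x1^2), 0)
    }
    A[A < 0] <- 0
  }
  list(A = A, clipped = clipped)
}

#' Biexponential tail fit with both lifetimes fixed
#'
#' Fits `A1 * exp(-t/tau_noFRET) + A2 * exp(-t/tau_FRET)` to the histogram
#' tail with both lifetimes fixed, which reduces to a weighted linear
#' least-squares problem in the two amplitudes (Poisson weights
#' `1/max(count, 1)`). Photon fractions are `p_i = A_i tau_i / sum_j A_j
#' tau_j`; the molecule fraction of the no-FRET species corrects for the fact
#' that FRET also reduces the donor photon yield:
#' `f_raw = (p1/tau1) / (p1/tau1 + p2/tau2)`, which equals the amplitude
#' ratio `A1 / (A1 + A2)` exactly.
#'
#' @param hist a [decay_histogram()].
#' @param tau_noFRET lifetime of the open (non-FRET) species, ns.
#' @param tau_FRET lifetime of the closed (FRET) species, ns; must be smaller.
#' @param tail_start tail start in ns or `"auto"`.
#' @return object of class `biexp_fit`: `tau_noFRET_ns`, `tau_FRET_ns`,
#'   amplitudes `A`, photon fraction `p_noFRET`, molecule fraction
#'   `f_raw` (no-FRET species), `rel_error` (standard error of `f_raw`),
#'   `clipped`, `converged`.
#' @export
fit_biexponential_fixed <- function(hist, tau_noFRET, tau_FRET,
                                    tail_start = "auto") {
  assert_that(inherits(hist, "decay_histogram"), "`hist` must be a decay_histogram")
  assert_positive(tau_noFRET, "tau_noFRET")
  assert_positive(tau_FRET, "tau_FRET")
  assert_that(tau_FRET < tau_noFRET, "tau_FRET must be smaller than tau_noFRET")
  t0 <- resolve_tail_start(hist, tail_start)
  sel <- hist$bin_centers_ns >= t0
  assert_that(sum(sel) >= 10L, "need >= 10 bins after tail_start")
  t <- hist$bin_centers_ns[sel]
  y <- hist$counts[sel]
  w <- 1 / pmax(y, 1)
  x1 <- exp(-t / tau_noFRET)
  x2 <- exp(-t / tau_FRET)
  sol <- solve_two_amplitudes(y, x1, x2, w)
  ## reweight once with model-predicted variances (see tail fit)
  if (all(is.finite(sol$A))) {
    w <- 1 / pmax(sol$A[1] * x1 + sol$A[2] * x2, 1)
    sol <- solve_two_amplitudes(y, x1, x2, w)
  }
  A <- sol$A
  converged <- all(is.finite(A)) && sum(A) > 0
  if (sol$clipped && converged) {
    warning("negative amplitude clipped at 0 in fixed-lifetime biexponential fit")
  }
  if (!converged) {
    return(structure(list(tau_noFRET_ns = tau_noFRET, tau_FRET_ns = tau_FRET,
                          A = A, p_noFRET = NA_real_, f_raw = NA_real_,
                          rel_error = NA_real_, clipped = sol$clipped,
                          converged = FALSE),
                     class = "biexp_fit"))
  }
  ph <- A * c(tau_noFRET, tau_FRET)
  p_noFRET <- ph[1] / sum(ph)
  f_raw <- A[1] / sum(A)

  ## delta-method SE of f_raw from the amplitude covariance (weighted LS)
  rel_error <- NA_real_
  if (!sol$clipped) {
    X <- cbind(x1, x2)
    M <- t(X * w) %*% X
    resid <- y - X %*% A
    dof <- max(length(y) - 2L, 1L)
    s2 <- sum(w * resid^2) / dof
    V <- tryCatch(solve(M) * s2, error = function(e) NULL)
    if (!is.null(V)) {
      S <- sum(A)
      grad <- c(A[2], -A[1]) / S^2
      var_f <- as.numeric(t(grad) %*% V %*% grad)
      if (var_f >= 0 && f_raw > 0) rel_error <- sqrt(var_f) / f_raw
    }
  }
  structure(list(tau_noFRET_ns = tau_noFRET, tau_FRET_ns = tau_FRET,
                 A = A, p_noFRET = p_noFRET, f_raw = f_raw,
                 rel_error = rel_error, clipped = sol$clipped,
                 converged = TRUE),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> f_raw(noFRET) = %.4g, p(noFRET) = %.4g (tau %.3g / %.3g ns)\n",
              x$f_raw, x$p_noFRET, x$tau_noFRET_ns, x$tau_FRET_ns))
  invisible(x)
}

#' Calibrate the two reference lifetimes of the tension-sensor analysis
#'
#' `tau_noFRET` (open sensor, approximately the donor-only lifetime) is the
#' median of monoexponential tail fits on donor-only histograms.
#' `tau_FRET` (closed sensor) is the median of biexponential fits on
#' zero-force-control histograms with `tau_noFRET` held fixed: the control
#' contains both fully fluorescent sensor (FRET) and sensor with a
#' non-fluorescent acceptor (no FRET), so its decay constrains the FRET
#' lifetime.
#'
#' @param donor_only_hists list of [decay_histogram()] from donor-only
#'   samples.
#' @param control_hists list of [decay_histogram()] from the zero-force
#'   control construct.
#' @param tail_start tail start (ns or `"auto"`).
#' @param min_fret_photon_fraction controls with a fitted FRET photon share
#'   below this are considered unidentifiable and dropped (default 1e-3).
#' @return list with `tau_noFRET_ns`, `tau_FRET_ns`, and the per-histogram
#'   fits (`donor_fits`, `control_fits`).
#' @export
calibrate_reference_lifetimes <- function(donor_only_hists, control_hists,
                                          tail_start = "auto",
                                          min_fret_photon_fraction = 1e-3) {
  assert_that(length(donor_only_hists) >= 1L && length(control_hists) >= 1L,
              "both histogram lists must be non-empty")
  donor_fits <- lapply(donor_only_hists, fit_monoexponential_tail,
                       tail_start = tail_start)
  taus <- vapply(donor_fits, function(f) if (isTRUE(f$converged)) f$tau_ns else NA_real_,
                 numeric(1))
  assert_that(any(is.finite(taus)), "all donor-only lifetime fits failed")
  tau_noFRET <- stats::median(taus, na.rm = TRUE)

  fit_one_control <- function(hist) {
    t0 <- resolve_tail_start(hist, tail_start)
    sel <- hist$bin_centers_ns >= t0
    t <- hist$bin_centers_ns[sel]
    y <- hist$counts[sel]
    w <- 1 / pmax(y, 1)
    df <- data.frame(t = t, y = y)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ A1 * exp(-t / tau_noFRET) + A2 * exp(-t / tauF),
        data = df, weights = w,
        start = list(A1 = max(y) / 2, A2 = max(y) / 2, tauF = tau_noFRET / 2),
        lower = c(0, 0, 0.05), upper = c(Inf, Inf, 0.95 * tau_noFRET),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  control_fits <- lapply(control_hists, fit_one_control)
  tauF <- vapply(control_fits, function(f) {
    if (is.null(f)) return(NA_real_)
    cf <- stats::coef(f)
    ## FRET photon share; near-zero means the FRET lifetime is unidentifiable
    ph <- c(cf[["A1"]] * tau_noFRET, cf[["A2"]] * cf[["tauF"]])
    if (ph[2] / sum(ph) < min_fret_photon_fraction) return(NA_real_)
    cf[["tauF"]]
  }, numeric(1))
  assert_that(any(is.finite(tauF)),
              "tau_FRET unidentifiable: no control histogram shows a FRET component")
  list(tau_noFRET_ns = tau_noFRET,
       tau_FRET_ns = stats::median(tauF, na.rm = TRUE),
       donor_fits = donor_fits, control_fits = control_fits)
}

#' Mechanically engaged sensor fraction from raw open fractions
#'
#' The zero-force control's apparent open fraction measures the fraction `d`
#' of sensors with a non-fluorescent (dark) acceptor; a true engaged fraction
#' `f` among sensors with a fluorescent acceptor then produces an apparent
#' open fraction `f_raw_TS = d + (1 - d) * f` in the tension-sensor sample.
#' Inverting, the default normalization is
#' `f_engaged = (f_raw_TS - f_raw_C) / (1 - f_raw_C)`. A plain ratio
#' normalization (`f_raw_TS / f_raw_C`, reported shifted so that
#' TS = control gives 0) is available for comparison.
#'
#' @param biexp_TS `biexp_fit` of the tension-sensor sample (or a numeric
#'   raw fraction).
#' @param biexp_control `biexp_fit` of the zero-force control (or a numeric
#'   raw fraction).
#' @param method `"subtract_rescale"` (default) or `"divide"`.
#' @return object of class `engaged_fraction_result`: `f_engaged`,
#'   `f_raw_TS`, `f_raw_control`, `method`.
#' @export
engaged_fraction <- function(biexp_TS, biexp_control,
                             method = c("subtract_rescale", "divide")) {
  method <- match.arg(method)
  get_f <- function(x, nm) {
    if (inherits(x, "biexp_fit")) {
      assert_that(isTRUE(x$converged), sprintf("%s fit did not converge", nm))
      x$f_raw
    } else {
      assert_that(is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1,
                  sprintf("%s must be a biexp_fit or a fraction in [0,1]", nm))
      x
    }
  }
  f_ts <- get_f(biexp_TS, "TS")
  f_c <- get_f(biexp_control, "control")
  assert_that(f_c < 1, "control raw fraction of 1 leaves the engaged fraction undefined")
  f_eng <- switch(method,
                  subtract_rescale = (f_ts - f_c) / (1 - f_c),
                  divide = f_ts / f_c - 1)
  if (f_eng < 0) {
    warning("negative engaged fraction (TS below control); interpret as 0 within noise")
  }
  structure(list(f_engaged = f_eng, f_raw_TS = f_ts, f_raw_control = f_c,
                 method = method),
            class = "engaged_fraction_result")
}

#' @export
print.engaged_fraction_result <- function(x, ...) {
  cat(sprintf("<engaged_fraction> N_open/N_total = %.4g (raw TS %.4g, control %.4g)\n",
              x$f_engaged, x$f_raw_TS, x$f_raw_control))
  invisible(x)
}

#' Intermolecular FRET offset between genotypes
#'
#' Difference of median FRET efficiencies between a heterozygous sample
#' (donor and acceptor on different molecules possible) and its homozygous
#' baseline; values near zero indicate negligible intermolecular FRET.
#'
#' @param het_E FRET efficiencies of the heterozygous condition.
#' @param homo_E_baseline matched homozygous baseline efficiencies.
#' @return median(het) - median(baseline).
#' @export
intermolecular_fret_control <- function(het_E, homo_E_baseline) {
  assert_that(length(het_E) >= 1L && length(homo_E_baseline) >= 1L,
              "both efficiency lists must be non-empty")
  stats::median(as.numeric(het_E)) - stats::median(as.numeric(homo_E_baseline))
}
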