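#' Simulate a FRAP experiment (bleached region + control region)
#'
#' The bleached-region intensity recovers as
#' `post + (pre - post) * M * (1 - exp(-k t))` from the first post-bleach
#' frame; both the bleach and the control trace are multiplied by a shared
#' acquisition-photobleaching drift `exp(-drift * t_acq)` and carry
#' multiplicative Gaussian noise. Times are reported with 0 at the first
#' post-bleach frame; pre-bleach frames have negative times.
#'
#' @param mobile_fraction mobile fraction M in [0, 1].
#' @param k recovery rate in 1/s (half time = ln 2 / k).
#' @param pre_bleach mean intensity before the bleach (counts).
#' @param post_bleach intensity immediately after the bleach (< pre_bleach).
#' @param duration_s length of the post-bleach recording, s.
#' @param dt_s frame interval, s (default 5).
#' @param drift shared photobleaching drift, fraction per second (default 0).
#' @param noise_sd relative noise per frame (default 0).
#' @param n_pre number of pre-bleach frames (default 5).
#' @param seed integer seed.
#' @return object of class `frap_curve`: list with `times_s` (0 = first
#'   post-bleach frame), `bleach_trace`, `control_trace`, `pre_bleach_mean`,
#'   `n_pre` and ground `truth`.
#' @export
gen_frap_series <- function(mobile_fraction, k, pre_bleach, post_bleach,
                            duration_s, dt_s = 5, drift = 0, noise_sd = 0,
                            n_pre = 5L, seed = NULL) {
  assert_that(mobile_fraction >= 0 && mobile_fraction <= 1,
              "mobile_fraction must lie in [0, 1]")
  assert_positive(k, "k")
  assert_positive(pre_bleach, "pre_bleach")
  assert_nonneg(post_bleach, "post_bleach")
  assert_that(post_bleach < pre_bleach, "post_bleach must be below pre_bleach")
  assert_positive(duration_s, "duration_s")
  assert_positive(dt_s, "dt_s")
  assert_nonneg(drift, "drift")
  assert_that(n_pre >= 1L, "at least one pre-bleach frame required")

  t_post <- seq(0, duration_s, by = dt_s)
  t_pre <- -rev(seq_len(n_pre)) * dt_s
  times <- c(t_pre, t_post)

  recovery <- post_bleach + (pre_bleach - post_bleach) * mobile_fraction *
    (1 - exp(-k * t_post))
  bleach <- c(rep(pre_bleach, n_pre), recovery)
  control <- rep(pre_bleach, length(times))

  ## acquisition-time drift shared by both regions (starts at first frame)
  t_acq <- times - times[1]
  fade <- exp(-drift * t_acq)
  bleach <- bleach * fade
  control <- control * fade

  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * length(times), sd = noise_sd))
    bleach <- bleach * (1 + noise[seq_along(times)])
    control <- control * (1 + noise[length(times) + seq_along(times)])
  }

  structure(list(times_s = times, bleach_trace = bleach,
                 control_trace = control,
                 pre_bleach_mean = pre_bleach, n_pre = as.integer(n_pre),
                 truth = list(mobile_fraction = mobile_fraction, k = k,
                              half_time_s = log(2) / k, drift = drift,
                              noise_sd = noise_sd, seed = seed)),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("<frap_curve> %d frames (%d pre-bleach), dt = %.3g s\n",
              length(x$times_s), x$n_pre, diff(x$times_s[1:2])))
  invisible(x)
}

#' Simulate a kymograph with a retracting tissue edge
#'
#' Space (columns, one pixel = `px_size_um`) by time (rows, one frame =
#' `dt_s`). The tissue occupies positions left of the edge; after the cut
#' frame the edge recoils at constant velocity `v`. The edge profile is a
#' smooth sigmoid of width `edge_width` pixels; Gaussian noise is added on
#' top. True edge positions (um) per frame are attached.
#'
#' @param v recoil velocity in um/s.
#' @param dt_s frame interval in s.
#' @param px_size_um pixel size in um.
#' @param n_frames number of frames (rows).
#' @param width_px number of spatial pixels (columns, default 128).
#' @param x0_um initial edge position in um (default 25% across the field).
#' @param edge_width edge transition width in pixels (default 2).
#' @param cut_frame frame after which the edge starts moving (default 0:
#'   motion from the first frame).
#' @param hi,lo tissue and background intensity levels (default 1000, 100).
#' @param noise_sd absolute Gaussian noise SD (default 0).
#' @param seed integer seed.
#' @return object of class `kymograph`: `image` (n_frames x width_px),
#'   `dt_s`, `px_size_um`, `cut_frame`, and `truth$edge_positions_um`.
#'   If the edge leaves the field of view a warning is raised and the truth
#'   positions are truncated (NA past exit).
#' @export
gen_kymograph <- function(v, dt_s, px_size_um, n_frames, width_px = 128L,
                          x0_um = NULL, edge_width = 2, cut_frame = 0L,
                          hi = 1000, lo = 100, noise_sd = 0, seed = NULL) {
  assert_positive(dt_s, "dt_s")
  assert_positive(px_size_um, "px_size_um")
  assert_that(n_frames >= 2L, "need at least 2 frames")
  assert_that(width_px >= 8L, "need at least 8 spatial pixels")
  field_um <- width_px * px_size_um
  if (is.null(x0_um)) x0_um <- 0.25 * field_um
  t_rel <- pmax(0, (seq_len(n_frames) - 1 - cut_frame)) * dt_s
  x_true <- x0_um + v * t_rel

  out_of_view <- x_true < 0 | x_true > field_um
  if (any(out_of_view)) {
    warning("edge leaves the field of view; truth positions truncated")
    x_true[out_of_view] <- NA_real_
  }

  x_px <- (seq_len(width_px) - 0.5) * px_size_um
  img <- matrix(lo, nrow = n_frames, ncol = width_px)
  for (f in seq_len(n_frames)) {
    xe <- x_true[f]
    if (is.na(xe)) next
    ## tissue left of the edge: smooth step from hi to lo
    img[f, ] <- lo + (hi - lo) /
      (1 + exp((x_px - xe) / (edge_width * px_size_um / 4)))
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed,
                           matrix(stats::rnorm(length(img), sd = noise_sd),
                                  nrow = n_frames))
  }
  structure(list(image = img, dt_s = dt_s, px_size_um = px_size_um,
                 cut_frame = as.integer(cut_frame),
                 truth = list(edge_positions_um = x_true, v_um_s = v,
                              x0_um = x0_um, seed = seed)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d px, dt = %.3g s, px = %.3g um\n",
              nrow(x$image), ncol(x$image), x$dt_s, x$px_size_um))
  invisible(x)
}
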