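#' Track the tissue edge in a kymograph
#'
#' For each time row, the edge is located at the maximum-magnitude intensity
#' gradient along the spatial axis, refined to subpixel precision by a
#' parabolic fit through the gradient peak and its two neighbours. Rows whose
#' strongest gradient does not stand out from the noise floor mark a lost
#' edge; the track is truncated there with a warning.
#'
#' @param kymo a [gen_kymograph()] result, or a list with `image`
#'   (frames x pixels), `dt_s`, `px_size_um`.
#' @param cut_index index of the last frame before the cut (defaults to the
#'   generator's `cut_frame + 1` when available, else 1). Must not exceed the
#'   number of frames.
#' @param noise_factor a row is dropped if its peak gradient magnitude is
#'   below `noise_factor` times the row's median absolute gradient
#'   (default 8).
#' @return object of class `recoil_track`: `times_s`, `positions_um`,
#'   `cut_index`, `dt_s`.
#' @export
track_kymograph <- function(kymo, cut_index = NULL, noise_factor = 8) {
  assert_that(all(c("image", "dt_s", "px_size_um") %in% names(kymo)),
              "`kymo` lacks image / dt_s / px_size_um")
  img <- kymo$image
  n_frames <- nrow(img)
  if (is.null(cut_index)) {
    cut_index <- if (!is.null(kymo$cut_frame)) kymo$cut_frame + 1L else 1L
  }
  assert_that(cut_index >= 1L && cut_index <= n_frames,
              "cut_index beyond kymograph length")

  pos <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    g <- -diff(img[f, ])          # positive at a bright-to-dim edge
    i <- which.max(abs(g))
    floor_g <- stats::median(abs(g))
    if (abs(g[i]) <= noise_factor * max(floor_g, .Machine$double.eps)) {
      warning(sprintf("edge lost at frame %d; track truncated", f))
      break
    }
    delta <- 0
    if (i > 1L && i < length(g)) {
      denom <- g[i - 1L] - 2 * g[i] + g[i + 1L]
      if (abs(denom) > .Machine$double.eps) {
        delta <- 0.5 * (g[i - 1L] - g[i + 1L]) / denom
        delta <- max(min(delta, 0.5), -0.5)
      }
    }
    ## gradient sample i sits between pixel centers i and i+1, i.e. at i*px
    pos[f] <- (i + delta) * kymo$px_size_um
  }
  valid <- which(!is.na(pos))
  assert_that(length(valid) >= 2L, "fewer than 2 tracked frames")
  keep <- seq_len(max(valid))
  structure(list(times_s = (keep - 1) * kymo$dt_s,
                 positions_um = pos[keep],
                 cut_index = as.integer(cut_index),
                 dt_s = kymo$dt_s),
            class = "recoil_track")
}

#' @export
print.recoil_track <- function(x, ...) {
  cat(sprintf("<recoil_track> %d frames, cut after frame %d, dt = %.3g s\n",
              length(x$positions_um), x$cut_index, x$dt_s))
  invisible(x)
}

#' Recoil velocity after laser ablation
#'
#' Two conventions, matching the two acquisition modes:
#' * `single_plane` — the initial recoil velocity over one frame interval
#'   shortly after the cut. With `baseline = "post"` (default) it is the
#'   displacement between the first and second post-cut frames divided by
#'   the frame interval; `baseline = "pre"` instead uses the last pre-cut to
#'   first post-cut displacement.
#' * `z_stack` — the average velocity over the first stack interval: the
#'   displacement between the last pre-cut position and the first post-cut
#'   frame divided by the stack acquisition time (e.g. 5.3 s).
#'
#' @param track a `recoil_track`.
#' @param mode `"single_plane"` or `"z_stack"`.
#' @param baseline `"post"` or `"pre"` (single-plane mode only).
#' @return velocity in um/s.
#' @export
recoil_velocity <- function(track, mode = c("single_plane", "z_stack"),
                            baseline = c("post", "pre")) {
  assert_that(inherits(track, "recoil_track"), "`track` must be a recoil_track")
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  x <- track$positions_um
  t <- track$times_s
  ci <- track$cut_index
  n <- length(x)
  if (mode == "single_plane" && baseline == "post") {
    assert_that(n >= ci + 2L, "need two post-cut frames")
    (x[ci + 2L] - x[ci + 1L]) / (t[ci + 2L] - t[ci + 1L])
  } else {
    ## pre-baseline initial velocity and z-stack average share the same form:
    ## displacement from the last pre-cut to the first post-cut frame
    assert_that(n >= ci + 1L && ci >= 1L, "track must cover the cut")
    (x[ci + 1L] - x[ci]) / (t[ci + 1L] - t[ci])
  }
}
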