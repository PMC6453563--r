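#' Multi-level Otsu thresholds
#'
#' Exhaustive search for the `n_classes - 1` thresholds maximizing the
#' between-class variance of the intensity histogram (the multi-class
#' generalization of Otsu's method). Implemented for 3 classes, the case used
#' to separate attachment sites (bright), muscle interior (mid) and background.
#'
#' @param x numeric vector (or matrix) of intensities.
#' @param n_classes number of classes (only 3 supported).
#' @param n_bins histogram resolution (default 128).
#' @return numeric vector of 2 thresholds (lower, upper) on the intensity
#'   scale; pixels `> upper` form the brightest class.
#' @export
multi_otsu_thresholds <- function(x, n_classes = 3L, n_bins = 128L) {
  assert_that(n_classes == 3L, "only 3-class thresholding is implemented")
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  assert_that(diff(rng) > 0, "degenerate thresholds: intensities are constant")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  ## cumulative moments for O(1) class statistics
  P <- cumsum(p)
  M <- cumsum(p * mids)
  class_var <- function(i, j) {
    ## classes: bins [1..i], (i..j], (j..n]
    w1 <- P[i]; w2 <- P[j] - P[i]; w3 <- 1 - P[j]
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(-Inf)
    m1 <- M[i] / w1
    m2 <- (M[j] - M[i]) / w2
    m3 <- (M[n_bins] - M[j]) / w3
    mt <- M[n_bins]
    w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
  }
  best <- c(-Inf, NA_integer_, NA_integer_)
  for (i in 1:(n_bins - 2L)) {
    for (j in (i + 1L):(n_bins - 1L)) {
      v <- class_var(i, j)
      if (v > best[1]) best <- c(v, i, j)
    }
  }
  assert_that(is.finite(best[1]),
              "degenerate thresholds: fewer than 3 occupied intensity levels")
  c(breaks[best[2] + 1L], breaks[best[3] + 1L])
}

## even-odd point-in-polygon test; polygon as matrix with columns x (col) and
## y (row) in pixel coordinates, pixel centers at integers
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## rasterize an ROI (logical matrix, polygon, or NULL = whole image)
roi_to_matrix <- function(roi, dims) {
  if (is.null(roi)) return(matrix(TRUE, dims[1], dims[2]))
  if (is.logical(roi) && is.matrix(roi)) {
    assert_that(all(dim(roi) == dims), "ROI mask dimensions must match image")
    return(roi)
  }
  roi <- as.matrix(roi)
  assert_that(ncol(roi) == 2L && nrow(roi) >= 3L,
              "polygon ROI needs >= 3 vertices with columns (row, col)")
  grid <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  inside <- point_in_polygon(grid$col, grid$row, roi[, 2], roi[, 1])
  matrix(inside, nrow = dims[1], ncol = dims[2])
}

#' Segment the bright attachment-site class inside an ROI
#'
#' Reproduces the masking procedure of the FLIM-FRET analysis: the image is
#' median-filtered (3 x 3), three-class multi-level Otsu thresholding is
#' computed on the filtered intensities inside the ROI only, the mask is the
#' brightest class, and holes fully enclosed by the mask are filled.
#'
#' @param image a [count_image()] or a numeric matrix.
#' @param roi region of interest: `NULL` (whole image), a logical matrix of
#'   image dimensions, or an n x 2 matrix of polygon vertices as
#'   `(row, col)` pixel coordinates.
#' @return object of class `region_mask`: list with `mask` (logical matrix),
#'   `roi` (logical matrix), `thresholds` and `n_pixels`.
#' @export
build_mask <- function(image, roi = NULL) {
  counts <- if (inherits(image, "count_image")) image$counts else image
  assert_that(is.matrix(counts), "`image` must be a count_image or matrix")
  roi_m <- roi_to_matrix(roi, dim(counts))
  assert_that(any(roi_m), "ROI is empty")

  ## 3x3 median filter (EBImage radius 1) on intensities scaled to [0,1]
  mx <- max(counts)
  assert_that(mx > min(counts), "degenerate thresholds: constant image")
  filtered <- EBImage::medianFilter(counts / mx, size = 1L) * mx

  thr <- multi_otsu_thresholds(filtered[roi_m], n_classes = 3L)
  mask <- filtered > thr[2] & roi_m

  ## fill holes enclosed in the brightest class
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- (as.matrix(filled) > 0) & roi_m

  structure(list(mask = mask, roi = roi_m, thresholds = thr,
                 n_pixels = sum(mask)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d / %d px selected (thresholds %.4g, %.4g)\n",
              x$n_pixels, length(x$mask), x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Apply a region mask to an image
#'
#' Zeroes pixels outside the mask. Idempotent: applying the same mask twice
#' equals applying it once.
#'
#' @param image a [count_image()] or numeric matrix.
#' @param mask a `region_mask` or logical matrix.
#' @return object of the same kind as `image`.
#' @export
apply_mask <- function(image, mask) {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  if (inherits(image, "count_image")) {
    image$counts <- image$counts * m
    image
  } else {
    image * m
  }
}
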