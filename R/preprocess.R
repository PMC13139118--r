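#' Maximum intensity projection of a z-stack
#'
#' Collapses a multi-layer stack to a single 2D frame by taking the
#' per-pixel maximum across layers, the standard reduction for thin tissue
#' imaged with few z-layers.
#'
#' @param stack A list of 2D numeric matrices (layers), all the same shape.
#'
#' @return A single matrix of the common layer shape.
#' @examples
#' max_intensity_project(list(matrix(1, 2, 2), matrix(2, 2, 2)))
#' @export
max_intensity_project <- function(stack) {
  if (length(stack) == 0L) stop("empty stack", call. = FALSE)
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("stack layers have mismatched shapes", call. = FALSE)
  }
  Reduce(pmax, stack)
}

#' Percentile linear contrast stretch
#'
#' Linearly rescales intensities so that the `low_pct` percentile maps to 0
#' and the `high_pct` percentile to 1, clipping values outside. The
#' transform is monotone non-decreasing. A degenerate frame (both
#' percentiles equal) is returned as a constant zero frame with a warning.
#'
#' @param frame 2D numeric matrix.
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#'   Defaults 1 and 99.8 clip hot pixels without flattening the signal.
#'
#' @return Matrix with values in `[0, 1]`.
#' @export
enhance_contrast <- function(frame, low_pct = 1, high_pct = 99.8) {
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  q <- stats::quantile(frame, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("degenerate frame: contrast percentiles coincide; returning constant frame")
    return(matrix(0, nrow(frame), ncol(frame)))
  }
  out <- (frame - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Median denoising filter
#'
#' Replaces each pixel by the median of its `(2 radius + 1)^2` neighborhood.
#' Image edges are handled by reflection (symmetric padding), so output is
#' bit-reproducible across platforms.
#'
#' @param frame 2D numeric matrix.
#' @param radius Neighborhood radius in pixels (>= 1); the default 1 gives
#'   the classic 3x3 median.
#'
#' @return Filtered matrix of the same shape.
#' @export
denoise_median <- function(frame, radius = 1L) {
  stopifnot(radius >= 1)
  radius <- as.integer(radius)
  nr <- nrow(frame)
  nc <- ncol(frame)
  p <- pad_reflect(frame, radius)
  k <- 2L * radius + 1L
  neigh <- matrix(NA_real_, nr * nc, k * k)
  s <- 0L
  for (dc in 0:(k - 1L)) {
    for (dr in 0:(k - 1L)) {
      s <- s + 1L
      neigh[, s] <- as.vector(p[dr + seq_len(nr), dc + seq_len(nc)])
    }
  }
  matrix(apply(neigh, 1L, median), nr, nc)
}

#' Gaussian smoothing filter
#'
#' Convolution with a normalized, separable Gaussian kernel truncated at
#' `ceiling(3 sigma)`; edges handled by reflection. Total intensity is
#' conserved up to boundary effects.
#'
#' @param frame 2D numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#'
#' @return Smoothed matrix of the same shape.
#' @export
smooth_gaussian <- function(frame, sigma = 1) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  nr <- nrow(frame)
  nc <- ncol(frame)
  p <- pad_reflect(frame, r)
  # separable: filter rows then columns
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(kern)) {
    tmp <- tmp + kern[i] * p[(i - 1L) + seq_len(nr), ]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(kern)) {
    out <- out + kern[i] * tmp[, (i - 1L) + seq_len(nc)]
  }
  out
}

#' Standard pre-processing chain for one frame
#'
#' Applies, in order: percentile contrast stretch, median denoising, and
#' Gaussian smoothing — the order that first highlights dim cells, then
#' suppresses the noise amplified by the stretch, then smooths the cell
#' surface for stable segmentation.
#'
#' @param frame 2D numeric matrix (optionally the output of
#'   [max_intensity_project()]).
#' @param low_pct,high_pct Contrast percentiles, see [enhance_contrast()].
#' @param median_radius Median filter radius, see [denoise_median()].
#' @param gaussian_sigma Smoothing sigma, see [smooth_gaussian()].
#'
#' @return Pre-processed matrix.
#' @export
preprocess_frame <- function(frame, low_pct = 1, high_pct = 99.8,
                             median_radius = 1L, gaussian_sigma = 1) {
  frame |>
    enhance_contrast(low_pct, high_pct) |>
    denoise_median(median_radius) |>
    smooth_gaussian(gaussian_sigma)
}
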