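# Threshold-based detectors of the central specular part.
#
# Three detectors are provided: a fixed luminance threshold, the
# specular-peak method (suppress saturation, then place the threshold at
# the valley before the brightest peak of the smoothed luminance
# histogram), and the gray-axis cone (accept pixels whose RGB value lies
# inside a cone opening around r = g = b).

#' HSV saturation channel
#'
#' `S = 0` where `max(R, G, B) = 0`, else `(max - min) / max`.
#'
#' @param img a [color_image()] or H x W x 3 array in `[0, 255]`.
#' @return Numeric H x W matrix with values in `[0, 1]`.
#' @export
saturation_channel <- function(img) {
  px <- as_image_array(img)
  mx <- pmax(ch_matrix(px, 1), ch_matrix(px, 2), ch_matrix(px, 3))
  mn <- pmin(ch_matrix(px, 1), ch_matrix(px, 2), ch_matrix(px, 3))
  s <- matrix(0, nrow(mx), ncol(mx))
  nz <- mx > 0
  s[nz] <- (mx[nz] - mn[nz]) / mx[nz]
  s
}

#' Saturation-suppressed color transform
#'
#' Multiplies every channel pixel-wise by `1 - S(x)`, pulling saturated
#' (tissue-colored) pixels toward black while leaving near-gray glare
#' untouched. This widens the gap between glare and bright tissue in the
#' luminance histogram.
#'
#' @inheritParams saturation_channel
#' @return Real-valued H x W x 3 array in `[0, 255]`.
#' @export
suppress_saturation <- function(img) {
  px <- as_image_array(img)
  w <- 1 - saturation_channel(px)
  px * as.vector(w) # recycles across the 3 channel slices
}

#' BT.601 luminance
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, the classic YUV luma.
#'
#' @inheritParams saturation_channel
#' @return Numeric H x W matrix in `[0, 255]`.
#' @export
luminance <- function(img) {
  px <- as_image_array(img)
  0.299 * ch_matrix(px, 1) + 0.587 * ch_matrix(px, 2) +
    0.114 * ch_matrix(px, 3)
}

#' 256-bin intensity histogram
#'
#' Values are rounded to the nearest integer bin; the counts sum to the
#' pixel count.
#'
#' @param gray numeric matrix with values in `[0, 255]`.
#' @return Numeric vector of length 256 (bins 0..255).
#' @export
compute_histogram <- function(gray) {
  v <- round(as.vector(gray))
  stopifnot(min(v) >= 0, max(v) <= 255)
  tabulate(v + 1L, nbins = 256L)
}

#' Smooth a histogram with a Gaussian kernel
#'
#' Discrete convolution with a unit-sum Gaussian truncated at
#' `ceiling(3 * sigma)` bins, mirror-reflected at the ends so total mass is
#' preserved.
#'
#' @param h numeric vector of length 256.
#' @param sigma kernel standard deviation in bins, `> 0`.
#' @return Smoothed histogram, length 256.
#' @export
smooth_histogram <- function(h, sigma) {
  stopifnot(length(h) == 256L, sigma > 0)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- numeric(256L)
  for (j in seq_along(k)) {
    idx <- reflect_index(seq_len(256L) + (j - r - 1L), 256L)
    out <- out + k[j] * h[idx]
  }
  out
}

#' Select the specular-peak threshold from a smoothed histogram
#'
#' Builds the descent indicator `h1(t) = 1` iff `h(t) - h(t+1) > 0` and
#' returns the largest `t` where a descent run ends (`h1(t) = 1`,
#' `h1(t+1) = 0`) — the valley after the brightest peak — subject to two
#' robustness rules: candidates must have positive histogram mass above
#' them (otherwise the final descent of the histogram, which encloses no
#' pixels, would always win), and the result must be strictly greater than
#' `t_min`. Returns `NA` when no admissible valley exists, signalling that
#' no specular reflections are present.
#'
#' @param h_smooth smoothed histogram, length 256.
#' @param params a [peak_params()] record.
#' @return Integer threshold in `[0, 253]`, or `NA_integer_`.
#' @export
select_specular_peak_threshold <- function(h_smooth, params = peak_params()) {
  stopifnot(length(h_smooth) == 256L, inherits(params, "peak_params"))
  h <- h_smooth
  # descent indicator over t = 0..254 (1-based index t + 1)
  h1 <- as.integer(h[1:255] - h[2:256] > 0)
  mass_above <- rev(cumsum(rev(h)))[-1] # mass in bins strictly above t, t = 0..254
  cand <- which(h1[1:254] == 1L & h1[2:255] == 0L & mass_above[1:254] > 0) - 1L
  cand <- cand[cand > params$t_min]
  if (length(cand) == 0L) return(NA_integer_)
  max(cand)
}

#' Specular-peak segmentation
#'
#' Full pipeline: saturation suppression, luminance, histogram, Gaussian
#' smoothing, valley selection, then the strict comparison
#' `Y_t(x) > t_spec`. An absent threshold yields an empty mask.
#'
#' @inheritParams saturation_channel
#' @param params a [peak_params()] record.
#' @return Logical H x W mask with the selected threshold attached as
#'   attribute `t_spec` (`NA` if none).
#' @export
specular_peak_segment <- function(img, params = peak_params()) {
  gray_t <- luminance(suppress_saturation(img))
  h <- smooth_histogram(compute_histogram(gray_t), params$sigma)
  t_spec <- select_specular_peak_threshold(h, params)
  mask <- if (is.na(t_spec)) {
    matrix(FALSE, nrow(gray_t), ncol(gray_t))
  } else {
    gray_t > t_spec
  }
  attr(mask, "t_spec") <- t_spec
  mask
}

#' Gray-axis cone segmentation
#'
#' A pixel `I(x)` belongs to the specular set iff its Euclidean distance to
#' the gray axis is strictly less than `a * (p(x) - x0)`, where `p(x)` is
#' the projection of `I(x)` onto the axis direction `(1, 1, 1) / sqrt(3)`.
#' Pixels with `p(x) <= x0` can never be members. Assumes a reasonable
#' white balance (the axis is the locus of neutral colors).
#'
#' @inheritParams saturation_channel
#' @param params a [cone_params()] record.
#' @return Logical H x W mask.
#' @export
cone_segment <- function(img, params = cone_params()) {
  stopifnot(inherits(params, "cone_params"))
  px <- as_image_array(img)
  r <- ch_matrix(px, 1); g <- ch_matrix(px, 2); b <- ch_matrix(px, 3)
  s <- r + g + b
  proj <- s / sqrt(3) # <n, I> / |n|
  m <- s / 3         # coordinates of the projected point on the axis
  d2 <- (r - m)^2 + (g - m)^2 + (b - m)^2
  sqrt(d2) < params$a * (proj - params$x0)
}

#' Fixed gray-level segmentation
#'
#' The classical baseline: threshold the BT.601 luminance at a fixed value.
#'
#' @inheritParams saturation_channel
#' @param params a [gray_params()] record.
#' @return Logical H x W mask.
#' @export
gray_level_segment <- function(img, params = gray_params()) {
  stopifnot(inherits(params, "gray_params"))
  luminance(img) > params$t_gray
}
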