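# Shared pixel-grid conventions
#
# A color image is a numeric H x W x 3 array with channel values in
# [0, 255]; a gray image is a numeric H x W matrix (real-valued after
# transforms); a binary mask is a logical H x W matrix on the same grid.
# Pixels are indexed (row, col) with row 1 at the top, R's native matrix
# convention.

#' Construct and validate a color image
#'
#' @param pixels numeric H x W x 3 array with values in `[0, 255]`.
#' @return The validated array with class `color_image`.
#' @examples
#' img <- color_image(array(128, dim = c(4, 4, 3)))
#' dim(img)
#' @export
color_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array, got ",
         paste(dim(pixels), collapse = " x "), call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have H >= 1 and W >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255] and contain no NA",
         call. = FALSE)
  }
  structure(pixels, class = c("color_image", class(pixels)))
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image> %d x %d pixels, 3 channels, range [%.1f, %.1f]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

# internal: accept a color_image or raw array, return plain array
as_image_array <- function(img) {
  if (inherits(img, "color_image")) return(unclass(img))
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) return(img)
  stop("expected a color image (H x W x 3 array)", call. = FALSE)
}

# internal: validate a binary mask against an optional reference grid
as_mask <- function(mask, reference = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("expected a logical H x W matrix mask", call. = FALSE)
  }
  if (!is.null(reference)) {
    rd <- if (is.matrix(reference)) dim(reference) else dim(reference)[1:2]
    if (!identical(dim(mask), rd)) {
      stop(sprintf("mask dimensions %d x %d do not match reference %d x %d",
                   nrow(mask), ncol(mask), rd[1], rd[2]), call. = FALSE)
    }
  }
  mask
}

#' Separable Gaussian smoothing of a matrix
#'
#' Convolves with a unit-sum 1-D Gaussian kernel truncated at
#' `ceiling(3 * sigma)` taps on each side, applied along rows then columns,
#' with mirror-reflected boundaries.
#'
#' @param m numeric matrix.
#' @param sigma kernel standard deviation in pixels; `sigma <= 0` returns
#'   `m` unchanged.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  m <- conv_along(m, k, margin = 1L)
  conv_along(m, k, margin = 2L)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect index i (possibly outside 1..n) back into range, mirroring at the
# boundary without duplicating the edge sample; falls back to clamping for
# kernels wider than the image
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i <- ifelse(i >= n, period - i, i)
  i + 1L
}

conv_along <- function(m, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(m)[margin]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    out <- out + k[j] * (if (margin == 1L) m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

# internal: channel slice as a matrix even for 1-pixel-high/wide images
ch_matrix <- function(px, k) {
  matrix(px[, , k], dim(px)[1], dim(px)[2])
}

# internal: logical mask from an n x 2 (row, col) coordinate matrix
mask_from_pixels <- function(pixels, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[pixels] <- TRUE
  m
}

# internal: n x 2 (row, col) coordinates of TRUE pixels (column-major order)
pixels_from_mask <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  dimnames(px) <- list(NULL, c("row", "col"))
  px
}
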