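# Parameter records for the detectors. Each constructor validates its
# arguments and returns a lightweight classed list; defaults are starting
# points for grid optimization, not values claimed to be optimal for any
# particular camera.

#' Parameters for specular-peak threshold selection
#'
#' @param t_min lowest admissible threshold; thresholds must be strictly
#'   greater, which guards against selecting a tissue valley when no
#'   specular reflections are present. Integer in `[0, 254]`.
#' @param sigma standard deviation (in histogram bins) of the Gaussian
#'   kernel used to merge neighbouring specular peaks before the valley
#'   scan.
#' @return A `peak_params` list.
#' @export
peak_params <- function(t_min = 100, sigma = 2) {
  stopifnot(t_min >= 0, t_min < 255, sigma > 0)
  structure(list(t_min = as.integer(t_min), sigma = sigma),
            class = "peak_params")
}

#' Parameters of the gray-axis cone detector
#'
#' The detector accepts a pixel when its Euclidean distance to the gray
#' axis (r = g = b) is less than `a * (p - x0)`, where `p` is the pixel's
#' projection onto the axis. `x0` is therefore expressed on the axial
#' projection scale: a gray level `v` projects to `v * sqrt(3)`.
#'
#' @param x0 cone tip position along the gray axis (axial projection
#'   units), `>= 0`.
#' @param a cone slope, dimensionless, `> 0`.
#' @return A `cone_params` list.
#' @export
cone_params <- function(x0 = 100 * sqrt(3), a = 0.3) {
  stopifnot(x0 >= 0)
  if (a <= 0) stop("cone slope `a` must be > 0", call. = FALSE)
  structure(list(x0 = x0, a = a), class = "cone_params")
}

#' Parameters for fixed gray-level thresholding
#'
#' @param t_gray luminance threshold in `[0, 255]`.
#' @return A `gray_params` list.
#' @export
gray_params <- function(t_gray = 230) {
  stopifnot(t_gray >= 0, t_gray <= 255)
  structure(list(t_gray = t_gray), class = "gray_params")
}

#' Parameters for specular-lobe region growing
#'
#' @param c scaling factor applied to each core component's mean luminance
#'   to obtain its growth threshold; in `(0, 1.5]`. Values above 1 permit
#'   no growth on clipped cores.
#' @return A `lobe_params` list.
#' @export
lobe_params <- function(c = 0.7) {
  stopifnot(c > 0, c <= 1.5)
  structure(list(c = c), class = "lobe_params")
}

#' Parameters of the edge-map stage of the hybrid detector
#'
#' Hysteresis thresholds are absolute gradient magnitudes on the 8-bit
#' luminance scale (intensity units per pixel, Sobel normalized so a unit
#' ramp has gradient 1). Absolute thresholds keep the operating point
#' independent of the brightest edge that happens to be present in an
#' image.
#'
#' @param canny_low,canny_high hysteresis thresholds, `0 <= low < high`.
#' @param canny_sigma Gaussian pre-smoothing scale of the edge detector.
#' @param closing_radius radius (pixels, `>= 1`) of the disk structuring
#'   element used to close small contour gaps.
#' @return A `contour_params` list.
#' @export
contour_params <- function(canny_low = 3, canny_high = 6, canny_sigma = 1,
                           closing_radius = 1) {
  if (canny_low < 0 || canny_low >= canny_high) {
    stop("need 0 <= canny_low < canny_high", call. = FALSE)
  }
  stopifnot(canny_sigma > 0, closing_radius >= 1)
  structure(list(canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma,
                 closing_radius = as.integer(closing_radius)),
            class = "contour_params")
}

#' Constraints identifying weak (Type 3) reflections among closed contours
#'
#' A candidate enclosed component is kept only if all four strict
#' inequalities hold: mean interior luminance above `t_av`; drop from
#' interior to the one-pixel ring beyond the contour above `t_diff`;
#' component size strictly between `t_cc_min` and `t_cc_max` pixels.
#'
#' @param t_av minimum mean interior luminance, `[0, 255]`.
#' @param t_diff minimum interior-to-surround luminance drop, `> 0`.
#' @param t_cc_min,t_cc_max size band in pixels, `t_cc_min < t_cc_max`.
#' @return A `type3_constraints` list.
#' @export
type3_constraints <- function(t_av = 140, t_diff = 30, t_cc_min = 5,
                              t_cc_max = 2000) {
  stopifnot(t_av >= 0, t_av <= 255, t_diff > 0, t_cc_min > 0,
            t_cc_min < t_cc_max)
  structure(list(t_av = t_av, t_diff = t_diff,
                 t_cc_min = as.integer(t_cc_min),
                 t_cc_max = as.integer(t_cc_max)),
            class = "type3_constraints")
}

#' Full default parameter set for every detector
#'
#' @return Named list with elements `gray`, `peak`, `cone`, `lobe`,
#'   `contour`, `type3`.
#' @export
default_params <- function() {
  list(gray = gray_params(), peak = peak_params(), cone = cone_params(),
       lobe = lobe_params(), contour = contour_params(),
       type3 = type3_constraints())
}
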