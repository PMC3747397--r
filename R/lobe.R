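# Specular lobe segmentation: each thresholded core component is grown
# outward into the surrounding bright halo with a per-component adaptive
# threshold, c times the component's mean luminance.

#' Connected components of a binary mask
#'
#' Maximal 8-connected components (diagonal contact joins), labelled in
#' raster-scan order of each component's first pixel, so the labelling is
#' deterministic.
#'
#' @param mask logical H x W matrix.
#' @param gray optional luminance matrix; when supplied, each component's
#'   `mean_intensity` is filled in.
#' @param connectivity 8 (default) or 4.
#' @return A tibble with one row per component: `label`, `size`, `pixels`
#'   (list of n x 2 (row, col) matrices), and `mean_intensity` when `gray`
#'   is given.
#' @export
connected_components <- function(mask, gray = NULL, connectivity = 8) {
  mask <- as_mask(mask)
  stopifnot(connectivity %in% c(4, 8))
  lab <- cpp_label_components(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(label = integer(), size = integer(),
                          pixels = list(),
                          mean_intensity = if (is.null(gray)) NULL
                                           else numeric()))
  }
  idx <- which(lab > 0)
  ord <- order(lab[idx])
  idx <- idx[ord]
  px <- arrayInd(idx, dim(lab))
  dimnames(px) <- list(NULL, c("row", "col"))
  splits <- split(seq_along(idx), lab[idx])
  out <- tibble::tibble(
    label = as.integer(names(splits)),
    size = unname(lengths(splits)),
    pixels = unname(purrr::map(splits, ~ px[.x, , drop = FALSE]))
  )
  if (!is.null(gray)) {
    out$mean_intensity <- purrr::map_dbl(out$pixels, ~ mean(gray[.x]))
  }
  out
}

#' Mean luminance over one component
#'
#' @param comp one component: a one-row slice of the tibble from
#'   [connected_components()], or any list with a `pixels` element.
#' @param gray luminance matrix covering the component.
#' @return Arithmetic mean of `gray` over the component's pixels.
#' @export
component_mean <- function(comp, gray) {
  px <- component_pixels(comp)
  if (any(px[, 1] < 1 | px[, 1] > nrow(gray) |
          px[, 2] < 1 | px[, 2] > ncol(gray))) {
    stop("component coordinates fall outside the image", call. = FALSE)
  }
  mean(gray[px])
}

# internal: extract the n x 2 pixel matrix from a component row/list
component_pixels <- function(comp) {
  if (is.matrix(comp)) return(comp)
  px <- comp$pixels
  if (is.list(px)) px <- px[[1]]
  stopifnot(is.matrix(px), ncol(px) == 2)
  px
}

#' Grow the specular lobe around one core component
#'
#' Region growing from the component: any pixel 8-connected to the seed
#' through accepted pixels is added when its luminance strictly exceeds
#' `c * mean_intensity` of the seed. Seed pixels are always retained (the
#' final segmentation is a union with the core), so the result is a single
#' connected region containing the seed.
#'
#' @param comp component to grow (see [component_mean()]).
#' @param gray raw-image luminance matrix (growth uses the untransformed
#'   luminance).
#' @param params a [lobe_params()] record.
#' @return Logical mask of the grown lobe.
#' @export
grow_lobe <- function(comp, gray, params = lobe_params()) {
  stopifnot(inherits(params, "lobe_params"))
  px <- component_pixels(comp)
  mu <- component_mean(px, gray)
  seed <- mask_from_pixels(px, dim(gray))
  cpp_region_grow(gray, seed, params$c * mu)
}

#' Threshold core plus grown lobes
#'
#' Applies [grow_lobe()] to every 8-connected component of the core mask
#' and returns the union of the core with all lobes. Overlapping lobes
#' simply merge.
#'
#' @param img source color image (supplies the luminance channel).
#' @param core_mask binary mask from any thresholding detector.
#' @param params a [lobe_params()] record.
#' @return Logical mask, always a superset of `core_mask`.
#' @export
segment_with_lobes <- function(img, core_mask, params = lobe_params()) {
  gray <- luminance(img)
  core_mask <- as_mask(core_mask, gray)
  comps <- connected_components(core_mask)
  out <- core_mask
  for (i in seq_len(nrow(comps))) {
    out <- out | grow_lobe(comps$pixels[[i]], gray, params)
  }
  out
}
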