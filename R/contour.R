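# Hybrid closed-contour segmentation.
#
# Three process lines run on each image and are combined: (1) cone
# thresholding finds the bright specular cores; (2) a Canny edge map,
# closed morphologically, yields candidate contours, and regions of the
# complement not reachable from the image border are "enclosed"
# components; (3) enclosed components are classified. An enclosed
# component containing at least one thresholded pixel is a Type 2
# reflection and is segmented by its contour. Thresholded components with
# no closed contour are Type 1 (large glare with a slow radial decay) and
# are expanded by lobe growing. Remaining enclosed components that pass
# four constraints on interior brightness, edge drop, and size are the
# weak Type 3 reflections that no single threshold can recover.

#' Canny edge detection on the luminance channel
#'
#' Gaussian smoothing, Sobel gradients (normalized to intensity units per
#' pixel), 4-sector non-maximum suppression, and hysteresis linking. Image
#' border pixels carry no edges.
#'
#' @param img a [color_image()] or H x W x 3 array.
#' @param params a [contour_params()] record; `canny_low`/`canny_high` are
#'   absolute gradient magnitudes.
#' @return Logical H x W edge map.
#' @export
detect_edges <- function(img, params = contour_params()) {
  stopifnot(inherits(params, "contour_params"))
  gray <- gaussian_blur(luminance(img), params$canny_sigma)
  H <- nrow(gray); W <- ncol(gray)
  if (H < 3 || W < 3) return(matrix(FALSE, H, W))
  # Sobel, /8 so a unit ramp has gradient magnitude 1
  p <- function(dr, dc) gray[(2:(H - 1)) + dr, (2:(W - 1)) + dc]
  gx <- (p(-1, 1) + 2 * p(0, 1) + p(1, 1) -
         p(-1, -1) - 2 * p(0, -1) - p(1, -1)) / 8
  gy <- (p(1, -1) + 2 * p(1, 0) + p(1, 1) -
         p(-1, -1) - 2 * p(-1, 0) - p(-1, 1)) / 8
  mag <- matrix(0, H, W)
  mag[2:(H - 1), 2:(W - 1)] <- sqrt(gx^2 + gy^2)
  ang <- matrix(0, H, W)
  ang[2:(H - 1), 2:(W - 1)] <- atan2(gy, gx)
  # quantize direction to 4 sectors: 0 = E/W, 1 = NE/SW, 2 = N/S, 3 = NW/SE
  sector <- floor(((ang / pi * 180 + 180) %% 180 + 22.5) / 45) %% 4
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  keep <- matrix(FALSE, H, W)
  for (s in 0:3) {
    d <- off[[s + 1]]
    n1 <- shift(mag, d[1], d[2])    # neighbour in +direction
    n2 <- shift(mag, -d[1], -d[2])  # neighbour in -direction
    keep <- keep | (sector == s & mag >= n1 & mag > n2)
  }
  ridge <- keep & mag > 0
  strong <- ridge & mag > params$canny_high
  weak <- ridge & mag > params$canny_low
  cpp_hysteresis(strong, weak)
}

# disk structuring element offsets for a given radius; the +1 slack keeps
# the rasterized disk 8-connected (radius 1 is the full 3x3 square, so a
# radius-1 closing bridges 1-pixel contour gaps)
disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 + 1, ]
  list(dr = as.integer(g$dr), dc = as.integer(g$dc))
}

#' Morphological closing of an edge map
#'
#' Dilation then erosion with a disk structuring element; bridges contour
#' gaps narrower than roughly twice the radius. Closing is extensive: the
#' output is a superset of the input.
#'
#' @param edges logical edge map.
#' @param closing_radius disk radius in pixels, `>= 1`.
#' @return Logical edge map with small gaps closed.
#' @export
close_gaps <- function(edges, closing_radius = 1) {
  stopifnot(closing_radius >= 1)
  se <- disk_offsets(closing_radius)
  dil <- cpp_morph(as_mask(edges), se$dr, se$dc, FALSE)
  # erosion ignoring out-of-bounds would eat the border; pad by reflection
  # is overkill here — treat out-of-bounds as background but re-add the
  # original edges so closing stays extensive
  ero <- cpp_morph(dil, se$dr, se$dc, TRUE)
  ero | edges
}

#' Components enclosed by contours
#'
#' Flood-fills the complement of the edge set from every border pixel
#' (4-connectivity, the duality partner of 8-connected edge curves). Every
#' non-edge region the outside cannot reach is one enclosed component;
#' regions touching the border are never enclosed.
#'
#' @param edges logical (closed) edge map.
#' @param gray optional luminance matrix to fill in component means.
#' @return Component tibble as in [connected_components()].
#' @export
enclosed_components <- function(edges, gray = NULL) {
  edges <- as_mask(edges)
  outside <- cpp_flood_outside(edges)
  interior <- !edges & !outside
  connected_components(interior, gray, connectivity = 4)
}

#' One-pixel surround ring of an enclosed component
#'
#' The set of pixels outside the component and outside the edge set that
#' are 8-adjacent to the component or to edge pixels touching it — the
#' ring just beyond the contour, where tissue intensity is measured.
#' Clipped at image borders.
#'
#' @param comp component (see [component_mean()]).
#' @param edges logical edge map on the same grid.
#' @return n x 2 (row, col) coordinate matrix (possibly 0 rows).
#' @export
component_perimeter_ring <- function(comp, edges) {
  edges <- as_mask(edges)
  px <- component_pixels(comp)
  comp_mask <- mask_from_pixels(px, dim(edges))
  se <- disk_offsets(1.5) # the 8-neighbourhood
  rim <- cpp_morph(comp_mask, se$dr, se$dc, FALSE) & edges
  grown <- cpp_morph(comp_mask | rim, se$dr, se$dc, FALSE)
  ring <- grown & !comp_mask & !edges
  pixels_from_mask(ring)
}

#' Filter enclosed components down to Type 3 reflections
#'
#' Keeps candidates satisfying all four strict constraints: mean interior
#' luminance `> t_av`; interior minus surround-ring mean `> t_diff`; size
#' `> t_cc_min` and `< t_cc_max`. Candidates with an empty surround ring
#' are excluded (the drop constraint cannot be evaluated) with a warning.
#'
#' @param candidates component tibble (enclosed components not already
#'   classified as Type 2).
#' @param gray luminance matrix.
#' @param edges logical (closed) edge map.
#' @param constraints a [type3_constraints()] record.
#' @return The accepted subset of `candidates`, with columns
#'   `mean_intensity`, `ring_mean`, `size` filled in.
#' @export
classify_type3 <- function(candidates, gray, edges,
                           constraints = type3_constraints()) {
  stopifnot(inherits(constraints, "type3_constraints"))
  if (nrow(candidates) == 0L) return(candidates)
  stats <- purrr::map(candidates$pixels, function(px) {
    ring <- component_perimeter_ring(px, edges)
    list(mean = mean(gray[px]),
         ring_mean = if (nrow(ring) == 0L) NA_real_ else mean(gray[ring]))
  })
  candidates$mean_intensity <- purrr::map_dbl(stats, "mean")
  candidates$ring_mean <- purrr::map_dbl(stats, "ring_mean")
  no_ring <- is.na(candidates$ring_mean)
  if (any(no_ring)) {
    warning(sum(no_ring), " candidate component(s) had an empty surround",
            " ring and were excluded", call. = FALSE)
  }
  dplyr::filter(
    candidates,
    !is.na(.data$ring_mean),
    .data$mean_intensity > constraints$t_av,
    .data$mean_intensity - .data$ring_mean > constraints$t_diff,
    .data$size > constraints$t_cc_min,
    .data$size < constraints$t_cc_max
  )
}

#' Hybrid closed-contour segmentation
#'
#' Runs the full pipeline (cone thresholding, Canny + closing, enclosed
#' components, Type 1/2/3 classification) and returns per-type masks plus
#' their union. Contour-based masks (Types 2 and 3) consist of the
#' enclosed interior plus the edge pixels touching it — the glare rim is
#' part of the glare; Type 1 masks are lobe-grown from the thresholded
#' cores.
#'
#' @param img a [color_image()] or H x W x 3 array.
#' @param cone a [cone_params()] record.
#' @param lobe a [lobe_params()] record.
#' @param contour a [contour_params()] record.
#' @param constraints a [type3_constraints()] record.
#' @return A `specseg_segmentation` object: list with masks `type1`,
#'   `type2`, `type3`, `union`, the edge map, a `components_by_type`
#'   tibble, and `params_used`.
#' @export
hybrid_segment <- function(img, cone = cone_params(), lobe = lobe_params(),
                           contour = contour_params(),
                           constraints = type3_constraints()) {
  gray <- luminance(img)
  dims <- dim(gray)
  core <- cone_segment(img, cone)
  edges <- close_gaps(detect_edges(img, contour), contour$closing_radius)
  enc <- enclosed_components(edges, gray)
  enc_mask <- matrix(FALSE, dims[1], dims[2])
  for (px in enc$pixels) enc_mask[px] <- TRUE

  # enclosed components containing >= 1 thresholded pixel are Type 2
  is_type2 <- purrr::map_lgl(enc$pixels, ~ any(core[.x]))
  type2 <- matrix(FALSE, dims[1], dims[2])
  if (any(is_type2)) {
    for (px in enc$pixels[is_type2]) {
      type2 <- type2 | contour_region_mask(px, edges, dims)
    }
  }

  # thresholded components with no closed contour are Type 1, lobe-grown
  cores <- connected_components(core, gray)
  core_enclosed <- purrr::map_lgl(cores$pixels, ~ any(enc_mask[.x]))
  type1 <- matrix(FALSE, dims[1], dims[2])
  for (px in cores$pixels[!core_enclosed]) {
    type1 <- type1 | grow_lobe(px, gray, lobe)
  }

  # remaining enclosed components: Type 3 candidates
  cand <- enc[!is_type2, , drop = FALSE]
  kept <- suppressWarnings(classify_type3(cand, gray, edges, constraints))
  type3 <- matrix(FALSE, dims[1], dims[2])
  for (px in kept$pixels) {
    type3 <- type3 | contour_region_mask(px, edges, dims)
  }

  comps <- dplyr::bind_rows(
    if (nrow(cores) > 0)
      dplyr::mutate(cores[!core_enclosed, ], type = 1L),
    if (nrow(enc) > 0)
      dplyr::mutate(enc[is_type2, intersect(names(enc),
                                            c("label", "size", "pixels",
                                              "mean_intensity"))],
                    type = 2L),
    if (nrow(kept) > 0)
      dplyr::mutate(kept[, intersect(names(kept),
                                     c("label", "size", "pixels",
                                       "mean_intensity"))],
                    type = 3L)
  )
  structure(
    list(type1 = type1, type2 = type2, type3 = type3,
         union = type1 | type2 | type3, edges = edges,
         components_by_type = comps,
         params_used = list(cone = cone, lobe = lobe, contour = contour,
                            type3 = constraints)),
    class = "specseg_segmentation"
  )
}

# interior plus the edge pixels 8-adjacent to it (the contour belongs to
# the reflection it encloses)
contour_region_mask <- function(px, edges, dims) {
  comp_mask <- mask_from_pixels(px, dims)
  se <- disk_offsets(1.5)
  rim <- cpp_morph(comp_mask, se$dr, se$dc, FALSE) & edges
  comp_mask | rim
}

#' @export
print.specseg_segmentation <- function(x, ...) {
  n <- if (is.null(x$components_by_type)) integer(3) else
    vapply(1:3, function(t) sum(x$components_by_type$type == t), 1L)
  cat(sprintf(paste0("<specseg_segmentation> %d x %d | components: ",
                     "%d Type 1, %d Type 2, %d Type 3 | union area %d px\n"),
              nrow(x$union), ncol(x$union), n[1], n[2], n[3], sum(x$union)))
  invisible(x)
}
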