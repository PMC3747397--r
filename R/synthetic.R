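# Synthetic laparoscopic scenes with ground-truth reflections.
#
# The generator emulates the three glare phenotypes seen on liver-like
# tissue: Type 1 — large reflections with a clipped center and a slow,
# radially decreasing intensity (rendered as an angularly modulated
# Gaussian profile, so parts of the rim have a gradient too shallow for
# edge detection, as real large glare does); Type 2 — small bright disks
# with a step-shaped border; Type 3 — small disks whose luminance lifts
# only modestly above the local tissue and overlaps the background's
# upper range, so no single global threshold can capture them without
# flooding bright tissue. Type 3 color is local tissue plus a neutral
# (gray) offset, placing it in RGB space exactly where wet bright tissue
# sits — the color-space overlap that limits thresholding detectors.

#' Specification of one synthetic scene
#'
#' @param width,height image size in pixels.
#' @param n_type1,n_type2,n_type3 reflection counts per type.
#' @param background_level mean tissue luminance in `[0, 255]`.
#' @param background_smoothness spatial correlation length of the tissue
#'   field, pixels.
#' @param noise_sd additive per-channel Gaussian noise, intensity units.
#' @param type1_radius_range Gaussian scale range (pixels) of Type 1
#'   profiles; the ground-truth footprint extends to roughly twice this.
#' @param type23_radius_range disk radius range (pixels) for Types 2/3.
#' @param type2_intensity peak luminance range of Type 2 disks.
#' @param type3_intensity allowed luminance band of Type 3 disks; must lie
#'   entirely below `type2_intensity`.
#' @param type1_mask_frac fraction of a Type 1 profile's amplitude at
#'   which its ground-truth footprint is cut (a Gaussian tail has no
#'   natural boundary).
#' @param seed integer seed; scenes are bit-identical given the same spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 128, height = 128,
                       n_type1 = 2, n_type2 = 3, n_type3 = 4,
                       background_level = 81, background_smoothness = 12,
                       noise_sd = 2,
                       type1_radius_range = c(5, 7),
                       type23_radius_range = c(2.5, 4.5),
                       type2_intensity = c(235, 255),
                       type3_intensity = c(85, 112),
                       type1_mask_frac = 0.1,
                       seed = 1L) {
  stopifnot(width >= 32, height >= 32,
            n_type1 >= 0, n_type2 >= 0, n_type3 >= 0,
            background_level > 0, background_level < 255,
            background_smoothness > 0, noise_sd >= 0,
            length(type1_radius_range) == 2, length(type23_radius_range) == 2,
            type1_mask_frac > 0, type1_mask_frac < 1)
  if (max(type3_intensity) >= min(type2_intensity)) {
    stop("type3_intensity must lie entirely below type2_intensity",
         call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_type1 = as.integer(n_type1), n_type2 = as.integer(n_type2),
                 n_type3 = as.integer(n_type3),
                 background_level = background_level,
                 background_smoothness = background_smoothness,
                 noise_sd = noise_sd,
                 type1_radius_range = type1_radius_range,
                 type23_radius_range = type23_radius_range,
                 type2_intensity = type2_intensity,
                 type3_intensity = type3_intensity,
                 type1_mask_frac = type1_mask_frac,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run code under a local RNG stream; the caller's random state is untouched
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic scene
#'
#' Deterministic given `spec$seed`. Ground-truth masks: Type 1 footprints
#' are the pixels where the added profile exceeds `type1_mask_frac` of its
#' amplitude; Types 2/3 footprints are the generating disks. Reflections
#' are placed mutually disjoint and away from the image border; if a
#' reflection cannot be placed after bounded retries, a placement error is
#' raised.
#'
#' @param spec a [scene_spec()].
#' @return A `specseg_scene`: list with `image` ([color_image()]),
#'   `labels` (tibble `id`, `type`, `mask`), and `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    f <- gaussian_blur(matrix(stats::rnorm(H * W), H, W),
                       spec$background_smoothness / 2)
    # rank transform: smooth level sets, stable site availability per seed
    f <- matrix((rank(f, ties.method = "average") - 0.5) / (H * W), H, W)
    sheen <- 45 * f^2
    offset <- spec$background_level - 81 # nominal mean luminance is 81
    bg <- array(0, dim = c(H, W, 3))
    bg[, , 1] <- 90 + 45 * f + sheen + offset
    bg[, , 2] <- 40 + 25 * f + sheen + offset
    bg[, , 3] <- 35 + 20 * f + sheen + offset

    img <- bg
    occupied <- matrix(FALSE, H, W)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    labels <- list()
    place <- function(footprint_r, site_ok) {
      for (try in seq_len(500L)) {
        cy <- sample.int(H, 1); cx <- sample.int(W, 1)
        if (cy - footprint_r < 4 || cy + footprint_r > H - 3 ||
            cx - footprint_r < 4 || cx + footprint_r > W - 3) next
        if (!site_ok(cy, cx)) next
        r2 <- (rows - cy)^2 + (cols - cx)^2
        if (any(occupied[r2 <= (footprint_r + 4)^2])) next
        return(list(cy = cy, cx = cx, r2 = r2))
      }
      stop("could not place a reflection without overlap after 500 tries; ",
           "reduce counts or radii, or enlarge the scene", call. = FALSE)
    }
    lum_at <- function(cy, cx) {
      0.299 * img[cy, cx, 1] + 0.587 * img[cy, cx, 2] + 0.114 * img[cy, cx, 3]
    }

    # Type 1: large, clipped center, slow angularly-modulated radial decay
    for (i in seq_len(spec$n_type1)) {
      s <- runif1(spec$type1_radius_range)
      foot <- 2.2 * s
      at <- place(foot, function(cy, cx) f[cy, cx] >= 0.6)
      # amplitude clips all three channels at the center: clipped glare
      # centers are pure white, not just red-saturated
      amp <- 1.05 * (255 - min(img[at$cy, at$cx, ]))
      r <- sqrt(at$r2)
      theta <- atan2(rows - at$cy, cols - at$cx)
      phase <- stats::runif(1, 0, 2 * pi)
      modfac <- 1 - 0.8 * pmin(1, r / s) * (1 + sin(3 * theta + phase)) / 2
      prof <- amp * exp(-at$r2 / (2 * s^2)) * modfac
      for (ch in 1:3) img[, , ch] <- img[, , ch] + prof
      mask <- prof >= spec$type1_mask_frac * amp
      occupied <- occupied | (r <= foot)
      labels[[length(labels) + 1L]] <- list(type = 1L, mask = mask)
    }

    # Type 2: small bright near-white disks, step-shaped border
    for (i in seq_len(spec$n_type2)) {
      rad <- runif1(spec$type23_radius_range)
      at <- place(rad + 1, function(cy, cx) TRUE)
      v <- runif1(spec$type2_intensity)
      cov <- pmin(1, pmax(0, rad + 0.5 - sqrt(at$r2))) # <= 1 px anti-alias
      white <- c(1, 0.98, 0.96) * v
      for (ch in 1:3) {
        img[, , ch] <- (1 - cov) * img[, , ch] + cov * white[ch]
      }
      mask <- at$r2 <= rad^2
      occupied <- occupied | (at$r2 <= (rad + 1)^2)
      labels[[length(labels) + 1L]] <- list(type = 2L, mask = mask)
    }

    # Type 3: small weak disks — local tissue plus a neutral lift chosen so
    # the disk sits at the same gray-axis distance-to-projection ratio as
    # bright wet tissue (ratio ~0.29-0.31), overlapping it in color space
    for (i in seq_len(spec$n_type3)) {
      rad <- runif1(spec$type23_radius_range)
      ok <- FALSE
      for (attempt in seq_len(50L)) {
        at <- place(rad + 1, function(cy, cx) f[cy, cx] <= 0.35)
        base <- img[at$cy, at$cx, ]
        m <- mean(base)
        d <- sqrt(sum((base - m)^2))       # distance to the gray axis
        p <- sum(base) / sqrt(3)           # axial projection
        rho <- stats::runif(1, 0.29, 0.31)
        lift <- (d / rho - p) / sqrt(3)
        y_local <- lum_at(at$cy, at$cx)
        lift <- min(lift, spec$type3_intensity[2] - y_local)
        lift <- max(lift, spec$type3_intensity[1] - y_local)
        if (lift >= 12 && y_local + lift <= spec$type3_intensity[2] + 1e-9) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not find a Type 3 site within the intensity band",
             call. = FALSE)
      }
      cov <- pmin(1, pmax(0, rad + 0.5 - sqrt(at$r2)))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + cov * lift
      mask <- at$r2 <= rad^2
      occupied <- occupied | (at$r2 <= (rad + 1)^2)
      labels[[length(labels) + 1L]] <- list(type = 3L, mask = mask)
    }

    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                         dim = dim(img))
    }
    img <- round(pmin(pmax(img, 0), 255))

    ord <- order(purrr::map_int(labels, "type"))
    labels <- labels[ord]
    lab_tbl <- tibble::tibble(
      id = seq_along(labels),
      type = purrr::map_int(labels, "type"),
      mask = purrr::map(labels, "mask")
    )
    structure(list(image = color_image(img), labels = lab_tbl, spec = spec),
              class = "specseg_scene")
  })
}

#' @export
print.specseg_scene <- function(x, ...) {
  cat(sprintf("<specseg_scene> %d x %d, %d reflections (%d/%d/%d of Types 1/2/3), seed %d\n",
              x$spec$height, x$spec$width, nrow(x$labels),
              sum(x$labels$type == 1), sum(x$labels$type == 2),
              sum(x$labels$type == 3), x$spec$seed))
  invisible(x)
}

#' Generate a corpus of synthetic scenes
#'
#' Per-scene seeds are drawn from one corpus-level stream, so the whole
#' corpus is reproducible from `seed` alone.
#'
#' @param spec_template a [scene_spec()]; its `seed` field is overridden
#'   per scene.
#' @param n_images number of scenes, `>= 1`.
#' @param seed corpus seed.
#' @return List with `scenes` (list of `specseg_scene`) and `manifest`
#'   (tibble: `image`, `seed`, per-type counts, `total`).
#' @export
generate_corpus <- function(spec_template = scene_spec(), n_images = 20,
                            seed = 1L) {
  stopifnot(n_images >= 1)
  seeds <- with_local_seed(seed,
                           sample.int(.Machine$integer.max, n_images))
  scenes <- purrr::map(seeds, function(s) {
    sp <- spec_template
    sp$seed <- s
    generate_scene(sp)
  })
  manifest <- tibble::tibble(
    image = sprintf("scene_%03d", seq_len(n_images)),
    seed = seeds,
    n_type1 = purrr::map_int(scenes, ~ sum(.x$labels$type == 1L)),
    n_type2 = purrr::map_int(scenes, ~ sum(.x$labels$type == 2L)),
    n_type3 = purrr::map_int(scenes, ~ sum(.x$labels$type == 3L))
  )
  manifest$total <- manifest$n_type1 + manifest$n_type2 + manifest$n_type3
  list(scenes = scenes, manifest = manifest)
}

#' Write a scene (image, union mask, label sidecar) to a directory
#'
#' @param scene a `specseg_scene`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return Named vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  mask_path <- file.path(dir, paste0(stem, "_mask.png"))
  lab_path <- file.path(dir, paste0(stem, "_labels.json"))
  write_image(scene$image, img_path)
  truth <- Reduce(`|`, scene$labels$mask,
                  matrix(FALSE, nrow(scene$image), ncol(scene$image)))
  write_mask(truth, mask_path)
  write_labels(scene$labels, lab_path)
  invisible(c(image = img_path, mask = mask_path, labels = lab_path))
}
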