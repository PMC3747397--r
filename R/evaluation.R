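# Scoring segmentations against ground truth: pixel-level Jaccard index,
# object-level sensitivity by reflection type and positive predictive
# value, corpus summaries, and exhaustive grid-search parameter
# optimization.

#' Jaccard index of two masks
#'
#' `tp / (tp + fp + fn)` over pixels. True negatives are ignored, which
#' matters here: glare usually covers a tiny fraction of a laparoscopic
#' frame, so specificity would look good even for grossly oversized
#' segmentations. Two empty masks score 1 (perfect agreement).
#'
#' @param pred,truth logical matrices of identical dimensions.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) {
  pred <- as_mask(pred)
  truth <- as_mask(truth, pred)
  tp <- sum(pred & truth)
  denom <- tp + sum(pred & !truth) + sum(!pred & truth)
  if (denom == 0) return(1)
  tp / denom
}

#' Match predicted components against ground-truth reflections
#'
#' A ground-truth reflection counts as detected when its mask shares at
#' least one pixel with the prediction; a predicted connected component
#' sharing no pixel with any ground-truth mask is one false positive.
#'
#' @param pred logical prediction mask.
#' @param truth_labels label tibble (`id`, `type`, `mask`) as produced by
#'   [generate_scene()] or [read_labels()].
#' @return A `reflection_confusion` object: list with counts `tp`, `fp`
#'   and a `per_type` tibble (`type`, `detected`, `total`).
#' @export
match_reflections <- function(pred, truth_labels) {
  pred <- as_mask(pred)
  types <- truth_labels$type
  detected <- purrr::map_lgl(truth_labels$mask,
                             ~ any(pred & as_mask(.x, pred)))
  truth_union <- Reduce(`|`, truth_labels$mask,
                        matrix(FALSE, nrow(pred), ncol(pred)))
  comps <- connected_components(pred)
  stray <- purrr::map_lgl(comps$pixels, ~ !any(truth_union[.x]))
  per_type <- tibble::tibble(type = 1:3) |>
    dplyr::mutate(
      detected = purrr::map_int(.data$type, ~ sum(detected[types == .x])),
      total = purrr::map_int(.data$type, ~ sum(types == .x))
    )
  structure(list(tp = sum(detected), fp = sum(stray), per_type = per_type),
            class = "reflection_confusion")
}

# pool several reflection_confusion objects
pool_confusions <- function(confs) {
  per_type <- purrr::map(confs, "per_type") |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(detected = sum(.data$detected),
                     total = sum(.data$total), .groups = "drop")
  structure(list(tp = sum(purrr::map_int(confs, "tp")),
                 fp = sum(purrr::map_int(confs, "fp")),
                 per_type = per_type),
            class = "reflection_confusion")
}

#' Positive predictive value over detected reflections
#'
#' `tp / (tp + fp)` at the object level; `NA` when nothing was predicted
#' at all (reported as "n/a" in written reports).
#'
#' @param conf a `reflection_confusion` from [match_reflections()].
#' @return A number in `[0, 1]`, or `NA_real_`.
#' @export
ppv <- function(conf) {
  if (conf$tp + conf$fp == 0) return(NA_real_)
  conf$tp / (conf$tp + conf$fp)
}

#' Summarize per-image Jaccard scores and pooled reflection counts
#'
#' Quartiles use linear interpolation (R's default type-7 quantiles).
#' The average sensitivity is the unweighted mean over the three reflection
#' types (matching the per-type-then-average layout of the comparison
#' table); a reflection-count-weighted sensitivity is also reported for
#' transparency.
#'
#' @param per_image_jaccard numeric vector, one Jaccard value per image.
#' @param conf pooled `reflection_confusion` over the same images.
#' @return One-row tibble: `f_jaccard`, `q1`, `q3`, `sens_t1`..`sens_t3`,
#'   `sens_avg`, `sens_weighted`, `ppv`.
#' @export
summarize_evaluation <- function(per_image_jaccard, conf) {
  if (length(per_image_jaccard) == 0L) {
    stop("need at least one Jaccard value", call. = FALSE)
  }
  q <- stats::quantile(per_image_jaccard, c(0.25, 0.75), names = FALSE,
                       type = 7)
  pt <- conf$per_type
  sens <- ifelse(pt$total > 0, pt$detected / pt$total, NA_real_)
  tibble::tibble(
    f_jaccard = mean(per_image_jaccard),
    q1 = q[1], q3 = q[2],
    sens_t1 = sens[pt$type == 1], sens_t2 = sens[pt$type == 2],
    sens_t3 = sens[pt$type == 3],
    sens_avg = mean(sens, na.rm = TRUE),
    sens_weighted = if (sum(pt$total) > 0) sum(pt$detected) / sum(pt$total)
                    else NA_real_,
    ppv = ppv(conf)
  )
}

#' Segment one image with a named detector
#'
#' Dispatcher used by evaluation and the command-line tool. The three
#' thresholding detectors are combined with specular-lobe growing, as in
#' the comparison protocol; `"hybrid"` runs [hybrid_segment()] and returns
#' its union mask.
#'
#' @param img a [color_image()] or H x W x 3 array.
#' @param method one of `"gray"`, `"peak"`, `"cone"`, `"hybrid"`.
#' @param params full parameter list as from [default_params()].
#' @return Logical union mask; for `"hybrid"`, the full
#'   `specseg_segmentation` is attached as attribute `"result"`.
#' @export
segment_image <- function(img, method = c("gray", "peak", "cone", "hybrid"),
                          params = default_params()) {
  method <- match.arg(method)
  if (method == "hybrid") {
    res <- hybrid_segment(img, cone = params$cone, lobe = params$lobe,
                          contour = params$contour,
                          constraints = params$type3)
    mask <- res$union
    attr(mask, "result") <- res
    return(mask)
  }
  core <- switch(method,
                 gray = gray_level_segment(img, params$gray),
                 peak = specular_peak_segment(img, params$peak),
                 cone = cone_segment(img, params$cone))
  segment_with_lobes(img, core, params$lobe)
}

#' Evaluate one detector over a corpus of labelled scenes
#'
#' @param scenes list of `specseg_scene` objects (or lists with elements
#'   `image` and `labels`).
#' @param method detector id, see [segment_image()].
#' @param params full parameter list.
#' @return List: `summary` (one-row tibble), `per_image` tibble with
#'   per-scene Jaccard values, pooled `confusion`.
#' @export
evaluate_corpus <- function(scenes, method, params = default_params()) {
  res <- purrr::map(scenes, function(sc) {
    pred <- segment_image(sc$image, method, params)
    truth <- Reduce(`|`, sc$labels$mask,
                    matrix(FALSE, nrow(pred), ncol(pred)))
    list(jaccard = jaccard(pred, truth),
         conf = match_reflections(pred, sc$labels))
  })
  jac <- purrr::map_dbl(res, "jaccard")
  conf <- pool_confusions(purrr::map(res, "conf"))
  list(summary = summarize_evaluation(jac, conf),
       per_image = tibble::tibble(image = seq_along(jac), jaccard = jac),
       confusion = conf)
}

# fold a named flat parameter row (t_gray, t_min, sigma, x0, a, c,
# canny_low, canny_high, closing_radius, t_av, t_diff, t_cc_min, t_cc_max)
# into the structured parameter list
apply_param_row <- function(params, row) {
  for (nm in names(row)) {
    val <- row[[nm]]
    params <- switch(
      nm,
      t_gray = { params$gray <- gray_params(val); params },
      t_min = { params$peak <- peak_params(val, params$peak$sigma); params },
      sigma = { params$peak <- peak_params(params$peak$t_min, val); params },
      x0 = { params$cone <- cone_params(val, params$cone$a); params },
      a = { params$cone <- cone_params(params$cone$x0, val); params },
      c = { params$lobe <- lobe_params(val); params },
      canny_low = ,
      canny_high = ,
      canny_sigma = ,
      closing_radius = {
        cp <- unclass(params$contour); cp[[nm]] <- val
        params$contour <- do.call(contour_params, cp); params
      },
      t_av = ,
      t_diff = ,
      t_cc_min = ,
      t_cc_max = {
        tc <- unclass(params$type3); tc[[nm]] <- val
        params$type3 <- do.call(type3_constraints, tc); params
      },
      stop("unknown parameter name: ", nm, call. = FALSE)
    )
  }
  params
}

#' Exhaustive grid-search parameter optimization
#'
#' Evaluates the mean Jaccard index over the full Cartesian grid and
#' returns the argmax; ties are broken by the lexicographically smallest
#' parameter tuple (in the grid's column order). The full score surface is
#' returned for plotting.
#'
#' @param scenes labelled corpus, as for [evaluate_corpus()].
#' @param method detector id.
#' @param grid named list mapping flat parameter names (see
#'   [apply_param_row()] names such as `t_gray`, `c`, `x0`, `a`,
#'   `canny_high`, `t_diff`, ...) to value vectors.
#' @param params base parameter list; grid values override it point by
#'   point.
#' @return A `specseg_optimization` object: list with `best_params`
#'   (structured list), `best_row`, `best_score`, and the `surface`
#'   tibble.
#' @export
optimize_parameters <- function(scenes, method, grid,
                                params = default_params()) {
  if (length(scenes) == 0L) stop("empty corpus", call. = FALSE)
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("empty parameter grid", call. = FALSE)
  }
  surface <- do.call(expand.grid,
                     c(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE))
  scores <- vapply(seq_len(nrow(surface)), function(i) {
    p <- apply_param_row(params, as.list(surface[i, , drop = FALSE]))
    mean(purrr::map_dbl(scenes, function(sc) {
      pred <- segment_image(sc$image, method, p)
      truth <- Reduce(`|`, sc$labels$mask,
                      matrix(FALSE, nrow(pred), ncol(pred)))
      jaccard(pred, truth)
    }))
  }, numeric(1))
  surface <- tibble::as_tibble(surface)
  surface$score <- scores
  # argmax with lexicographic tie-break on the parameter columns
  best_idx <- which(scores == max(scores))
  if (length(best_idx) > 1L) {
    ord <- do.call(order, surface[best_idx, setdiff(names(surface), "score"),
                                  drop = FALSE])
    best_idx <- best_idx[ord[1]]
  }
  best_row <- as.list(surface[best_idx, setdiff(names(surface), "score"),
                              drop = FALSE])
  structure(list(method = method,
                 best_params = apply_param_row(params, best_row),
                 best_row = tibble::as_tibble(best_row),
                 best_score = scores[best_idx],
                 surface = surface),
            class = "specseg_optimization")
}

#' @export
print.specseg_optimization <- function(x, ...) {
  cat(sprintf("<specseg_optimization> method '%s', %d grid points\n",
              x$method, nrow(x$surface)))
  cat("best (mean Jaccard ", format(x$best_score, digits = 4), "): ",
      paste(names(x$best_row), unlist(x$best_row), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
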