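# broom-style accessors for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a hybrid segmentation into a component table
#'
#' @param x a `specseg_segmentation`.
#' @param ... ignored.
#' @return Tibble with one row per detected component: `type`, `label`,
#'   `size`, `mean_intensity` (and `ring_mean` for Type 3 rows).
#' @export
tidy.specseg_segmentation <- function(x, ...) {
  comps <- x$components_by_type
  if (is.null(comps) || nrow(comps) == 0) {
    return(tibble::tibble(type = integer(), label = integer(),
                          size = integer(), mean_intensity = numeric()))
  }
  dplyr::select(comps, "type", "label", "size",
                dplyr::any_of(c("mean_intensity", "ring_mean")))
}

#' One-row summary of a hybrid segmentation
#'
#' @param x a `specseg_segmentation`.
#' @param ... ignored.
#' @return Tibble: component counts and mask areas per type.
#' @export
glance.specseg_segmentation <- function(x, ...) {
  ct <- x$components_by_type
  tibble::tibble(
    n_type1 = sum(ct$type == 1), n_type2 = sum(ct$type == 2),
    n_type3 = sum(ct$type == 3),
    area_type1 = sum(x$type1), area_type2 = sum(x$type2),
    area_type3 = sum(x$type3), area_union = sum(x$union)
  )
}

#' Tidy a grid-search result into its score surface
#'
#' @param x a `specseg_optimization`.
#' @param ... ignored.
#' @return The surface tibble (parameters plus `score`).
#' @export
tidy.specseg_optimization <- function(x, ...) x$surface

#' One-row summary of a grid search
#'
#' @param x a `specseg_optimization`.
#' @param ... ignored.
#' @return Tibble: method, best score, number of grid points, best tuple.
#' @export
glance.specseg_optimization <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method, best_score = x$best_score,
                   n_grid = nrow(x$surface)),
    x$best_row
  )
}

#' Tidy a benchmark into its comparison report
#'
#' @param x a `specseg_benchmark`.
#' @param ... ignored.
#' @return The report tibble, one row per algorithm.
#' @export
tidy.specseg_benchmark <- function(x, ...) x$report

#' One-row summary of a benchmark
#'
#' @param x a `specseg_benchmark`.
#' @param ... ignored.
#' @return Tibble: corpus shape and the best algorithm by mean Jaccard.
#' @export
glance.specseg_benchmark <- function(x, ...) {
  best <- x$report[which.max(x$report$f_jaccard), ]
  tibble::tibble(n_images = nrow(x$manifest),
                 n_reflections = sum(x$manifest$total),
                 seed = x$seed,
                 best_algorithm = best$algorithm,
                 best_f_jaccard = best$f_jaccard)
}
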