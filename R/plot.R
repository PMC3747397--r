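# ggplot2 displays for scenes, segmentations, and optimization surfaces.

image_tbl <- function(px) {
  d <- dim(px)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(px[, , 1], px[, , 2], px[, , 3], maxColorValue = 255)
  )
}

#' Plot a synthetic scene with its ground-truth outlines
#'
#' @param object a `specseg_scene`.
#' @param show_truth overlay ground-truth footprints, colored by type.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.specseg_scene <- function(object, show_truth = TRUE, ...) {
  tb <- image_tbl(as_image_array(object$image))
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (show_truth && nrow(object$labels) > 0) {
    out <- purrr::pmap(object$labels, function(id, type, mask) {
      px <- pixels_from_mask(mask)
      tibble::tibble(row = px[, 1], col = px[, 2], type = factor(type, 1:3))
    }) |> dplyr::bind_rows()
    p <- p + ggplot2::geom_tile(
      data = out, ggplot2::aes(color = .data$type), fill = NA,
      linewidth = 0.1, width = 1, height = 1, alpha = 0.6) +
      ggplot2::scale_color_manual(values = c("1" = "#e41a1c",
                                             "2" = "#377eb8",
                                             "3" = "#4daf4a"),
                                  name = "Type")
  }
  p
}

#' Plot a hybrid segmentation's per-type masks
#'
#' @param object a `specseg_segmentation` from [hybrid_segment()].
#' @param ... ignored.
#' @return A ggplot object with one colored layer per reflection type.
#' @export
autoplot.specseg_segmentation <- function(object, ...) {
  layers <- purrr::map(1:3, function(t) {
    m <- object[[paste0("type", t)]]
    px <- pixels_from_mask(m)
    if (nrow(px) == 0) return(NULL)
    tibble::tibble(row = px[, 1], col = px[, 2], type = factor(t, 1:3))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(layers, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("1" = "#e41a1c", "2" = "#377eb8",
                                          "3" = "#4daf4a"),
                               name = "Type", drop = FALSE) +
    ggplot2::scale_y_reverse(limits = c(nrow(object$union) + 0.5, 0.5)) +
    ggplot2::scale_x_continuous(limits = c(0.5, ncol(object$union) + 0.5)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a grid-search score surface
#'
#' For one or two varying parameters the surface is drawn directly
#' (line/tiles); with more, each parameter is shown against the score in
#' facets.
#'
#' @param object a `specseg_optimization` from [optimize_parameters()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.specseg_optimization <- function(object, ...) {
  surf <- object$surface
  vars <- setdiff(names(surf), "score")
  varying <- vars[purrr::map_int(surf[vars], dplyr::n_distinct) > 1]
  if (length(varying) == 1) {
    return(ggplot2::ggplot(surf, ggplot2::aes(.data[[varying]],
                                              .data$score)) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::labs(y = "mean Jaccard index") +
             ggplot2::theme_minimal())
  }
  if (length(varying) == 2) {
    return(ggplot2::ggplot(surf, ggplot2::aes(.data[[varying[1]]],
                                              .data[[varying[2]]],
                                              fill = .data$score)) +
             ggplot2::geom_tile() +
             ggplot2::scale_fill_viridis_c(name = "mean Jaccard") +
             ggplot2::theme_minimal())
  }
  long <- tidyr_pivot(surf, varying)
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$score)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(y = "mean Jaccard index") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(surf, varying) {
  purrr::map(varying, function(v) {
    tibble::tibble(parameter = v, value = surf[[v]], score = surf$score)
  }) |> dplyr::bind_rows()
}
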