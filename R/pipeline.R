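# Workflow layer: default optimization grids, batch segmentation, and the
# end-to-end benchmark (simulate -> optimize per method -> evaluate at the
# optimum -> comparison report). These functions back the command-line
# script in inst/cli/specseg.R.

#' Default optimization grid for a detector
#'
#' Modest grids fixed a priori: thresholding detectors search their core
#' parameter(s) jointly with the lobe scaling factor `c`; the hybrid
#' searches the edge-map operating point and the Type 3 constraints while
#' inheriting cone and lobe parameters (pass them via `params` to
#' [optimize_parameters()], typically the cone detector's optimum).
#'
#' @param method detector id: `"gray"`, `"peak"`, `"cone"`, `"hybrid"`.
#' @return Named list of parameter value vectors.
#' @export
default_grid <- function(method = c("gray", "peak", "cone", "hybrid")) {
  method <- match.arg(method)
  switch(method,
    gray = list(t_gray = c(140, 170, 200, 230), c = c(0.5, 0.7, 0.9)),
    peak = list(t_min = c(60, 90, 120), sigma = c(1, 2, 4),
                c = c(0.5, 0.7, 0.9)),
    cone = list(x0 = c(80, 140, 200, 260, 320), a = c(0.15, 0.3, 0.5, 0.8),
                c = c(0.5, 0.7, 0.9)),
    hybrid = list(canny_high = c(5, 6.5, 8), closing_radius = c(1, 2),
                  t_diff = c(8, 15, 25), t_av = c(60, 100),
                  t_cc_min = c(3, 5))
  )
}

#' Segment a batch of images and write the masks
#'
#' One union-mask PNG is written per input image; with `per_type = TRUE`
#' the hybrid also writes the three per-type masks. A JSON log records the
#' parameters used and per-image component counts. Inputs are never
#' modified; outputs land only under `out_dir`.
#'
#' @param inputs character vector of PNG paths, or a directory (all
#'   `*.png` inside, masks excluded).
#' @param out_dir output directory.
#' @param method detector id, see [segment_image()].
#' @param params full parameter list, see [default_params()].
#' @param per_type also write `_type1/2/3` masks (hybrid only).
#' @return Tibble with one row per image (`input`, `mask`, `n_components`),
#'   invisibly.
#' @export
run_segment <- function(inputs, out_dir, method = "cone",
                        params = default_params(), per_type = FALSE) {
  if (length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list.files(inputs, pattern = "\\.png$", full.names = TRUE)
    inputs <- inputs[!grepl("_mask|_type[123]", inputs)]
  }
  if (length(inputs) == 0L) stop("no input images found", call. = FALSE)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("missing input image(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(inputs, function(path) {
    img <- read_image(path)
    seg <- segment_image(img, method, params)
    res <- attr(seg, "result")
    attributes(seg) <- attributes(seg)["dim"]
    stem <- sub("\\.png$", "", basename(path))
    mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
    write_mask(seg, mask_path)
    if (per_type && method == "hybrid") {
      for (t in 1:3) {
        write_mask(res[[paste0("type", t)]],
                   file.path(out_dir, paste0(stem, "_type", t, ".png")))
      }
    }
    tibble::tibble(input = path, mask = mask_path,
                   n_components = nrow(connected_components(seg)))
  })
  log <- list(method = method,
              params = rapply(params, unclass, how = "replace"),
              images = purrr::map(rows, as.list))
  jsonlite::write_json(log, file.path(out_dir, "segment_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dplyr::bind_rows(rows))
}

#' End-to-end benchmark on a synthetic corpus
#'
#' Reproduces the comparison protocol on generated data: simulate a
#' labelled corpus, grid-optimize each detector's parameters by mean
#' Jaccard index, evaluate every detector at its optimum, and assemble a
#' comparison table (one row per algorithm with Jaccard mean/quartiles,
#' per-type and average sensitivity, and PPV). The hybrid inherits the
#' optimized cone and lobe parameters before searching its own grid, so
#' `"cone"` is always optimized when `"hybrid"` is requested.
#'
#' Fully reproducible from `seed`.
#'
#' @param spec a [scene_spec()] template.
#' @param n_images corpus size.
#' @param seed corpus seed.
#' @param methods detectors to compare.
#' @param grids optional named list of grids overriding [default_grid()].
#' @param out_dir if non-NULL, the report is written there via
#'   [write_report()] together with the corpus manifest.
#' @return A `specseg_benchmark` object: list with `report` (tibble),
#'   `optimizations`, `evaluations`, and `manifest`.
#' @export
run_end_to_end <- function(spec = scene_spec(), n_images = 20, seed = 1L,
                           methods = c("gray", "peak", "cone", "hybrid"),
                           grids = NULL, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  corpus <- generate_corpus(spec, n_images, seed)
  need <- if ("hybrid" %in% methods) union("cone", methods) else methods
  opts <- list()
  for (m in setdiff(need, "hybrid")) {
    g <- if (!is.null(grids[[m]])) grids[[m]] else default_grid(m)
    opts[[m]] <- optimize_parameters(corpus$scenes, m, g)
  }
  if ("hybrid" %in% need) {
    g <- if (!is.null(grids[["hybrid"]])) grids[["hybrid"]]
         else default_grid("hybrid")
    opts[["hybrid"]] <- optimize_parameters(corpus$scenes, "hybrid", g,
                                            params = opts[["cone"]]$best_params)
  }
  evals <- purrr::map(opts[methods], function(o) {
    evaluate_corpus(corpus$scenes, o$method, o$best_params)
  })
  algo_names <- c(gray = "Gray-level thresholding",
                  peak = "Specular peak thresholding",
                  cone = "Cone thresholding",
                  hybrid = "Hybrid closed contour")
  report <- purrr::imap(evals, function(ev, m) {
    dplyr::bind_cols(tibble::tibble(algorithm = algo_names[[m]]),
                     ev$summary)
  }) |>
    dplyr::bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report"))
    utils::write.csv(corpus$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(report = report, optimizations = opts[methods],
                 evaluations = evals, manifest = corpus$manifest,
                 seed = seed),
            class = "specseg_benchmark")
}

#' @export
print.specseg_benchmark <- function(x, ...) {
  cat("<specseg_benchmark> seed", x$seed, "-", nrow(x$manifest),
      "scenes,", sum(x$manifest$total), "reflections\n")
  print(as.data.frame(x$report), digits = 3)
  invisible(x)
}

#' Simulate a corpus and write it to disk
#'
#' Writes one PNG image, one union ground-truth mask, and one label
#' sidecar per scene, plus `manifest.json`.
#'
#' @inheritParams run_end_to_end
#' @param out_dir output directory.
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(spec = scene_spec(), n_images = 20, seed = 1L,
                         out_dir = "scenes") {
  corpus <- generate_corpus(spec, n_images, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  purrr::walk2(corpus$scenes, corpus$manifest$image,
               ~ write_scene(.x, out_dir, .y))
  manifest <- corpus$manifest
  jsonlite::write_json(
    list(n_images = nrow(manifest), seed = seed,
         total_reflections = sum(manifest$total),
         images = purrr::transpose(as.list(manifest))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
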