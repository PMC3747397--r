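# Reading and writing images, masks, label sidecars, and metric reports.
# Images and masks travel as PNG (masks as 0/255 single-channel PNG);
# ground-truth reflection labels as a JSON sidecar; reports as CSV + JSON.

#' Read an RGB image from a PNG file
#'
#' 16-bit PNGs are rescaled linearly to `[0, 255]`; no gamma handling is
#' applied. Only 3-channel images are accepted: grayscale or alpha-carrying
#' files raise a format error naming the channel count.
#'
#' @param path path to a PNG file.
#' @return A [color_image()] with integer-valued channels in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("TIFF input is not supported in this build; convert to PNG",
         call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  px <- tryCatch(png::readPNG(path),
                 error = function(e) stop("unreadable PNG file '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  nc <- if (length(dim(px)) == 3L) dim(px)[3] else 1L
  if (nc != 3L) {
    stop(sprintf("expected a 3-channel RGB image, got %d channel(s): %s",
                 nc, path), call. = FALSE)
  }
  color_image(round(px * 255))
}

#' Write an RGB image to a PNG file
#'
#' @param img a [color_image()] or H x W x 3 array in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_image_array(img)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Pixels with value >= 128 (on the 8-bit scale) become `TRUE`, giving some
#' tolerance to masks saved through lossy editors.
#'
#' @param path path to a single-channel PNG.
#' @param reference optional image or matrix whose grid the mask must match.
#' @return A logical H x W matrix.
#' @export
read_mask <- function(path, reference = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    stop(sprintf("expected a single-channel mask, got %d channels: %s",
                 dim(px)[3], path), call. = FALSE)
  }
  as_mask(px * 255 >= 128, reference)
}

#' Write a binary mask as a 0/255 single-channel PNG
#'
#' @param mask logical H x W matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' Write ground-truth reflection labels as a JSON sidecar
#'
#' Each label (one reflection footprint plus its type tag) is serialized
#' with a run-length encoding of its mask over the column-major pixel
#' order, so the sidecar is self-contained plain text.
#'
#' @param labels a label tibble as produced by [generate_scene()]: columns
#'   `id`, `type`, `mask` (list of logical matrices).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("id", "type", "mask") %in% names(labels)))
  recs <- purrr::pmap(labels, function(id, type, mask, ...) {
    r <- rle(as.vector(mask))
    list(id = id, type = type, height = nrow(mask), width = ncol(mask),
         rle_lengths = r$lengths, rle_values = as.integer(r$values))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reflection label sidecar written by [write_labels()]
#'
#' @param path path to the `.json` sidecar.
#' @return A tibble with columns `id`, `type`, `mask`.
#' @export
read_labels <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  rows <- purrr::map(recs, function(rec) {
    v <- inverse.rle(structure(list(lengths = rec$rle_lengths,
                                    values = as.logical(rec$rle_values)),
                               class = "rle"))
    tibble::tibble(id = as.integer(rec$id), type = as.integer(rec$type),
                   mask = list(matrix(v, rec$height, rec$width)))
  })
  dplyr::bind_rows(rows)
}

report_columns <- c("algorithm", "f_jaccard", "q1", "q3",
                    "sens_t1", "sens_t2", "sens_t3", "sens_avg", "ppv")

#' Write an evaluation report as CSV and JSON
#'
#' Emits `<path>.csv` and `<path>.json` with the fixed column order
#' `algorithm, f_jaccard, q1, q3, sens_t1, sens_t2, sens_t3, sens_avg, ppv`.
#' Undefined PPV values (no detections at all) are written as `"n/a"` in the
#' CSV and `null` in the JSON.
#'
#' @param results data frame with an `algorithm` column and metric columns.
#' @param path output path without extension (or with `.csv`/`.json`, which
#'   is stripped).
#' @return Named character vector of the two files written, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  if (nrow(results) > 0 && !"algorithm" %in% names(results)) {
    stop("report rows must contain an `algorithm` column", call. = FALSE)
  }
  base <- sub("\\.(csv|json)$", "", path)
  keep <- intersect(report_columns, names(results))
  extra <- setdiff(names(results), report_columns)
  out <- results[, c(keep, extra), drop = FALSE]
  csv <- paste0(base, ".csv")
  js <- paste0(base, ".json")
  csv_out <- out
  if ("ppv" %in% names(csv_out)) {
    csv_out$ppv <- ifelse(is.na(csv_out$ppv), "n/a",
                          format(csv_out$ppv, digits = 15, trim = TRUE))
  }
  utils::write.csv(csv_out, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out, js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv, json = js))
}

#' Read a JSON report back into a tibble
#'
#' @param path path to a `.json` report written by [write_report()].
#' @return A tibble with the report rows.
#' @export
read_report <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
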