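# Reading and writing the package's on-disk formats: 8-bit grayscale images
# (PNG/TIFF), 3-class label masks (PNG with raw levels 0/1/2), probability
# maps (float multi-channel TIFF), and reports (CSV/JSON).
#
# On disk, images follow the usual raster convention; in memory everything is
# a matrix indexed [row, col].

#' Read and write grayscale images
#'
#' Images are stored as 8-bit grayscale PNG or TIFF; in memory they are
#' numeric matrices with intensities 0-255.
#'
#' @param image numeric matrix, intensities 0-255.
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_image` returns the intensity matrix.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  x <- pmin(pmax(image, 0), 255) / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else {
    png::writePNG(x, path)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 3) x <- x[, , 1]  # first channel of RGB(A)
  round(x * 255)
}

#' Read and write 3-class label masks
#'
#' Label masks use raw levels 0 = background, 1 = wall, 2 = lumen stored in
#' an 8-bit single-channel PNG (values 0, 1, 2 out of 255, as produced by
#' annotation tools that save label indices directly).
#'
#' @param labels integer matrix with values in `{0, 1, 2}`.
#' @param path PNG file path.
#' @return `read_label_mask` returns the integer label matrix.
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  lab <- round(x * 255)
  if (!all(lab %in% 0:2))
    stop("not a 3-class label mask (expected raw levels 0/1/2)", call. = FALSE)
  matrix(as.integer(lab), nrow(lab))
}

#' Read and write probability maps as multi-channel float TIFF
#'
#' @param pm a [probability_map()].
#' @param path TIFF file path.
#' @return `read_probability_map` returns a [probability_map()].
#' @export
write_probability_map <- function(pm, path) {
  stopifnot(inherits(pm, "probability_map"))
  tiff::writeTIFF(lapply(seq_len(pm$n_classes), function(k) pm$p[, , k]),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  ch <- tiff::readTIFF(path, all = TRUE)
  p <- array(unlist(ch), c(dim(ch[[1]]), length(ch)))
  probability_map(p)
}

#' Write morphometry reports to CSV and JSON
#'
#' One CSV row per vessel (see [as.data.frame.morphometry_report()] for the
#' column layout); the JSON mirrors the full report structure including QC.
#'
#' @param reports a single `morphometry_report` or a list of them.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return the combined data.frame, invisibly.
#' @export
write_morphometry_reports <- function(reports, csv_path = NULL, json_path = NULL) {
  if (inherits(reports, "morphometry_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  if (nrow(df)) df <- cbind(vessel = seq_len(nrow(df)), df)
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(reports, unclass), json_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(df)
}

#' Write phantom placement records to CSV
#'
#' @param records the `records` data.frame from [make_synthetic_wsi()].
#' @param path CSV file path.
#' @export
write_phantom_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
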