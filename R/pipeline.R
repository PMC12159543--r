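# End-to-end harness: tile a large image on a regular grid, keep tiles whose
# detection confidence clears the threshold, center them with ORCA, gate on
# the arteriolosclerosis classifier, segment wall/lumen, validate, and run
# morphometry. Every tile receives exactly one terminal disposition.

#' Pipeline configuration
#'
#' @param tile_size tile edge length in pixels.
#' @param um_per_px physical resolution.
#' @param detection_threshold minimum tile confidence score kept.
#' @param shift_threshold,max_iter ORCA parameters (see [orca_center()]).
#' @param classifier_midpoint wall/lumen ratio mapped to score 0.5 by the
#'   reference classifier.
#' @param classifier_threshold minimum classifier score kept.
#' @param dark_threshold,min_area reference segmenter parameters.
#' @param seed RNG seed recorded with the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tile_size = 512, um_per_px = 0.220,
                            detection_threshold = 0.5, shift_threshold = 8,
                            max_iter = 10, classifier_midpoint = 2,
                            classifier_threshold = 0.5,
                            dark_threshold = 150, min_area = 64, seed = 1L) {
  stopifnot(tile_size >= 32, um_per_px > 0,
            detection_threshold >= 0, detection_threshold <= 1,
            shift_threshold > 0, max_iter >= 1,
            classifier_threshold >= 0, classifier_threshold <= 1)
  structure(list(tile_size = as.integer(tile_size), um_per_px = um_per_px,
                 detection_threshold = detection_threshold,
                 shift_threshold = shift_threshold,
                 max_iter = as.integer(max_iter),
                 classifier_midpoint = classifier_midpoint,
                 classifier_threshold = classifier_threshold,
                 dark_threshold = dark_threshold, min_area = min_area,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Tile an image on a regular non-overlapping grid
#'
#' Tiles start at origin (0, 0) with stride equal to the tile size; partial
#' tiles at the right/bottom edges are dropped and counted in the attributes.
#'
#' @param source numeric matrix, at least `tile_size` in both dimensions.
#' @param tile_size tile edge length in pixels.
#' @return data.frame (the tile manifest) with columns `id`, `row`, `col`
#'   (0-based origins); attributes `dropped_rows_px` / `dropped_cols_px`
#'   give the size of the discarded edge remainders.
#' @export
tile_image <- function(source, tile_size = 512) {
  stopifnot(is.matrix(source))
  if (any(dim(source) < tile_size)) stop("source too small", call. = FALSE)
  r0 <- seq(0, nrow(source) - tile_size, by = tile_size)
  c0 <- seq(0, ncol(source) - tile_size, by = tile_size)
  manifest <- expand.grid(row = r0, col = c0)
  manifest <- manifest[order(manifest$row, manifest$col), ]
  manifest <- data.frame(id = seq_len(nrow(manifest)),
                         row = manifest$row, col = manifest$col)
  attr(manifest, "dropped_rows_px") <- nrow(source) - (max(r0) + tile_size)
  attr(manifest, "dropped_cols_px") <- ncol(source) - (max(c0) + tile_size)
  manifest
}

#' Run the full detection-centering-classification-morphometry pipeline
#'
#' Stages per tile: (1) detection — tiles whose confidence score (from
#' `segmenter`) falls below the threshold are dropped; (2) ORCA centering;
#' tiles converging onto a vessel already reported (final origins within the
#' shift threshold) are dropped as duplicates; (3) classification gate on
#' `classifier`; (4) wall/lumen segmentation with `wall_lumen_segmenter`,
#' single-vessel validation, and morphometry. Every tile's terminal
#' disposition is recorded in the log.
#'
#' @param source numeric intensity matrix (e.g. a synthetic slide from
#'   [make_synthetic_wsi()]).
#' @param config a [pipeline_config()].
#' @param segmenter detection segmenter (tile -> 2-class probability map).
#' @param wall_lumen_segmenter morphometry segmenter (tile -> 3-class map).
#' @param classifier function (vessel_segmentation) -> score in `[0, 1]`.
#' @param roi_mask optional binary matrix the size of `source`; tiles whose
#'   region of interest coverage is zero are dropped before detection.
#' @return list with `reports` (list of [morphometry_report()]), `manifest`
#'   (tile manifest with `disposition` and `confidence` columns), and `log`
#'   (data.frame: stage, tile, action, reason).
#' @export
run_pipeline <- function(source, config = pipeline_config(),
                         segmenter = NULL, wall_lumen_segmenter = NULL,
                         classifier = NULL, roi_mask = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(segmenter))
    segmenter <- function(tile) reference_vessel_segmenter(
      tile, config$dark_threshold, config$min_area)
  if (is.null(wall_lumen_segmenter))
    wall_lumen_segmenter <- function(tile) reference_wall_lumen_segmenter(
      tile, config$dark_threshold, config$min_area)
  if (is.null(classifier))
    classifier <- function(seg) reference_arteriolosclerosis_classifier(
      seg, midpoint = config$classifier_midpoint)
  ts <- config$tile_size
  manifest <- tile_image(source, ts)
  manifest$confidence <- NA_real_
  manifest$disposition <- NA_character_
  log <- list()
  note <- function(stage, tile, action, reason)
    log[[length(log) + 1]] <<- data.frame(stage = stage, tile = tile,
                                          action = action, reason = reason)
  reports <- list()
  report_origins <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(manifest))) {
    org <- c(manifest$row[i], manifest$col[i])
    if (!is.null(roi_mask)) {
      roi <- extract_tile(roi_mask, org, ts)
      if (!any(roi != 0)) {
        manifest$disposition[i] <- "dropped_roi"
        note("roi", i, "dropped", "outside_roi"); next
      }
    }
    tile <- extract_tile(source, org, ts)
    score <- confidence_score(segmenter(tile))
    manifest$confidence[i] <- score
    if (score < config$detection_threshold) {
      manifest$disposition[i] <- "dropped_detection"
      note("detection", i, "dropped", "no_vessel"); next
    }
    note("detection", i, "kept", sprintf("confidence=%.3f", score))
    cen <- orca_center(source, org, segmenter, tile_size = ts,
                       shift_threshold = config$shift_threshold,
                       max_iter = config$max_iter)
    if (!cen$trace$converged) {
      manifest$disposition[i] <- "dropped_centering"
      note("centering", i, "dropped", cen$trace$reason); next
    }
    fin <- cen$trace$origins[nrow(cen$trace$origins), ]
    if (nrow(report_origins) &&
        any(sqrt(rowSums(sweep(report_origins, 2, fin)^2)) < config$shift_threshold)) {
      manifest$disposition[i] <- "dropped_duplicate"
      note("centering", i, "dropped", "duplicate_center"); next
    }
    labels <- binarize(wall_lumen_segmenter(cen$tile))
    seg <- vessel_segmentation(labels == 1, labels == 2, config$um_per_px)
    cls <- classifier(seg)
    if (cls < config$classifier_threshold) {
      manifest$disposition[i] <- "dropped_classification"
      note("classification", i, "dropped", sprintf("score=%.3f", cls)); next
    }
    note("classification", i, "kept", sprintf("score=%.3f", cls))
    rep <- tryCatch(morphometry_report(seg), error = function(e) e)
    if (inherits(rep, "error")) {
      manifest$disposition[i] <- "dropped_validation"
      note("validation", i, "dropped", conditionMessage(rep)); next
    }
    reports[[length(reports) + 1]] <- rep
    report_origins <- rbind(report_origins, fin)
    manifest$disposition[i] <- "reported"
    note("morphometry", i, "kept", "reported")
  }
  list(reports = reports, manifest = manifest,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(stage = character(), tile = integer(),
                             action = character(), reason = character()))
}
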