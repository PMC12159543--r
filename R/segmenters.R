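# Pluggable segmenter/classifier contracts, a classical reference segmenter
# for phantoms, and the conversion of pixel-wise segmentations into
# tile-level confidence scores.
#
# A "segmenter" is any function tile -> probability_map of identical
# dimensions; a "tile classifier" is any function producing a score in [0,1].
# The reference implementations below are classical (threshold + hole fill +
# component filtering) and exact on noise-free phantoms, so the downstream
# geometry can be exercised without a trained model.

#' Construct a per-pixel class probability map
#'
#' @param p numeric array `height x width x n_classes`; class 1 is background.
#'   For 2-class maps class 2 is "vessel"; for 3-class maps classes 2 and 3
#'   are "wall" and "lumen".
#' @return a `probability_map` object.
#' @export
probability_map <- function(p) {
  stopifnot(is.array(p), length(dim(p)) == 3, dim(p)[3] >= 2)
  if (any(p < -1e-6 | p > 1 + 1e-6))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  sums <- apply(p, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("per-pixel probabilities must sum to 1", call. = FALSE)
  structure(list(p = p, height = dim(p)[1], width = dim(p)[2],
                 n_classes = dim(p)[3]), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d px, %d classes\n",
              x$height, x$width, x$n_classes))
  invisible(x)
}

# build a 2-class map from a binary vessel mask: vessel pixels (eps, 1-eps),
# background (1-eps, eps), the 1-px outer boundary ring softened to 0.5
two_class_map <- function(vessel_mask, eps = 0.01) {
  v <- vessel_mask != 0
  pv <- matrix(eps, nrow(v), ncol(v))
  pv[v] <- 1 - eps
  ring <- EBImage::dilate(matrix(as.numeric(v), nrow(v)),
                          EBImage::makeBrush(3, "box")) != 0 & !v
  pv[ring] <- 0.5
  probability_map(array(c(1 - pv, pv), c(nrow(v), ncol(v), 2)))
}

#' Classical reference vessel segmenter
#'
#' A stand-in for a learned detection model, exact on phantoms: pixels darker
#' than `dark_threshold` are wall candidates; holes (lumens) are filled;
#' connected components smaller than `min_area` px are discarded. The result
#' is returned as a 2-class probability map with vessel probability
#' `1 - eps` inside the detected region, `eps` outside, and `0.5` on the
#' 1-px boundary ring just outside the region.
#'
#' @param tile numeric matrix, 8-bit grayscale intensities.
#' @param dark_threshold intensity below which a pixel is wall tissue.
#' @param min_area minimum component area (px) kept.
#' @param eps probability floor.
#' @return a [probability_map()] with classes (background, vessel).
#' @export
reference_vessel_segmenter <- function(tile, dark_threshold = 150,
                                       min_area = 64, eps = 0.01) {
  stopifnot(is.matrix(tile))
  wall <- tile < dark_threshold
  vessel <- fill_holes(wall)
  lab <- label_components(vessel, connectivity = 8)
  if (max(lab) > 0) {
    keep <- which(tabulate(lab[lab > 0]) >= min_area)
    vessel <- matrix(as.numeric(lab %in% keep & lab > 0), nrow(tile))
  }
  two_class_map(vessel, eps)
}

#' Classical reference wall/lumen segmenter
#'
#' Three-class variant of [reference_vessel_segmenter()] for the morphometry
#' stage: wall = dark pixels within a kept component, lumen = enclosed
#' non-wall pixels. Probabilities are one-hot softened to `1 - 2*eps`.
#'
#' @inheritParams reference_vessel_segmenter
#' @return a [probability_map()] with classes (background, wall, lumen).
#' @export
reference_wall_lumen_segmenter <- function(tile, dark_threshold = 150,
                                           min_area = 64, eps = 0.01) {
  stopifnot(is.matrix(tile))
  wall <- tile < dark_threshold
  vessel <- fill_holes(wall)
  lab <- label_components(vessel, connectivity = 8)
  if (max(lab) > 0) {
    keep <- which(tabulate(lab[lab > 0]) >= min_area)
    vessel <- lab %in% keep & lab > 0
    dim(vessel) <- dim(tile)
  }
  wall <- wall & vessel
  lumen <- vessel & !wall
  p_bg <- matrix(1 - 2 * eps, nrow(tile), ncol(tile))
  p_wall <- matrix(eps, nrow(tile), ncol(tile))
  p_lum <- matrix(eps, nrow(tile), ncol(tile))
  p_bg[vessel] <- eps
  p_wall[wall] <- 1 - 2 * eps
  p_lum[lumen] <- 1 - 2 * eps
  probability_map(array(c(p_bg, p_wall, p_lum), c(dim(tile), 3)))
}

#' Convert a probability map into a tile-level confidence score
#'
#' The detection confidence of a tile is the mean of the vessel-class
#' probabilities over the set of pixels where the vessel probability is
#' strictly greater than the background probability; when that set is empty
#' the score is 0. For maps with more than two classes the vessel
#' probability is `1 - p(background)`.
#'
#' @param pm a [probability_map()].
#' @return a score in `[0, 1]`.
#' @export
confidence_score <- function(pm) {
  stopifnot(inherits(pm, "probability_map"))
  p_bg <- pm$p[, , 1]
  p_vessel <- 1 - p_bg
  set <- p_vessel > p_bg
  if (!any(set)) return(0)
  mean(p_vessel[set])
}

#' Binarize a probability map into a label mask
#'
#' Two-class maps use a threshold on the vessel probability with strict
#' inequality, so a pixel at exactly the threshold is background; maps with
#' three or more classes use per-pixel argmax with ties broken towards the
#' lowest class index (background first).
#'
#' @param pm a [probability_map()].
#' @param threshold vessel-probability threshold for 2-class maps.
#' @return integer label matrix (0 = background, 1 = vessel for 2-class;
#'   0/1/2 = background/wall/lumen for 3-class).
#' @export
binarize <- function(pm, threshold = 0.5) {
  stopifnot(inherits(pm, "probability_map"))
  if (pm$n_classes == 2) {
    out <- matrix(0L, pm$height, pm$width)
    out[pm$p[, , 2] > threshold] <- 1L
    return(out)
  }
  flat <- matrix(pm$p, pm$height * pm$width, pm$n_classes)
  cls <- max.col(flat, ties.method = "first") - 1L
  matrix(cls, pm$height, pm$width)
}

#' Rule-based arteriolosclerosis classifier
#'
#' A transparent stand-in for a learned tile classifier, motivated by the
#' quantitative definition of arteriolosclerosis as wall thickening with
#' luminal narrowing: a logistic transform of the wall-to-lumen area ratio
#' around a configurable midpoint. Monotone increasing in the ratio; a
#' vessel with no measurable lumen scores 1 (fully stenosed convention).
#'
#' @param seg a [vessel_segmentation()].
#' @param midpoint ratio at which the score is 0.5.
#' @param scale logistic scale (ratio units).
#' @return a score in `[0, 1]`.
#' @export
reference_arteriolosclerosis_classifier <- function(seg, midpoint = 2, scale = 1) {
  stopifnot(inherits(seg, "vessel_segmentation"))
  lumen_px <- sum(seg$lumen_mask)
  if (lumen_px == 0) return(1)
  ratio <- sum(seg$wall_mask) / lumen_px
  stats::plogis((ratio - midpoint) / scale)
}
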