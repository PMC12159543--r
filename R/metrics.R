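# Segmentation and classification evaluation: Dice overlap, symmetric
# Hausdorff distance on boundary pixels, pixel/um conversions, AUC-ROC from
# tile confidence scores, and k-fold mean aggregation for report tables.

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks agree perfectly (1).
#'
#' @param a,b binary matrices of identical dimensions.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dimension mismatch", call. = FALSE)
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Symmetric Hausdorff distance between mask boundaries
#'
#' The classic symmetric max-min Euclidean distance between the boundary
#' pixel sets of the two masks (boundaries per [mask_boundary()]): the
#' larger of the two directed Hausdorff distances.
#'
#' @param a,b non-empty binary matrices of identical dimensions.
#' @return distance in pixels.
#' @export
hausdorff_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dimension mismatch", call. = FALSE)
  if (!any(a != 0) || !any(b != 0)) stop("undefined for empty set", call. = FALSE)
  pa <- mask_boundary(a)
  pb <- mask_boundary(b)
  directed <- function(p, q) {
    # min distance from each point of p to the set q, in chunks
    best <- rep(Inf, nrow(p))
    chunk <- 2048L
    for (s in seq(1, nrow(q), by = chunk)) {
      qq <- q[s:min(s + chunk - 1, nrow(q)), , drop = FALSE]
      d2 <- outer(p[, 1], qq[, 1], `-`)^2 + outer(p[, 2], qq[, 2], `-`)^2
      best <- pmin(best, apply(d2, 1, min))
    }
    max(sqrt(best))
  }
  max(directed(pa, pb), directed(pb, pa))
}

#' Pixel/micrometer conversions
#'
#' Lengths scale with the resolution, areas with its square (0.220 um/px
#' gives 0.0484 um^2 per pixel).
#'
#' @param length_px,area_px quantities in pixel units.
#' @param um_per_px resolution in micrometers per pixel (> 0).
#' @return converted quantity in um / um^2.
#' @export
px_to_um <- function(length_px, um_per_px = 0.220) {
  if (um_per_px <= 0) stop("invalid resolution", call. = FALSE)
  length_px * um_per_px
}

#' @rdname px_to_um
#' @export
px2_to_um2 <- function(area_px, um_per_px = 0.220) {
  if (um_per_px <= 0) stop("invalid resolution", call. = FALSE)
  area_px * um_per_px^2
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counting one half — the
#' rank-statistic (Mann-Whitney) form, identical to the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric vector of confidence scores.
#' @param labels binary vector (1 = positive) of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean of per-fold metric values for report tables
#'
#' Arithmetic mean rounded half-away-from-zero to two decimals, the
#' convention for the mean row of a cross-validation table.
#'
#' @param fold_values numeric vector, one value per fold.
#' @return rounded mean.
#' @export
kfold_mean <- function(fold_values) {
  if (!length(fold_values)) stop("no folds", call. = FALSE)
  m <- mean(fold_values)
  sign(m) * floor(abs(m) * 100 + 0.5) / 100
}

#' Evaluate a predicted segmentation against a reference
#'
#' @param pred,truth binary matrices of identical dimensions.
#' @param um_per_px resolution for the Hausdorff conversion.
#' @return list: `dice`, `hausdorff_px`, `hausdorff_um`.
#' @export
evaluate_segmentation <- function(pred, truth, um_per_px = 0.220) {
  h <- hausdorff_distance(pred, truth)
  list(dice = dice_score(pred, truth),
       hausdorff_px = h,
       hausdorff_um = px_to_um(h, um_per_px))
}
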