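# Vascular morphometry from a single-vessel wall/lumen segmentation:
# sclerotic index, wall thickness by the tangent-line and radii methods, and
# the wall-to-lumen area ratio, with summary statistics in physical units.

#' Construct a vessel segmentation
#'
#' Paired wall and lumen binary masks with the physical pixel size. The
#' masks must have identical dimensions and be disjoint.
#'
#' @param wall_mask,lumen_mask binary matrices (non-zero = member).
#' @param um_per_px physical resolution in micrometers per pixel.
#' @return a `vessel_segmentation` object.
#' @export
vessel_segmentation <- function(wall_mask, lumen_mask, um_per_px = 0.220) {
  stopifnot(is.matrix(wall_mask), is.matrix(lumen_mask),
            all(dim(wall_mask) == dim(lumen_mask)), um_per_px > 0)
  wall <- matrix(as.numeric(wall_mask != 0), nrow(wall_mask))
  lumen <- matrix(as.numeric(lumen_mask != 0), nrow(lumen_mask))
  if (any(wall == 1 & lumen == 1))
    stop("wall and lumen masks must be disjoint", call. = FALSE)
  structure(list(wall_mask = wall, lumen_mask = lumen,
                 um_per_px = um_per_px), class = "vessel_segmentation")
}

#' Build a vessel segmentation from a 3-class label mask
#'
#' @param labels integer matrix with 0 = background, 1 = wall, 2 = lumen.
#' @inheritParams vessel_segmentation
#' @return a [vessel_segmentation()].
#' @export
as_vessel_segmentation <- function(labels, um_per_px = 0.220) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  vessel_segmentation(labels == 1, labels == 2, um_per_px)
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("<vessel_segmentation> %d x %d px @ %.3f um/px; wall %d px, lumen %d px\n",
              nrow(x$wall_mask), ncol(x$wall_mask), x$um_per_px,
              sum(x$wall_mask), sum(x$lumen_mask)))
  invisible(x)
}

#' Validate that a segmentation contains exactly one closed vessel
#'
#' Morphometry is defined for tiles containing a single vessel whose wall
#' fully encloses the lumen. The check fails with `"multi-vessel tile"` when
#' wall plus lumen form more than one 8-connected component or when several
#' disjoint lumens share one contiguous wall (vessel clusters), and with
#' `"open wall"` when any lumen pixel can reach the raster border through
#' non-wall pixels (4-connected flood fill), i.e. the wall ring is broken.
#'
#' @param seg a [vessel_segmentation()].
#' @return the segmentation, invisibly, when valid; otherwise an error.
#' @export
validate_single_vessel <- function(seg) {
  stopifnot(inherits(seg, "vessel_segmentation"))
  vessel <- seg$wall_mask + seg$lumen_mask
  if (!any(vessel > 0)) stop("empty segmentation", call. = FALSE)
  if (!any(seg$lumen_mask > 0)) stop("no lumen", call. = FALSE)
  lab <- label_components(vessel, connectivity = 8)
  if (max(lab) > 1) stop("multi-vessel tile", call. = FALSE)
  # contiguous-wall clusters: one vessel component but several disjoint lumens
  if (max(label_components(seg$lumen_mask, connectivity = 8)) > 1)
    stop("multi-vessel tile", call. = FALSE)
  # free space = everything but wall; lumen must not share a 4-connected
  # free-space component with the raster border
  free <- label_components(1 - seg$wall_mask, connectivity = 4)
  border <- unique(c(free[1, ], free[nrow(free), ], free[, 1], free[, ncol(free)]))
  border <- border[border > 0]
  lumen_labels <- unique(free[seg$lumen_mask == 1])
  if (any(lumen_labels %in% border)) stop("open wall", call. = FALSE)
  invisible(seg)
}

#' Centroid of the lumen mask
#'
#' @param lumen_mask binary matrix.
#' @return `(row, col)` arithmetic mean of lumen pixel coordinates, 0-based.
#' @export
lumen_centroid <- function(lumen_mask) {
  if (inherits(lumen_mask, "vessel_segmentation")) lumen_mask <- lumen_mask$lumen_mask
  idx <- which(lumen_mask != 0, arr.ind = TRUE) - 1
  if (!nrow(idx)) stop("no lumen", call. = FALSE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Summary statistics of a measurement set
#'
#' Median, mean, sample standard deviation (n-1 denominator; 0 for a single
#' measurement), minimum, maximum and the number of contributing
#' measurements. `NA` values (excluded/invalid measurements) are dropped.
#'
#' @param x numeric vector.
#' @return named list: `median`, `mean`, `sd`, `min`, `max`, `n_valid`.
#' @export
summary_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no measurable values", call. = FALSE)
  list(median = median(x), mean = mean(x),
       sd = if (length(x) > 1) sd(x) else 0,
       min = min(x), max = max(x), n_valid = length(x))
}

#' Per-angle internal/external diameters and sclerotic index
#'
#' For each angle theta over a half circle, two rays are cast from the lumen
#' centroid at theta and theta + 180 deg (sub-pixel sampling every
#' `step` px on bilinearly interpolated masks). The internal diameter
#' `D_i(theta)` spans the first lumen exits of the two rays, the external
#' diameter `D_e(theta)` the last wall-to-background transitions, and the
#' sclerotic index is `SI = 1 - D_i/D_e`. An angle is invalid when either
#' ray meets background before wall (broken wall ring).
#'
#' @param seg a [vessel_segmentation()].
#' @param centroid `(row, col)` override; defaults to [lumen_centroid()].
#' @param angle_step angle increment in degrees.
#' @param step ray sampling step in pixels.
#' @return data.frame of class `radial_diameter_profile` with columns
#'   `theta`, `d_i`, `d_e`, `si`, `valid`; attribute `qc_centroid_outside`
#'   is `TRUE` when the centroid fell outside the lumen (all angles
#'   invalid).
#' @export
radial_diameter_profile <- function(seg, centroid = NULL, angle_step = 1,
                                    step = 0.25) {
  stopifnot(inherits(seg, "vessel_segmentation"))
  if (is.null(centroid)) centroid <- lumen_centroid(seg$lumen_mask)
  thetas <- seq(0, 180 - angle_step, by = angle_step)
  vessel <- pmin(seg$wall_mask + seg$lumen_mask, 1)
  out <- data.frame(theta = thetas, d_i = NA_real_, d_e = NA_real_,
                    si = NA_real_, valid = FALSE)
  centroid_outside <- bilinear_sample(seg$lumen_mask, centroid[1], centroid[2]) < 0.5
  if (!centroid_outside) {
    fwd <- cast_rays(seg$lumen_mask, vessel, centroid, thetas, step)
    bwd <- cast_rays(seg$lumen_mask, vessel, centroid, thetas + 180, step)
    ok <- fwd$valid & bwd$valid
    out$d_i[ok] <- fwd$r_in[ok] + bwd$r_in[ok]
    out$d_e[ok] <- fwd$r_out[ok] + bwd$r_out[ok]
    out$si[ok] <- 1 - out$d_i[ok] / out$d_e[ok]
    out$valid <- ok
  }
  structure(out, class = c("radial_diameter_profile", "data.frame"),
            qc_centroid_outside = centroid_outside)
}

#' Summary statistics of the sclerotic index profile
#'
#' @param profile a [radial_diameter_profile()].
#' @return [summary_stats()] over the valid per-angle sclerotic indices.
#' @export
sclerotic_index_stats <- function(profile) {
  stopifnot(inherits(profile, "radial_diameter_profile"))
  si <- profile$si[profile$valid]
  if (!length(si)) stop("no measurable angles", call. = FALSE)
  summary_stats(si)
}

#' Per-degree radial wall thickness
#'
#' For each angle over a full circle, a single ray from the lumen centroid
#' measures the internal radius `R_i(theta)` (first lumen exit) and external
#' radius `R_e(theta)` (last wall-to-background transition); the thickness is
#' `T = R_e - R_i`. Angles where background precedes wall are invalid.
#'
#' @inheritParams radial_diameter_profile
#' @return data.frame of class `radial_thickness_profile` with columns
#'   `theta`, `r_i`, `r_e`, `t_px`, `valid`.
#' @export
radial_thickness_profile <- function(seg, centroid = NULL, angle_step = 1,
                                     step = 0.25) {
  stopifnot(inherits(seg, "vessel_segmentation"))
  if (is.null(centroid)) centroid <- lumen_centroid(seg$lumen_mask)
  thetas <- seq(0, 360 - angle_step, by = angle_step)
  vessel <- pmin(seg$wall_mask + seg$lumen_mask, 1)
  out <- data.frame(theta = thetas, r_i = NA_real_, r_e = NA_real_,
                    t_px = NA_real_, valid = FALSE)
  centroid_outside <- bilinear_sample(seg$lumen_mask, centroid[1], centroid[2]) < 0.5
  if (!centroid_outside) {
    rays <- cast_rays(seg$lumen_mask, vessel, centroid, thetas, step)
    ok <- rays$valid
    out$r_i[ok] <- rays$r_in[ok]
    out$r_e[ok] <- rays$r_out[ok]
    out$t_px[ok] <- rays$r_out[ok] - rays$r_in[ok]
    out$valid <- ok
  }
  structure(out, class = c("radial_thickness_profile", "data.frame"),
            qc_centroid_outside = centroid_outside)
}

# Extract the lumen contour at the 0.5 level of the binary mask, oriented
# counterclockwise (positive shoelace area in (row, col) axes), resampled to
# n arc-length-equidistant points starting at the point with the smallest
# positive angle from the centroid's +col axis.
lumen_contour <- function(lumen_mask, n = 100, centroid = NULL) {
  if (is.null(centroid)) centroid <- lumen_centroid(lumen_mask)
  cl <- contourLines(x = 0:(nrow(lumen_mask) - 1), y = 0:(ncol(lumen_mask) - 1),
                     z = lumen_mask, levels = 0.5)
  if (!length(cl)) stop("contour too small", call. = FALSE)
  shoelace <- function(p) 0.5 * sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                                    c(p[-1, 1], p[1, 1]) * p[, 2])
  # keep the contour enclosing the largest area
  areas <- vapply(cl, function(k) abs(shoelace(cbind(k$x, k$y))), numeric(1))
  k <- cl[[which.max(areas)]]
  pts <- cbind(row = k$x, col = k$y)
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 8) stop("contour too small", call. = FALSE)
  if (shoelace(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  # rotate to start at the smallest positive angle from the +col axis
  ang <- atan2(pts[, 1] - centroid[1], pts[, 2] - centroid[2]) %% (2 * pi)
  start <- which.min(ang)
  pts <- pts[c(start:nrow(pts), seq_len(start - 1)), , drop = FALSE]
  # arc-length resampling to n points
  closed <- rbind(pts, pts[1, ])
  seglen <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- (seq_len(n) - 1) / n * total
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  f <- (s - cum[i]) / pmax(seglen[i], .Machine$double.eps)
  cbind(row = closed[i, 1] + f * (closed[i + 1, 1] - closed[i, 1]),
        col = closed[i, 2] + f * (closed[i + 1, 2] - closed[i, 2]))
}

#' Tangent-line wall thickness profile
#'
#' The lumen contour is traced at the 0.5 level of the mask and resampled to
#' `n_points` arc-length-equidistant points. At each point the tangent is
#' estimated by central differences over a moving-average-smoothed window
#' (half-width `smooth_halfwidth` points, wide enough to suppress the
#' raster zigzag of the traced contour); the thickness `T` is the length of
#' the ray from the point along
#' the outward normal to the last wall-to-background transition. Points
#' whose outward normal points towards the lumen center
#' (`normal . (point - centroid) < 0`, as arises inside lumen involutions)
#' are excluded with reason `inward_pointing`; rays that leave the raster
#' before exiting the wall are excluded with reason `no_intersection`.
#'
#' @param seg a [vessel_segmentation()].
#' @param n_points number of contour sample points.
#' @param step ray sampling step in pixels.
#' @param smooth_halfwidth half-width (in contour points) of the smoothing
#'   and differencing window for the tangent estimate.
#' @return data.frame of class `tangent_thickness_profile` with columns
#'   `alpha` (sample index), `row`, `col` (contact point), `normal_row`,
#'   `normal_col`, `t_px`, `excluded`, `reason`.
#' @export
tangent_thickness_profile <- function(seg, n_points = 100, step = 0.25,
                                      smooth_halfwidth = 4) {
  stopifnot(inherits(seg, "vessel_segmentation"), smooth_halfwidth >= 1)
  centroid <- lumen_centroid(seg$lumen_mask)
  pts <- lumen_contour(seg$lumen_mask, n = n_points, centroid = centroid)
  vessel <- pmin(seg$wall_mask + seg$lumen_mask, 1)
  n <- nrow(pts)
  hw <- min(smooth_halfwidth, floor((n - 1) / 2))
  wrap <- function(i) ((i - 1) %% n) + 1
  # moving-average smoothing, then central differences hw points apart;
  # contact points stay unsmoothed, only the tangent uses the smoothed curve
  sm <- Reduce(`+`, lapply(-hw:hw, function(d)
    pts[wrap(seq_len(n) + d), , drop = FALSE])) / (2 * hw + 1)
  tang <- sm[wrap(seq_len(n) + hw), ] - sm[wrap(seq_len(n) - hw), ]
  tlen <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(tlen, .Machine$double.eps)
  # CCW contour in (row, col) axes: outward normal = (t_col, -t_row)
  normal <- cbind(tang[, 2], -tang[, 1])
  out <- data.frame(alpha = seq_len(n), row = pts[, 1], col = pts[, 2],
                    normal_row = normal[, 1], normal_col = normal[, 2],
                    t_px = NA_real_, excluded = TRUE,
                    reason = NA_character_)
  inward <- rowSums(normal * sweep(pts, 2, centroid)) < 0
  out$reason[inward] <- "inward_pointing"
  for (i in which(!inward)) {
    theta <- atan2(normal[i, 1], normal[i, 2]) * 180 / pi
    ray <- cast_rays(seg$lumen_mask, vessel, pts[i, ], theta, step,
                     require_lumen_start = FALSE)
    if (ray$valid[1]) {
      out$t_px[i] <- ray$r_out[1]
      out$excluded[i] <- FALSE
    } else {
      out$reason[i] <- "no_intersection"
    }
  }
  structure(out, class = c("tangent_thickness_profile", "data.frame"),
            centroid = centroid)
}

#' Wall and lumen areas in physical units
#'
#' Pixel counts converted with the squared resolution (`0.220` um/px gives
#' the per-pixel area factor `0.0484` um^2). The ratio is wall over lumen;
#' it is `NA` (flagged undefined) when the lumen is empty.
#'
#' @param seg a [vessel_segmentation()].
#' @return list: `wall_area_um2`, `lumen_area_um2`, `wall_lumen_ratio`.
#' @export
wall_lumen_areas <- function(seg) {
  stopifnot(inherits(seg, "vessel_segmentation"))
  f <- seg$um_per_px^2
  wall <- sum(seg$wall_mask) * f
  lumen <- sum(seg$lumen_mask) * f
  list(wall_area_um2 = wall, lumen_area_um2 = lumen,
       wall_lumen_ratio = if (lumen > 0) wall / lumen else NA_real_)
}

#' Eccentric sectioning geometry of an elliptical cross-section
#'
#' A cylindrical vessel sectioned at angle theta yields an ellipse whose
#' short/long diameter ratio equals `cos(theta)`; the reciprocal can serve
#' as a thickness correction factor. The correction is reported but never
#' applied inside default morphometry reports.
#'
#' @param d_s,d_l short and long diameters (same units).
#' @return list: `d_s`, `d_l`, `cos_theta`, `theta_deg`, `correction_factor`.
#' @export
eccentricity_correction <- function(d_s, d_l) {
  stopifnot(d_s > 0, d_l > 0)
  if (d_s > d_l) stop("diameters swapped", call. = FALSE)
  ct <- d_s / d_l
  list(d_s = d_s, d_l = d_l, cos_theta = ct,
       theta_deg = acos(ct) * 180 / pi, correction_factor = 1 / ct)
}

#' Full morphometry report for a single vessel
#'
#' Validates the segmentation, then composes the sclerotic index profile,
#' both wall thickness estimators (reported in micrometers), and the
#' wall-to-lumen area ratio, with per-stage QC counts of invalid angles and
#' excluded tangent points.
#'
#' @param seg a [vessel_segmentation()].
#' @param n_tangent_points number of tangent-method contour samples.
#' @param angle_step degree step for the radial profiles.
#' @return a `morphometry_report` object: `si_stats`,
#'   `thickness_tangent_stats` and `thickness_radial_stats` (um),
#'   `wall_area_um2`, `lumen_area_um2`, `wall_lumen_ratio`, `um_per_px`,
#'   and `qc` (invalid/excluded counts by reason).
#' @export
morphometry_report <- function(seg, n_tangent_points = 100, angle_step = 1) {
  validate_single_vessel(seg)
  dia <- radial_diameter_profile(seg, angle_step = angle_step)
  rad <- radial_thickness_profile(seg, angle_step = angle_step)
  tan <- tangent_thickness_profile(seg, n_points = n_tangent_points)
  areas <- wall_lumen_areas(seg)
  u <- seg$um_per_px
  structure(list(
    si_stats = sclerotic_index_stats(dia),
    thickness_tangent_stats = summary_stats(tan$t_px * u),
    thickness_radial_stats = summary_stats(rad$t_px * u),
    wall_area_um2 = areas$wall_area_um2,
    lumen_area_um2 = areas$lumen_area_um2,
    wall_lumen_ratio = areas$wall_lumen_ratio,
    um_per_px = u,
    qc = list(
      si_invalid_angles = sum(!dia$valid),
      radial_invalid_angles = sum(!rad$valid),
      tangent_excluded = sum(tan$excluded),
      tangent_inward_pointing = sum(tan$reason %in% "inward_pointing"),
      tangent_no_intersection = sum(tan$reason %in% "no_intersection"),
      centroid_outside_lumen = isTRUE(attr(dia, "qc_centroid_outside")))),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  fmt <- function(s, d = 3) sprintf(
    "median %.*f  mean %.*f  sd %.*f  min %.*f  max %.*f  (n=%d)",
    d, s$median, d, s$mean, d, s$sd, d, s$min, d, s$max, s$n_valid)
  cat("<morphometry_report>\n")
  cat("  sclerotic index:      ", fmt(x$si_stats), "\n")
  cat("  thickness tangent um: ", fmt(x$thickness_tangent_stats, 2), "\n")
  cat("  thickness radial um:  ", fmt(x$thickness_radial_stats, 2), "\n")
  cat(sprintf("  wall area %.2f um2, lumen area %.2f um2, ratio %s\n",
              x$wall_area_um2, x$lumen_area_um2,
              if (is.na(x$wall_lumen_ratio)) "undefined"
              else sprintf("%.2f", x$wall_lumen_ratio)))
  qc <- x$qc
  cat(sprintf("  qc: %d invalid SI angle(s), %d invalid radial angle(s), %d excluded tangent point(s)\n",
              qc$si_invalid_angles, qc$radial_invalid_angles, qc$tangent_excluded))
  invisible(x)
}

#' Flatten a morphometry report into a one-row data frame
#'
#' Column layout matches the CSV report written by the pipeline: `si_*`,
#' `tt_*` (tangent thickness, um), `rt_*` (radial thickness, um), areas,
#' ratio and QC counts.
#'
#' @param x a `morphometry_report`.
#' @param row.names,optional,... ignored; present for the generic.
#' @return a one-row data.frame.
#' @export
as.data.frame.morphometry_report <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  unpack <- function(s, prefix)
    setNames(as.data.frame(s[c("median", "mean", "sd", "min", "max")]),
             paste0(prefix, c("median", "mean", "sd", "min", "max")))
  cbind(unpack(x$si_stats, "si_"),
        unpack(x$thickness_tangent_stats, "tt_"),
        unpack(x$thickness_radial_stats, "rt_"),
        data.frame(wall_area_um2 = x$wall_area_um2,
                   lumen_area_um2 = x$lumen_area_um2,
                   wall_lumen_ratio = x$wall_lumen_ratio,
                   qc_si_invalid = x$qc$si_invalid_angles,
                   qc_radial_invalid = x$qc$radial_invalid_angles,
                   qc_tangent_excluded = x$qc$tangent_excluded))
}
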