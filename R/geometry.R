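# Low-level raster geometry shared by the phantom, centering and morphometry
# code: bilinear sampling, connected components, boundary extraction, and the
# sub-pixel ray caster used by every radial measurement.

#' Bilinearly sample a matrix at fractional (row, col) positions
#'
#' Coordinates are 0-based pixel centers; positions outside the raster are
#' clamped to the edge. Used to evaluate binary masks as continuous indicator
#' fields, so that the 0.5 level traces the sub-pixel region boundary.
#'
#' @param m numeric matrix.
#' @param row,col numeric vectors of equal length, 0-based coordinates.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(row), nr - 2L)
  c0 <- pmin(floor(col), nc - 2L)
  fr <- row - r0
  fc <- col - c0
  m[cbind(r0 + 1L, c0 + 1L)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0 + 2L)] * (1 - fr) * fc +
    m[cbind(r0 + 2L, c0 + 1L)] * fr * (1 - fc) +
    m[cbind(r0 + 2L, c0 + 2L)] * fr * fc
}

#' Label connected components of a binary mask
#'
#' 4-connected labelling is delegated to [EBImage::bwlabel()]; 8-connectivity
#' is obtained by merging 4-connected labels that touch diagonally.
#'
#' @param mask binary matrix (non-zero = foreground).
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  if (connectivity == 4 || max(lab) <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal label adjacencies
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Fill holes in a binary mask
#'
#' @param mask binary matrix.
#' @return binary (0/1) matrix with enclosed holes filled.
#' @export
fill_holes <- function(mask) {
  out <- EBImage::fillHull(matrix(as.numeric(mask != 0), nrow(mask)))
  matrix(as.numeric(out != 0), nrow(mask))
}

#' Boundary pixels of a binary mask
#'
#' A foreground pixel is a boundary pixel if any 4-neighbour is background or
#' lies outside the raster.
#'
#' @param mask binary matrix.
#' @return two-column matrix of 0-based (row, col) boundary coordinates.
#' @export
mask_boundary <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  interior <- core &
    pad[1:nrow(m), 2:(ncol(m) + 1)] & pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] &
    pad[2:(nrow(m) + 1), 1:ncol(m)] & pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  idx <- which(core & !interior, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

# Cast rays from `origin` (0-based row,col) at angles `theta_deg` through the
# lumen/wall indicator fields. Along each ray (samples every `step` px, until
# the raster edge) the lumen and vessel (wall|lumen) masks are evaluated by
# bilinear interpolation and thresholded at 0.5; transitions are located at
# the midpoint between consecutive samples. Returns per angle:
#   r_in  - distance to the FIRST lumen -> non-lumen transition
#   r_out - distance to the LAST vessel -> background transition
#   valid - FALSE when background is met before wall after leaving the lumen,
#           when a required transition is missing, or when the ray starts
#           outside the lumen (for require_lumen_start = TRUE)
cast_rays <- function(lumen, vessel, origin, theta_deg, step = 0.25,
                      require_lumen_start = TRUE) {
  nr <- nrow(lumen); nc <- ncol(lumen)
  a <- theta_deg * pi / 180
  dr <- sin(a); dc <- cos(a)
  # per-ray distance to the raster edge
  lim_r <- ifelse(dr > 0, (nr - 1 - origin[1]) / dr,
                  ifelse(dr < 0, -origin[1] / dr, Inf))
  lim_c <- ifelse(dc > 0, (nc - 1 - origin[2]) / dc,
                  ifelse(dc < 0, -origin[2] / dc, Inf))
  tmax_all <- pmax(pmin(lim_r, lim_c), 0)
  n_ang <- length(theta_deg)
  res <- data.frame(theta = theta_deg, r_in = NA_real_, r_out = NA_real_,
                    valid = FALSE, reason = NA_character_)
  tmax <- max(tmax_all)
  ts <- seq(0, tmax, by = step)
  # sample all rays at once: matrix [n_samples x n_angles]
  rr <- outer(ts, dr) + origin[1]
  cc <- outer(ts, dc) + origin[2]
  in_range <- outer(ts, tmax_all, `<=`)
  L <- matrix(bilinear_sample(lumen, as.vector(rr), as.vector(cc)) >= 0.5, length(ts))
  V <- matrix(bilinear_sample(vessel, as.vector(rr), as.vector(cc)) >= 0.5, length(ts))
  L[!in_range] <- FALSE
  V[!in_range] <- FALSE
  for (j in seq_len(n_ang)) {
    nk <- sum(in_range[, j])
    if (nk < 2) { res$reason[j] <- "ray_outside_raster"; next }
    Lj <- L[seq_len(nk), j]; Vj <- V[seq_len(nk), j]
    if (require_lumen_start && !Lj[1]) { res$reason[j] <- "origin_outside_lumen"; next }
    i_exit <- which(Lj[-nk] & !Lj[-1])
    if (require_lumen_start) {
      if (!length(i_exit)) { res$reason[j] <- "no_lumen_exit"; next }
      i1 <- i_exit[1]
      res$r_in[j] <- (ts[i1] + ts[i1 + 1]) / 2
      if (!Vj[i1 + 1]) { res$reason[j] <- "background_before_wall"; next }
    }
    i_vexit <- which(Vj[-nk] & !Vj[-1])
    if (!length(i_vexit)) { res$reason[j] <- "no_wall_exit"; next }
    i2 <- max(i_vexit)
    res$r_out[j] <- (ts[i2] + ts[i2 + 1]) / 2
    res$valid[j] <- TRUE
  }
  res
}
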