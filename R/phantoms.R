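# Synthetic vessel phantoms: parametric cross-sectioned vessels rendered onto
# a raster with analytic ground truth, used as fixtures for every downstream
# stage (segmentation, centering, morphometry, evaluation).

#' Phantom shape constructors
#'
#' Shapes describing the lumen and the outer wall boundary of a synthetic
#' vessel. All lengths are in pixels; `rotation` is in degrees, measured from
#' the +col axis towards the +row axis. `shape_ellipse(a, b)` has semi-axis
#' `a` along the +col axis and `b` along the +row axis at `rotation = 0`.
#'
#' `shape_involuted` is a circle whose radius is modulated by an inward notch,
#' \eqn{r(\phi) = r (1 - depth \cdot \max(0, \cos(count \cdot \phi))^4)},
#' with `depth` a fraction of `r` in `[0, 1)`. This emulates infolded lumen
#' contours; because the curve stays star-shaped around its center, very deep
#' notches (`depth` near 1) are needed before discrete contour normals invert.
#'
#' `shape_spiked` is a circle with a thin wall spike (width `width` px)
#' protruding from the +col side of the boundary towards — and, when
#' `depth > r`, past — the center. It reproduces the pathological involution
#' case where tangent-line thickness measurement lines point towards the
#' lumen center and must be excluded.
#'
#' @param r,a,b,A,B radii / semi-axes in pixels.
#' @param rotation rotation in degrees.
#' @param depth involution depth: fraction of `r` in `[0,1)` for
#'   `shape_involuted`, absolute pixels for `shape_spiked`.
#' @param count number of notches around the circumference.
#' @param width spike width in pixels.
#' @return a `phantom_shape` list.
#' @name phantom_shapes
NULL

#' @rdname phantom_shapes
#' @export
shape_circle <- function(r) {
  stopifnot(r > 0)
  structure(list(type = "circle", r = r), class = "phantom_shape")
}

#' @rdname phantom_shapes
#' @export
shape_ellipse <- function(a, b, rotation = 0) {
  stopifnot(a > 0, b > 0)
  structure(list(type = "ellipse", a = a, b = b, rotation = rotation),
            class = "phantom_shape")
}

#' @rdname phantom_shapes
#' @export
shape_involuted <- function(r, depth, count = 1) {
  stopifnot(r > 0, depth >= 0, depth < 1, count >= 1)
  structure(list(type = "involuted", r = r, depth = depth, count = count),
            class = "phantom_shape")
}

#' @rdname phantom_shapes
#' @export
shape_spiked <- function(r, depth, width = 3) {
  stopifnot(r > 0, depth > 0, width > 0)
  structure(list(type = "spiked", r = r, depth = depth, width = width),
            class = "phantom_shape")
}

# largest extent of a shape from its center, used for containment checks
shape_extent <- function(shape) {
  switch(shape$type,
    circle = shape$r,
    ellipse = max(shape$a, shape$b),
    involuted = shape$r,
    spiked = shape$r,
    stop("unknown shape type"))
}

#' Specify a synthetic vessel phantom
#'
#' A parametric cross-sectioned vessel: a lumen shape nested inside an outer
#' wall shape, rendered at three gray levels with optional additive Gaussian
#' noise. The wall outer shape is centered at `center`; the lumen is centered
#' at `center + lumen_offset` (eccentric lumens). The rendered truth masks are
#' noise-free; noise only affects the image.
#'
#' @param canvas_size edge length of the square canvas in pixels.
#' @param center (row, col) of the wall center, 0-based pixels.
#' @param lumen_shape,wall_outer_shape `phantom_shape` objects; the wall outer
#'   shape must be a circle or ellipse.
#' @param lumen_offset (row, col) shift of the lumen center in pixels.
#' @param wall_intensity,lumen_intensity,background_intensity 8-bit gray
#'   levels. Defaults emulate an eosin-dark wall on a pale background with a
#'   near-white lumen.
#' @param noise_sd standard deviation of additive Gaussian noise (gray
#'   levels), clipped to `[0, 255]`.
#' @param seed integer RNG seed for the noise.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(canvas_size = 512,
                         center = c(canvas_size / 2, canvas_size / 2),
                         lumen_shape = shape_circle(10),
                         wall_outer_shape = shape_circle(20),
                         lumen_offset = c(0, 0),
                         wall_intensity = 90,
                         lumen_intensity = 240,
                         background_intensity = 200,
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot(canvas_size >= 16, length(center) == 2, length(lumen_offset) == 2,
            inherits(lumen_shape, "phantom_shape"),
            inherits(wall_outer_shape, "phantom_shape"),
            wall_outer_shape$type %in% c("circle", "ellipse"),
            noise_sd >= 0)
  spec <- structure(list(
    canvas_size = as.integer(canvas_size), center = as.numeric(center),
    lumen_shape = lumen_shape, wall_outer_shape = wall_outer_shape,
    lumen_offset = as.numeric(lumen_offset),
    wall_intensity = wall_intensity, lumen_intensity = lumen_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# boundary points of a shape (relative to its center), for containment checks
shape_boundary_points <- function(shape, n = 720) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  switch(shape$type,
    circle = cbind(shape$r * sin(phi), shape$r * cos(phi)),
    ellipse = {
      rho <- shape$rotation * pi / 180
      u <- shape$a * cos(phi); v <- shape$b * sin(phi)
      cbind(u * sin(rho) + v * cos(rho), u * cos(rho) - v * sin(rho))
    },
    involuted = {
      rphi <- shape$r * (1 - shape$depth * pmax(0, cos(shape$count * phi))^4)
      cbind(rphi * sin(phi), rphi * cos(phi))
    },
    spiked = cbind(shape$r * sin(phi), shape$r * cos(phi)),
    stop("unknown shape type"))
}

# containment: every lumen boundary point must lie inside the wall outer
# shape shrunk by a 2 px margin
validate_phantom_spec <- function(spec) {
  ls <- spec$lumen_shape; ws <- spec$wall_outer_shape
  pts <- sweep(shape_boundary_points(ls), 2, spec$lumen_offset, `+`)
  ok <- if (ws$type == "circle") {
    all(rowSums(pts^2) <= (ws$r - 2)^2)
  } else {
    rho <- ws$rotation * pi / 180
    u <- pts[, 2] * cos(rho) + pts[, 1] * sin(rho)
    v <- -pts[, 2] * sin(rho) + pts[, 1] * cos(rho)
    all((u / (ws$a - 2))^2 + (v / (ws$b - 2))^2 <= 1)
  }
  if (!ok) stop("invalid phantom geometry: lumen not strictly inside wall", call. = FALSE)
  invisible(spec)
}

# membership test: are 0-based points (row, col) inside `shape` centered at
# `center`? Pixel-center convention: strict inequality.
shape_contains <- function(shape, center, row, col) {
  dr <- row - center[1]; dc <- col - center[2]
  switch(shape$type,
    circle = dr^2 + dc^2 < shape$r^2,
    ellipse = {
      rho <- shape$rotation * pi / 180
      u <- dc * cos(rho) + dr * sin(rho)
      v <- -dc * sin(rho) + dr * cos(rho)
      (u / shape$a)^2 + (v / shape$b)^2 < 1
    },
    involuted = {
      phi <- atan2(dr, dc)
      rphi <- shape$r * (1 - shape$depth * pmax(0, cos(shape$count * phi))^4)
      dr^2 + dc^2 < rphi^2
    },
    spiked = {
      inside <- dr^2 + dc^2 < shape$r^2
      spike <- abs(dr) < shape$width / 2 & dc > shape$r - shape$depth & dc <= shape$r
      inside & !spike
    },
    stop("unknown shape type"))
}

#' Render a phantom to an image and ground-truth masks
#'
#' Rasterizes the spec by the pixel-center rule (a pixel belongs to a region
#' iff its center satisfies the region inequality), paints the three gray
#' levels, and adds seeded Gaussian noise clipped to `[0, 255]` and rounded to
#' integers. Identical `(spec, seed)` gives bit-identical output; the truth
#' masks are independent of the noise.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `image` (numeric matrix,
#'   0–255), `truth` (list: `wall_mask`, `lumen_mask`, `labels`
#'   (0=background, 1=wall, 2=lumen), `wall_area_px`, `lumen_area_px`), and
#'   `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$canvas_size
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  lum_center <- spec$center + spec$lumen_offset
  in_lumen <- shape_contains(spec$lumen_shape, lum_center, rows, cols)
  in_outer <- shape_contains(spec$wall_outer_shape, spec$center, rows, cols)
  lumen_mask <- matrix(as.numeric(in_lumen & in_outer), n)
  wall_mask <- matrix(as.numeric(in_outer & !in_lumen), n)
  img <- matrix(spec$background_intensity, n, n)
  img[wall_mask == 1] <- spec$wall_intensity
  img[lumen_mask == 1] <- spec$lumen_intensity
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed,
      img + matrix(rnorm(n * n, 0, spec$noise_sd), n))
  }
  img <- round(pmin(pmax(img, 0), 255))
  structure(list(
    image = img,
    truth = list(wall_mask = wall_mask, lumen_mask = lumen_mask,
                 labels = wall_mask + 2 * lumen_mask,
                 wall_area_px = sum(wall_mask), lumen_area_px = sum(lumen_mask)),
    spec = spec), class = "phantom")
}

#' Closed-form morphometry of a phantom spec
#'
#' Analytic expectations for concentric circle/ellipse phantoms, used as the
#' oracle for the raster-based estimators. For concentric circles the
#' sclerotic index is `1 - r/R` and the wall thickness `R - r` at every
#' angle; for an ellipse lumen the internal diameter through the center is
#' \eqn{D_i(\theta) = 2 / \sqrt{\cos^2\theta/a^2 + \sin^2\theta/b^2}}.
#' Involuted, spiked or offset specs have no closed form and raise an error;
#' use the rasterization oracle instead.
#'
#' @param spec a [phantom_spec()].
#' @param theta_deg angles (degrees) at which to evaluate the profiles.
#' @return list with `si` (per-angle sclerotic index), `radial_thickness_px`
#'   (per-angle `R_e - R_i`), `wall_area_px`, `lumen_area_px`,
#'   `wall_lumen_ratio` (all analytic, not rasterized).
#' @export
analytic_morphometry <- function(spec, theta_deg = 0:179) {
  stopifnot(inherits(spec, "phantom_spec"))
  ls <- spec$lumen_shape; ws <- spec$wall_outer_shape
  if (!ls$type %in% c("circle", "ellipse") || any(spec$lumen_offset != 0))
    stop("no closed form; use rasterization oracle", call. = FALSE)
  polar_radius <- function(shape, theta) {
    if (shape$type == "circle") return(rep(shape$r, length(theta)))
    th <- (theta - shape$rotation) * pi / 180
    1 / sqrt(cos(th)^2 / shape$a^2 + sin(th)^2 / shape$b^2)
  }
  shape_area <- function(shape) {
    if (shape$type == "circle") pi * shape$r^2 else pi * shape$a * shape$b
  }
  r_in <- polar_radius(ls, theta_deg)
  r_out <- polar_radius(ws, theta_deg)
  d_in <- polar_radius(ls, theta_deg) + polar_radius(ls, theta_deg + 180)
  d_out <- polar_radius(ws, theta_deg) + polar_radius(ws, theta_deg + 180)
  la <- shape_area(ls)
  wa <- shape_area(ws) - la
  list(si = 1 - d_in / d_out,
       radial_thickness_px = r_out - r_in,
       wall_area_px = wa, lumen_area_px = la,
       wall_lumen_ratio = wa / la)
}

#' Composite phantoms into a synthetic whole-slide-style image
#'
#' Places each phantom at its spec's `center` (absolute canvas coordinates)
#' on a common background, composites the truth labels, and records each
#' vessel's bookkeeping (centroid, contiguity with neighbouring vessels) for
#' centering experiments. Noise is applied once over the composited canvas.
#'
#' @param specs list of [phantom_spec()]; each spec's `center` is an absolute
#'   position on the canvas and its `canvas_size` is ignored.
#' @param wsi_size canvas edge length in pixels.
#' @param background_intensity background gray level.
#' @param noise_sd Gaussian noise sd applied to the composited image.
#' @param seed RNG seed for the noise.
#' @return list with `image` (numeric matrix), `labels` (0/1/2 truth),
#'   `records` (data.frame: id, row, col of wall center, centroid_row/col of
#'   the vessel mask, lumen_centroid_row/col, contiguous flag).
#' @export
make_synthetic_wsi <- function(specs, wsi_size = 2048, background_intensity = 200,
                               noise_sd = 0, seed = 1L) {
  stopifnot(is.list(specs), all(vapply(specs, inherits, TRUE, "phantom_spec")))
  n <- as.integer(wsi_size)
  img <- matrix(background_intensity, n, n)
  labels <- matrix(0, n, n)
  vessel_ids <- matrix(0L, n, n)
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  recs <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ext <- shape_extent(sp$wall_outer_shape)
    if (sp$center[1] - ext < 0 || sp$center[2] - ext < 0 ||
        sp$center[1] + ext > n - 1 || sp$center[2] + ext > n - 1)
      stop("phantom outside canvas", call. = FALSE)
    lum_center <- sp$center + sp$lumen_offset
    in_lumen <- shape_contains(sp$lumen_shape, lum_center, rows, cols)
    in_outer <- shape_contains(sp$wall_outer_shape, sp$center, rows, cols)
    lum <- in_lumen & in_outer
    wall <- in_outer & !in_lumen
    img[wall] <- sp$wall_intensity
    img[lum] <- sp$lumen_intensity
    labels[wall] <- 1
    labels[lum] <- 2
    vessel_ids[in_outer] <- i
    idx <- which(in_outer, arr.ind = TRUE) - 1
    lidx <- which(lum, arr.ind = TRUE) - 1
    recs[[i]] <- data.frame(
      id = i, row = sp$center[1], col = sp$center[2],
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
      lumen_centroid_row = if (nrow(lidx)) mean(lidx[, 1]) else NA_real_,
      lumen_centroid_col = if (nrow(lidx)) mean(lidx[, 2]) else NA_real_,
      contiguous = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(id = integer(), row = numeric(), col = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          lumen_centroid_row = numeric(),
                          lumen_centroid_col = numeric(), contiguous = logical())
  # contiguity: mark every vessel whose mask is 8-adjacent to a different one
  if (length(specs) > 1) {
    shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
    contig <- rep(FALSE, length(specs))
    for (s in shifts) {
      a <- vessel_ids
      nr <- nrow(a); nc <- ncol(a)
      r1 <- max(1, 1 + s[1]):min(nr, nr + s[1])
      c1 <- max(1, 1 + s[2]):min(nc, nc + s[2])
      r2 <- r1 - s[1]; c2 <- c1 - s[2]
      x <- a[r1, c1]; y <- a[r2, c2]
      hit <- x > 0 & y > 0 & x != y
      if (any(hit)) contig[unique(c(x[hit], y[hit]))] <- TRUE
    }
    records$contiguous <- contig[records$id]
  }
  if (noise_sd > 0) {
    img <- withr::with_seed(as.integer(seed),
      img + matrix(rnorm(n * n, 0, noise_sd), n))
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, labels = labels, records = records)
}
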