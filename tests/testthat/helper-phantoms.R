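# Shared fixture builders: all fixtures are generated in code, no files.

# concentric (or offset) annulus segmentation from rendered truth masks
annulus_seg <- function(r = 10, R = 20, canvas = 4 * ceiling(R) + 48,
                        offset = c(0, 0), um_per_px = 0.220, ...) {
  sp <- phantom_spec(canvas_size = canvas, center = c(canvas / 2, canvas / 2),
                     lumen_shape = shape_circle(r),
                     wall_outer_shape = shape_circle(R),
                     lumen_offset = offset, ...)
  ph <- render_phantom(sp)
  vessel_segmentation(ph$truth$wall_mask, ph$truth$lumen_mask, um_per_px)
}

# segmentation from arbitrary shapes
shape_seg <- function(lumen_shape, wall_shape, canvas = 200, offset = c(0, 0),
                      um_per_px = 0.220) {
  sp <- phantom_spec(canvas_size = canvas, center = c(canvas / 2, canvas / 2),
                     lumen_shape = lumen_shape, wall_outer_shape = wall_shape,
                     lumen_offset = offset)
  ph <- render_phantom(sp)
  vessel_segmentation(ph$truth$wall_mask, ph$truth$lumen_mask, um_per_px)
}

# filled disk mask (pixel-center rule), 0-based center
disk_mask <- function(n, center, r) {
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  matrix(as.numeric((rows - center[1])^2 + (cols - center[2])^2 < r^2), n)
}
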