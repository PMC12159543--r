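test_that("rasterized areas agree with the analytic circle area", {
  for (r in c(10, 14, 20, 31)) {
    sp <- phantom_spec(canvas_size = 128, center = c(64, 64),
                       lumen_shape = shape_circle(r),
                       wall_outer_shape = shape_circle(r + 10))
    ph <- render_phantom(sp)
    expect_lt(abs(ph$truth$lumen_area_px - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("noiseless rendering has exactly the three region gray levels", {
  ph <- render_phantom(phantom_spec(canvas_size = 96, center = c(48, 48)))
  expect_setequal(unique(as.vector(ph$image)), c(200, 90, 240))
})

test_that("noise is seeded, affects the image only, and is deterministic", {
  mk <- function(seed) render_phantom(phantom_spec(
    canvas_size = 96, center = c(48, 48), noise_sd = 10, seed = seed))
  a <- mk(1); b <- mk(2); a2 <- mk(1)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image, b$image))
  expect_identical(a$image, a2$image)  # bit-identical for identical spec+seed
})

test_that("rendering leaves the global RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  render_phantom(phantom_spec(canvas_size = 64, center = c(32, 32), noise_sd = 5))
  expect_identical(.Random.seed, before)
})

test_that("lumen is always enclosed by the wall ring (flood-fill containment)", {
  shapes <- list(shape_circle(10), shape_ellipse(12, 6, 25),
                 shape_involuted(11, 0.6, 2), shape_spiked(11, 16, 3))
  for (ls in shapes) {
    sp <- phantom_spec(canvas_size = 96, center = c(48, 48), lumen_shape = ls,
                       wall_outer_shape = shape_circle(20))
    ph <- render_phantom(sp)
    seg <- vessel_segmentation(ph$truth$wall_mask, ph$truth$lumen_mask)
    expect_no_error(validate_single_vessel(seg))
    expect_true(all(ph$truth$wall_mask * ph$truth$lumen_mask == 0))  # disjoint
  }
})

test_that("geometry violating containment is rejected", {
  expect_error(phantom_spec(lumen_shape = shape_circle(19),
                            wall_outer_shape = shape_circle(20)),
               "invalid phantom geometry")
  expect_error(phantom_spec(lumen_shape = shape_circle(10),
                            wall_outer_shape = shape_circle(15),
                            lumen_offset = c(0, 5)),
               "invalid phantom geometry")
})

test_that("analytic morphometry matches closed forms and refuses open cases", {
  sp <- phantom_spec(lumen_shape = shape_circle(10),
                     wall_outer_shape = shape_circle(20))
  am <- analytic_morphometry(sp)
  expect_equal(am$si, rep(0.5, 180))
  expect_equal(am$radial_thickness_px, rep(10, 180))
  expect_equal(am$wall_lumen_ratio, 3.0)

  spe <- phantom_spec(lumen_shape = shape_ellipse(10, 5),
                      wall_outer_shape = shape_circle(20))
  ame <- analytic_morphometry(spe)
  expect_equal(ame$si[1], 0.5)    # axis diameters 20 over 40
  expect_equal(ame$si[91], 0.75)  # 10 over 40

  expect_error(analytic_morphometry(phantom_spec(
    lumen_shape = shape_involuted(10, 0.5), wall_outer_shape = shape_circle(20))),
    "no closed form")
  expect_error(analytic_morphometry(phantom_spec(
    lumen_shape = shape_circle(8), wall_outer_shape = shape_circle(20),
    lumen_offset = c(0, 4))),
    "no closed form")
})

test_that("synthetic slides record placements and reject out-of-bounds vessels", {
  w <- make_synthetic_wsi(list(phantom_spec(
    center = c(700, 900), lumen_shape = shape_circle(12),
    wall_outer_shape = shape_circle(30))), wsi_size = 2048)
  expect_equal(nrow(w$records), 1)
  expect_lt(abs(w$records$centroid_row - 700), 0.5)
  expect_lt(abs(w$records$centroid_col - 900), 0.5)
  expect_equal(dim(w$image), c(2048, 2048))

  empty <- make_synthetic_wsi(list(), wsi_size = 128)
  expect_equal(nrow(empty$records), 0)
  expect_true(all(empty$image == 200))

  expect_error(make_synthetic_wsi(list(phantom_spec(
    center = c(10, 64), lumen_shape = shape_circle(8),
    wall_outer_shape = shape_circle(16))), wsi_size = 128),
    "phantom outside canvas")
})

test_that("touching vessels are flagged contiguous, separated ones are not", {
  near <- make_synthetic_wsi(list(
    phantom_spec(center = c(100, 80), lumen_shape = shape_circle(8),
                 wall_outer_shape = shape_circle(20)),
    phantom_spec(center = c(100, 119), lumen_shape = shape_circle(8),
                 wall_outer_shape = shape_circle(20))), wsi_size = 256)
  expect_true(all(near$records$contiguous))
  far <- make_synthetic_wsi(list(
    phantom_spec(center = c(60, 60), lumen_shape = shape_circle(8),
                 wall_outer_shape = shape_circle(20)),
    phantom_spec(center = c(180, 180), lumen_shape = shape_circle(8),
                 wall_outer_shape = shape_circle(20))), wsi_size = 256)
  expect_false(any(far$records$contiguous))
})
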