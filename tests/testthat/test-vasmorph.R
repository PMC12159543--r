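test_that("single-vessel validation accepts annuli and rejects broken geometry", {
  expect_no_error(validate_single_vessel(annulus_seg(10, 20)))

  two <- local({
    w1 <- disk_mask(200, c(60, 60), 20) - disk_mask(200, c(60, 60), 10)
    l1 <- disk_mask(200, c(60, 60), 10)
    w2 <- disk_mask(200, c(150, 150), 20) - disk_mask(200, c(150, 150), 10)
    l2 <- disk_mask(200, c(150, 150), 10)
    vessel_segmentation(pmax(w1, w2), pmax(l1, l2))
  })
  expect_error(validate_single_vessel(two), "multi-vessel tile")

  # annulus with a 3-px gap cut through the wall: lumen reaches background
  gap <- local({
    wall <- disk_mask(96, c(48, 48), 20) - disk_mask(96, c(48, 48), 10)
    wall[48:50, 58:69] <- 0
    vessel_segmentation(wall, disk_mask(96, c(48, 48), 10))
  })
  expect_error(validate_single_vessel(gap), "open wall")
})

test_that("lumen centroid matches closed-form centroids", {
  expect_equal(unname(lumen_centroid(disk_mask(128, c(64, 64), 12))), c(64, 64),
               tolerance = 0.51)
  one <- matrix(0, 32, 32); one[11, 21] <- 1
  expect_equal(unname(lumen_centroid(one)), c(10, 20))
  # half disk: centroid offset 4r/(3*pi) from the flat edge
  n <- 128; r <- 30
  rows <- matrix(0:(n - 1), n, n); cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  half <- matrix(as.numeric((rows - 64)^2 + (cols - 64)^2 < r^2 & cols >= 64), n)
  expect_equal(unname(lumen_centroid(half)), c(64, 64 + 4 * r / (3 * pi)),
               tolerance = 0.5)
})

test_that("diameter profile reproduces analytic sclerotic indices", {
  p <- radial_diameter_profile(annulus_seg(10, 20))
  expect_true(all(p$valid))
  # at r = 10 the raster boundary wiggle allows ~0.03 per angle; the profile
  # mean recovers the analytic value well within 0.02
  expect_true(all(abs(p$si - 0.5) <= 0.03))
  expect_lt(abs(mean(p$si) - 0.5), 0.02)

  pe <- radial_diameter_profile(shape_seg(shape_ellipse(10, 5), shape_circle(20),
                                          canvas = 96))
  expect_lt(abs(pe$si[pe$theta == 0] - 0.50), 0.02)
  expect_lt(abs(pe$si[pe$theta == 90] - 0.75), 0.02)

  # SI stays in [0, 1) wherever valid
  expect_true(all(pe$si[pe$valid] >= 0 & pe$si[pe$valid] < 1))
})

test_that("angles where the wall ring is open are marked invalid", {
  wall <- disk_mask(96, c(48, 48), 20) - disk_mask(96, c(48, 48), 10)
  # carve a ~20 degree wedge out of the wall on the +col side
  rows <- matrix(0:95, 96, 96); cols <- matrix(0:95, 96, 96, byrow = TRUE)
  ang <- atan2(rows - 48, cols - 48) * 180 / pi
  wall[abs(ang) < 10 & wall == 1] <- 0
  seg <- vessel_segmentation(wall, disk_mask(96, c(48, 48), 10))
  p <- radial_diameter_profile(seg)
  frac <- mean(!p$valid)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.25)  # ~20/180 of the half-circle angles
})

test_that("sclerotic index statistics summarize the valid angles", {
  p <- radial_diameter_profile(annulus_seg(10, 20))
  s <- sclerotic_index_stats(p)
  expect_equal(s$mean, 0.5, tolerance = 0.02)
  expect_equal(s$n_valid, 180)
  expect_true(s$min <= s$median && s$median <= s$max)

  # brute-force oracle: closed-form SI of the ellipse lumen at the 180 angles
  spe <- phantom_spec(canvas_size = 96, center = c(48, 48),
                      lumen_shape = shape_ellipse(10, 5),
                      wall_outer_shape = shape_circle(20))
  oracle <- analytic_morphometry(spe)$si
  pe <- radial_diameter_profile(shape_seg(shape_ellipse(10, 5), shape_circle(20),
                                          canvas = 96))
  expect_lt(abs(median(pe$si[pe$valid]) - median(oracle)), 0.02)
})

test_that("summary_stats follows the sample conventions", {
  s <- summary_stats(c(0.4, 0.5, 0.6))
  expect_equal(s$mean, 0.5)
  expect_equal(s$min, 0.4)
  expect_equal(s$max, 0.6)
  expect_equal(s$sd, sd(c(0.4, 0.5, 0.6)))  # n-1 denominator
  expect_equal(summary_stats(c(NA, 2))$n_valid, 1)
  expect_equal(summary_stats(2)$sd, 0)
  expect_error(summary_stats(NA_real_), "no measurable")
})

test_that("tangent thickness equals R - r on annuli with no exclusions", {
  tp <- tangent_thickness_profile(annulus_seg(10, 20))
  expect_equal(nrow(tp), 100)
  expect_equal(sum(tp$excluded), 0)
  expect_true(all(abs(tp$t_px - 10) <= 0.5))
})

test_that("tangent rays on an eccentric lumen match the analytic chord oracle", {
  off <- c(0, 5)
  seg <- annulus_seg(10, 25, canvas = 120, offset = off)
  tp <- tangent_thickness_profile(seg)
  lc <- c(60, 60) + off
  ok <- which(!tp$excluded)
  # rasterization oracle: march the binary truth masks along the analytic
  # normal (radial from the lumen center) from each contact point
  vessel <- pmin(seg$wall_mask + seg$lumen_mask, 1)
  for (i in ok[seq(1, length(ok), by = 4)]) {
    p <- c(tp$row[i], tp$col[i])
    expected <- brute_ray(seg$lumen_mask, vessel, p, p - lc)$r_out
    expect_lt(abs(tp$t_px[i] - expected), 0.7)
  }
})

test_that("involuted lumens trigger the inward-pointing exclusion rule", {
  seg <- shape_seg(shape_spiked(15, depth = 22, width = 4), shape_circle(30),
                   canvas = 160)
  tp <- tangent_thickness_profile(seg)
  expect_gte(sum(tp$reason %in% "inward_pointing"), 1)
  # statistics are computed over the remaining points
  s <- summary_stats(tp$t_px)
  expect_equal(s$n_valid, sum(!tp$excluded))
  expect_true(is.finite(s$mean))
})

test_that("radial thickness matches closed forms per angle", {
  rp <- radial_thickness_profile(annulus_seg(10, 20))
  expect_true(all(abs(rp$t_px - 10) <= 0.5))
  expect_equal(nrow(rp), 360)

  # ellipse wall: per-angle rasterization oracle on the truth geometry
  seg <- shape_seg(shape_circle(8), shape_ellipse(28, 16), canvas = 120)
  rp2 <- radial_thickness_profile(seg)
  ctr <- lumen_centroid(seg$lumen_mask)
  vessel <- pmin(seg$wall_mask + seg$lumen_mask, 1)
  for (th in seq(0, 350, by = 10)) {
    o <- brute_ray(seg$lumen_mask, vessel, ctr,
                   c(sin(th * pi / 180), cos(th * pi / 180)))
    expect_lt(abs(rp2$t_px[rp2$theta == th] - (o$r_out - o$r_in)), 0.7)
  }
})

test_that("areas and ratio convert through the squared resolution", {
  wall <- matrix(0, 32, 32); wall[1:10, 1:10] <- 1      # 100 px
  lumen <- matrix(0, 32, 32); lumen[20:24, 20:29] <- 1  # 50 px
  a <- wall_lumen_areas(vessel_segmentation(wall, lumen, 0.220))
  expect_equal(a$wall_area_um2, 4.84)
  expect_equal(a$lumen_area_um2, 2.42)
  expect_equal(a$wall_lumen_ratio, 2.0)

  ann <- wall_lumen_areas(annulus_seg(10, 20))
  expect_equal(ann$wall_lumen_ratio, 3.0, tolerance = 0.05 * 3)

  empty <- vessel_segmentation(wall, matrix(0, 32, 32))
  expect_true(is.na(wall_lumen_areas(empty)$wall_lumen_ratio))
})

test_that("eccentric sectioning geometry follows the cosine rule", {
  expect_equal(eccentricity_correction(20, 20)$correction_factor, 1)
  e <- eccentricity_correction(10, 20)
  expect_equal(e$cos_theta, 0.5)
  expect_equal(e$theta_deg, 60)
  expect_lt(abs(eccentricity_correction(14.14, 20)$theta_deg - 45), 0.1)
  expect_error(eccentricity_correction(21, 20), "diameters swapped")
})

test_that("the composed report carries physical units and QC", {
  rep <- morphometry_report(annulus_seg(10, 20))
  expect_equal(rep$thickness_tangent_stats$mean, 2.20, tolerance = 0.11 / 2.20)
  expect_equal(rep$thickness_radial_stats$mean, 2.20, tolerance = 0.11 / 2.20)
  expect_equal(rep$si_stats$mean, 0.50, tolerance = 0.02 / 0.5)
  expect_equal(rep$wall_lumen_ratio, 3.0, tolerance = 0.05)
  expect_equal(rep$qc$tangent_excluded, 0)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1)
  expect_true(all(c("si_mean", "tt_mean", "rt_mean", "wall_lumen_ratio") %in% names(df)))
})

test_that("circle oracle holds across the (r, R) grid", {
  cases <- list(c(8, 12), c(8, 20), c(12, 30), c(20, 40), c(30, 60))
  for (cs in cases) {
    r <- cs[1]; R <- cs[2]
    rep <- morphometry_report(annulus_seg(r, R, um_per_px = 1))
    expect_lt(abs(rep$si_stats$mean - (1 - r / R)), 0.02)
    expect_lt(abs(rep$thickness_tangent_stats$mean - (R - r)), 0.5)
    expect_lt(abs(rep$thickness_radial_stats$mean - (R - r)), 0.5)
    expect_lt(abs(rep$thickness_tangent_stats$mean - rep$thickness_radial_stats$mean), 0.5)
  }
})

test_that("summary statistics are invariant to a 30 degree rotation", {
  base <- shape_seg(shape_ellipse(12, 7, 0), shape_ellipse(25, 18, 0), canvas = 160)
  rot <- shape_seg(shape_ellipse(12, 7, 30), shape_ellipse(25, 18, 30), canvas = 160)
  a <- morphometry_report(base, angle_step = 1)
  b <- morphometry_report(rot, angle_step = 1)
  expect_lt(abs(a$si_stats$mean - b$si_stats$mean), 0.02)
  expect_lt(abs(a$thickness_tangent_stats$mean - b$thickness_tangent_stats$mean) / 0.220, 0.5)
  expect_lt(abs(a$thickness_radial_stats$mean - b$thickness_radial_stats$mean) / 0.220, 0.5)
})

test_that("mean SI increases strictly as the lumen narrows", {
  si <- vapply(c(18, 16, 14, 12, 10, 8), function(r)
    morphometry_report(annulus_seg(r, 22))$si_stats$mean, numeric(1))
  expect_true(all(diff(si) > 0))
})

test_that("radial thickness dominates tangent thickness on eccentric elongated lumens", {
  for (off in list(c(0, 3), c(0, 5), c(3, 0))) {
    rep <- morphometry_report(shape_seg(shape_ellipse(20, 6), shape_ellipse(30, 14),
                                        canvas = 180, offset = off))
    expect_gte(rep$thickness_radial_stats$mean, rep$thickness_tangent_stats$mean)
  }
})

test_that("thickness scales linearly and areas quadratically with resolution", {
  a <- morphometry_report(annulus_seg(10, 20, um_per_px = 0.220))
  b <- morphometry_report(annulus_seg(10, 20, um_per_px = 0.440))
  expect_equal(b$thickness_tangent_stats$mean, 2 * a$thickness_tangent_stats$mean)
  expect_equal(b$thickness_radial_stats$mean, 2 * a$thickness_radial_stats$mean)
  expect_equal(b$wall_area_um2, 4 * a$wall_area_um2)
  expect_equal(b$si_stats$mean, a$si_stats$mean)
  expect_equal(b$wall_lumen_ratio, a$wall_lumen_ratio)
})

test_that("degenerate inputs fail with informative errors", {
  expect_error(lumen_centroid(matrix(0, 8, 8)), "no lumen")
  tiny <- vessel_segmentation(disk_mask(32, c(16, 16), 6) - disk_mask(32, c(16, 16), 0.9),
                              disk_mask(32, c(16, 16), 0.9))
  expect_error(tangent_thickness_profile(tiny), "contour too small")
})
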