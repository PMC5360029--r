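test_that("straight-tube centerline tracks the axis at the 0.1 mm interval", {
  surf <- tube_surface_07()
  cl <- extract_centerline(surf)
  br <- cl$branches[[1]]
  expect_lt(max(sqrt(br$points[, 2]^2 + br$points[, 3]^2)), 0.05)
  # ~50 samples over 5 mm at 0.1 mm
  expect_gt(nrow(br$points), 44)
  # declared interval within 10%
  expect_true(all(abs(diff(br$s) / cl$interval - 1) < 0.1))
  # tangents are unit vectors
  expect_equal(sqrt(rowSums(br$tangents^2)), rep(1, nrow(br$points)))
  # interiority: wall distance positive, close to the radius
  expect_true(all(br$wall_distance > 0))
  mid <- br$s > 1 & br$s < 4
  expect_true(all(abs(br$wall_distance[mid] / 0.7 - 1) < 0.15))
})

test_that("curved-tube centerline stays within a tenth of the tube radius", {
  surf <- generate_phantom_surface(torus_spec(2, 0.7, 180))
  cl <- extract_centerline(surf)
  p <- cl$branches[[1]]$points
  dev <- sqrt((sqrt(p[, 1]^2 + p[, 2]^2) - 2)^2 + p[, 3]^2)
  expect_lt(max(dev), 0.07)
})

test_that("junction phantoms yield branch polylines sharing one junction", {
  surf <- generate_phantom_surface(avf_phantom_spec(), resolution = 0.09)
  cl <- extract_centerline(surf)
  expect_gte(length(cl$branches), 3)
  expect_false(is.null(cl$junction))
  # the junction sits near the anastomosis (artery-vein crossing at origin)
  expect_lt(sqrt(sum(cl$junction^2)), 1.2)
})

test_that("cylinder area profile is flat at pi r^2", {
  surf <- tube_surface_07()
  cl <- extract_centerline(surf)
  prof <- area_profile(cl, surf)
  interior <- prof[prof$s_mm > 0.3 & prof$s_mm < 4.7, ]
  expect_true(all(abs(interior$area_mm2 / (pi * 0.49) - 1) < 0.02))
  cv <- stats::sd(interior$area_mm2) / mean(interior$area_mm2)
  expect_lt(cv, 0.02)
  # areas are recorded in both unit systems
  expect_equal(interior$area_um2, interior$area_mm2 * 1e6)
})

test_that("an oblique cut inflates the area by 1/cos(tilt)", {
  surf <- tube_surface_07()
  p0 <- c(2.5, 0, 0)
  a_perp <- avflow:::plane_section_area(surf, p0, c(1, 0, 0))
  tilt <- 30 * pi / 180
  a_tilt <- avflow:::plane_section_area(surf, p0,
                                        c(cos(tilt), sin(tilt), 0))
  expect_lt(abs(a_perp / (pi * 0.49) - 1), 0.02)
  expect_lt(abs(a_tilt / (pi * 0.49 / cos(tilt)) - 1), 0.03)
})

test_that("the bulged vein phantom peaks at the configured bulge center", {
  spec <- tube_spec(0.7, 8, bulge_amplitude = 1.4, bulge_center = 3,
                    bulge_width = 1)
  surf <- generate_phantom_surface(spec)
  cl <- extract_centerline(surf)
  prof <- area_profile(cl, surf)
  expect_lt(abs(prof$s_mm[which.max(prof$area_mm2)] - 3), 0.2)
})

test_that("segment averages handle constant and ramp profiles analytically", {
  const <- structure(
    data.frame(branch = "main", s_mm = seq(0, 6, 0.1),
               area_mm2 = 2, area_um2 = 2e6),
    class = c("area_profile", "data.frame"))
  sa <- segment_average_area(const, 1, 4)
  expect_equal(sa$mean_um2, 2e6)
  expect_equal(sa$sd_um2, 0)
  s <- seq(0, 6, 0.1)
  ramp <- structure(
    data.frame(branch = "main", s_mm = s, area_mm2 = 1 + 0.5 * s,
               area_um2 = (1 + 0.5 * s) * 1e6),
    class = c("area_profile", "data.frame"))
  sr <- segment_average_area(ramp, 1, 4)
  # mean of a sampled linear ramp over [1, 5]: (a + b)/2 = 1 + 0.5 * 3
  expect_lt(abs(sr$mean_mm2 - 2.5), 0.5 * 0.1 / 2 + 1e-9)
  expect_equal(sr$n, 41)
})

test_that("windows beyond the profile extent raise an extent error", {
  prof <- structure(
    data.frame(branch = "main", s_mm = seq(0, 2, 0.1), area_mm2 = 1,
               area_um2 = 1e6),
    class = c("area_profile", "data.frame"))
  expect_error(segment_average_area(prof, 0, 4),
               class = "avflow_extent_error")
})

test_that("the control-vein calibrated phantom reports 1.55e6 um^2", {
  r <- sqrt(1.55 / pi)
  surf <- generate_phantom_surface(tube_spec(r, 6))
  cl <- extract_centerline(surf)
  prof <- area_profile(cl, surf)
  sa <- segment_average_area(prof, 1, 4)
  expect_lt(abs(sa$mean_um2 / 1.55e6 - 1), 0.03)
})

test_that("area profiles export as CSV with the documented columns", {
  prof <- structure(
    data.frame(branch = "main", s_mm = c(0, 0.1), area_mm2 = c(1, 1),
               area_um2 = c(1e6, 1e6)),
    class = c("area_profile", "data.frame"))
  path <- tempfile(fileext = ".csv")
  write_area_profile(prof, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("s_mm", "area_um2", "branch_id"))
  unlink(path)
})
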