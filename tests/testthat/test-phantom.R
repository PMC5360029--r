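test_that("noiseless phantom image is an exact indicator of the lumen", {
  spec <- tube_spec(0.7, 5)
  img <- generate_phantom_image(spec, spacing = c(0.1, 0.1, 0.5),
                                noise_sd = 0)
  gt <- phantom_ground_truth(img)
  # lumen voxels carry the dark intensity exactly, background the bright one
  expect_true(all(img$intensities[gt$labels] == 20))
  expect_true(all(img$intensities[!gt$labels] == 100))
  # ground truth is the set of centers strictly inside the analytic boundary
  ax <- do.call(expand.grid, grid_axes(dim(gt$labels), gt$spacing, gt$origin))
  inside <- phantom_field(spec, as.matrix(ax)) > 0
  expect_identical(as.vector(gt$labels), inside)
})

test_that("seeded noise is deterministic and RNG state is restored", {
  spec <- tube_spec(0.5, 3)
  set.seed(99)
  before <- .Random.seed
  a <- generate_phantom_image(spec, noise_sd = 8, seed = 7)
  b <- generate_phantom_image(spec, noise_sd = 8, seed = 7)
  expect_identical(a$intensities, b$intensities)
  expect_identical(before, .Random.seed)
  c <- generate_phantom_image(spec, noise_sd = 8, seed = 8)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("ground-truth mask volume matches the analytic cylinder", {
  # vessel through-plane: 0.1 mm in-plane resolution, 0.5 mm slices
  img <- generate_phantom_image(tube_spec(0.7, 5, axis = "z"),
                                spacing = c(0.1, 0.1, 0.5))
  gt <- phantom_ground_truth(img)
  vol_voxels <- sum(gt$labels) * prod(gt$spacing)
  expect_lt(abs(vol_voxels / (pi * 0.7^2 * 5) - 1), 0.02)
})

test_that("a phantom that does not fit the requested extent errors", {
  expect_error(
    generate_phantom_image(tube_spec(0.7, 5), extent = c(2, 2, 2)),
    class = "avflow_sizing_error")
})

test_that("analytic tube surface is watertight with accurate volume", {
  surf <- tube_surface_07()
  expect_true(is_watertight(surf))
  expect_lt(abs(surface_enclosed_volume(surf) / (pi * 0.49 * 5) - 1), 0.01)
  expect_setequal(names(surf$patches), c("inlet", "outlet"))
})

test_that("unit bulge amplitude leaves the surface unchanged", {
  a <- generate_phantom_surface(tube_spec(0.7, 4))
  b <- generate_phantom_surface(tube_spec(0.7, 4, bulge_amplitude = 1))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
})

test_that("the 90-degree junction carries exactly four labeled openings", {
  surf <- generate_phantom_surface(avf_phantom_spec(anastomosis_angle = 90),
                                   resolution = 0.09)
  expect_true(is_watertight(surf))
  expect_setequal(names(surf$patches),
                  c("inlet", "outlet_artery", "outlet_vein", "outlet_branch"))
  expect_true(all(lengths(surf$patches) > 0))
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(tube_spec(-1, 5))
  expect_error(avf_phantom_spec(anastomosis_angle = 0))
  expect_error(avf_phantom_spec(vein_bulge_amplitude = 0.5))
})
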