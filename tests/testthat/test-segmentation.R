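test_that("noiseless segmentation recovers the ground truth exactly", {
  img <- generate_phantom_image(tube_spec(0.7, 5),
                                spacing = c(0.1, 0.1, 0.5), noise_sd = 0)
  gt <- phantom_ground_truth(img)
  seed_vox <- round(dim(img$intensities) / 2)
  mask <- segment_lumen(img, seed_vox, threshold = 60)
  expect_identical(mask$labels, gt$labels)
})

test_that("well-separated noisy classes segment with Dice >= 0.95", {
  # class means 20 / 100 with sd 10: < 0.1% class overlap at threshold 60
  img <- generate_phantom_image(tube_spec(0.7, 5),
                                spacing = c(0.1, 0.1, 0.5),
                                noise_sd = 10, seed = 42)
  gt <- phantom_ground_truth(img)
  mask <- segment_lumen(img, round(dim(img$intensities) / 2), threshold = 60)
  expect_gte(dice_overlap(mask, gt), 0.95)
})

test_that("threshold below the lumen intensity yields an empty-segmentation error", {
  img <- generate_phantom_image(tube_spec(0.7, 5), noise_sd = 0)
  expect_error(segment_lumen(img, round(dim(img$intensities) / 2), 5),
               class = "avflow_empty_segmentation")
})

test_that("seeds outside the grid are rejected", {
  img <- generate_phantom_image(tube_spec(0.5, 3), noise_sd = 0)
  expect_error(segment_lumen(img, c(-1, 1, 1), 60),
               class = "avflow_seed_error")
})

test_that("the mask is a single 26-connected component containing the seed", {
  # two disjoint dark blobs: only the seeded one must be kept
  arr <- array(100, c(12, 12, 12))
  arr[2:4, 2:4, 2:4] <- 10
  arr[9:11, 9:11, 9:11] <- 10
  img <- image_stack(arr, c(0.1, 0.1, 0.1))
  mask <- segment_lumen(img, c(3, 3, 3), 50)
  expect_equal(sum(mask$labels), 27)
  expect_true(all(which(mask$labels, arr.ind = TRUE) <= 4))
})

test_that("the distance transform is exact on a simple slab", {
  m <- array(FALSE, c(9, 5, 5))
  m[3:7, , ] <- TRUE
  d <- distance_transform(m, c(2, 1, 1))
  expect_equal(d[5, 3, 3], 6)  # three voxels to the nearest background center
  expect_equal(d[3, 3, 3], 2)
  expect_true(all(d[m] > 0) && all(d[!m] == 0))
})
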