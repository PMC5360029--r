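test_that("cylinder mask reconstruction recovers the analytic volume", {
  mk <- cylinder_mask(r = 0.7, L = 5, h = 0.1, hz = 0.1)
  surf <- extract_surface(mk)
  expect_true(is_watertight(surf))
  expect_lt(abs(surface_enclosed_volume(surf) / (pi * 0.49 * 5) - 1), 0.03)
})

test_that("sphere mask reconstruction recovers the analytic area", {
  h <- 0.1
  ax <- lapply(1:3, function(i) seq(-1.5, 1.5, by = h))
  g <- expand.grid(ax[[1]], ax[[2]], ax[[3]])
  m <- array(sqrt(rowSums(g^2)) < 1, lengths(ax))
  surf <- extract_surface(lumen_mask(m, rep(h, 3), rep(-1.5, 3)))
  expect_lt(abs(surface_area(surf) / (4 * pi) - 1), 0.05)
  expect_lt(abs(surface_enclosed_volume(surf) / (4 / 3 * pi) - 1), 0.03)
  expect_equal(euler_characteristic(surf), 2)
})

test_that("a single voxel yields a small closed surface", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  surf <- extract_surface(lumen_mask(m, rep(0.1, 3)))
  v <- surface_enclosed_volume(surf)
  expect_gt(v, 0)
  expect_lte(v, 0.1^3)
  expect_true(is_watertight(surf))
})

test_that("masks touching the grid boundary are rejected with advice to pad", {
  m <- array(TRUE, c(4, 4, 4))
  expect_error(extract_surface(lumen_mask(m, rep(0.1, 3))),
               class = "avflow_open_surface_error")
  padded <- pad_mask(lumen_mask(m, rep(0.1, 3)), 2)
  expect_silent(s <- extract_surface(padded))
  expect_true(is_watertight(s))
})

test_that("reconstruction error obeys a first-order envelope in voxel size", {
  # the pointwise error oscillates with the lattice phase (mask quantization),
  # so convergence is asserted as a linear envelope |err| <= C h / r that
  # halves with the spacing across a 3-level sweep
  hs <- c(0.2, 0.1, 0.05)
  vol_err <- vapply(hs, function(h) {
    mk <- cylinder_mask(r = 0.7, L = 3, h = h, hz = h)
    abs(surface_enclosed_volume(extract_surface(mk)) / (pi * 0.49 * 3) - 1)
  }, numeric(1))
  expect_true(all(vol_err <= 0.5 * hs / 0.7))
})

test_that("smoothing is identity at 0 iterations and volume-preserving", {
  mk <- cylinder_mask(r = 0.7, L = 4, h = 0.1, hz = 0.1)
  raw <- extract_surface(mk, relax_iterations = 0)
  expect_identical(smooth_surface(raw, 0), raw)
  sm <- smooth_surface(raw, 20)
  v0 <- surface_enclosed_volume(raw)
  expect_lt(abs(surface_enclosed_volume(sm) / v0 - 1), 0.02)
  expect_identical(euler_characteristic(sm), euler_characteristic(raw))
  # staircase ripple decreases: max radial deviation from the true cylinder
  radial_dev <- function(s) {
    v <- s$vertices
    lateral <- v[, 3] > 0.5 & v[, 3] < 3.5
    max(abs(sqrt((v[lateral, 1] - 0.033)^2 + (v[lateral, 2] - 0.071)^2) -
              0.7))
  }
  expect_lt(radial_dev(sm), radial_dev(raw))
})

test_that("smoothing refuses non-watertight input", {
  open_surf <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            matrix(c(1L, 2L, 3L), 1))
  expect_error(smooth_surface(open_surf, 5), class = "avflow_topology_error")
})

test_that("STL round trip preserves the mesh in both dialects", {
  surf <- generate_phantom_surface(tube_spec(0.5, 2))
  for (binary in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_stl(surf, path, binary = binary)
    back <- read_stl(path)
    expect_equal(nrow(back$triangles), nrow(surf$triangles))
    tol <- if (binary) 1e-6 else 1e-8  # binary STL is float32
    expect_lt(abs(surface_enclosed_volume(back) -
                    surface_enclosed_volume(surf)), tol)
    unlink(path)
  }
  # patch sidecar round trip
  pth <- tempfile(fileext = ".json")
  write_patches(surf$patches, pth)
  expect_identical(lapply(read_patches(pth), as.integer),
                   lapply(surf$patches, as.integer))
  unlink(pth)
})
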