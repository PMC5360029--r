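test_that("voxel meshing recovers the analytic tube volume", {
  mesh <- tube_mesh_05()
  expect_lt(abs(mesh_total_volume(mesh) / (pi * 0.25e-6 * 5e-3) - 1), 0.02)
  expect_equal(mesh$quality$edge_mean, mesh$h)
})

test_that("halving the edge length scales cells by roughly 8", {
  surf <- tube_surface_07()
  m1 <- mesh_volume(surf, 0.2)
  m2 <- mesh_volume(surf, 0.1)
  ratio <- m2$quality$n_cells / m1$quality$n_cells
  expect_gte(ratio, 4)
  expect_lte(ratio, 16)
})

test_that("boundary faces partition exactly into openings plus wall", {
  mesh <- tube_mesh_05()
  expect_setequal(unique(mesh$faces$patch), c("inlet", "outlet", "wall"))
  # each (cell, dir) boundary face appears exactly once
  key <- paste(mesh$faces$cell, mesh$faces$dir)
  expect_false(any(duplicated(key)))
  # faces are boundary faces: the neighbor slot must be empty
  expect_true(all(mesh$nb[cbind(mesh$faces$cell, mesh$faces$dir)] == 0L))
  # every non-boundary direction has a fluid neighbor: counts must add to 6K
  expect_equal(sum(mesh$nb > 0) + length(mesh$faces$cell),
               6 * mesh$quality$n_cells)
})

test_that("surfaces without labeled openings are rejected", {
  mk <- cylinder_mask(r = 0.5, L = 3, h = 0.1, hz = 0.1)
  unlabeled <- extract_surface(mk)
  expect_error(mesh_volume(unlabeled, 0.1), class = "avflow_patch_error")
})

test_that("junction meshes label every opening with faces", {
  surf <- generate_phantom_surface(avf_phantom_spec(), resolution = 0.09)
  mesh <- mesh_volume(surf, 0.16)
  tab <- table(mesh$faces$patch)
  expect_true(all(c("inlet", "outlet_artery", "outlet_vein",
                    "outlet_branch", "wall") %in% names(tab)))
  expect_true(all(tab > 0))
})

test_that("VTK export writes a parseable unstructured grid", {
  mesh <- mesh_volume(tube_surface_07(), 0.25)
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(mesh, path,
                 cell_data = list(id = seq_len(mesh$quality$n_cells)))
  txt <- readLines(path)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", txt)))
  np <- as.integer(sub("POINTS (\\d+) double", "\\1",
                       grep("^POINTS", txt, value = TRUE)))
  expect_gt(np, 0)
  ct <- grep("^CELL_TYPES", txt)
  expect_true(all(txt[(ct + 1):(ct + mesh$quality$n_cells)] == "11"))
  expect_true(file.exists(paste0(path, ".patches.csv")))
  unlink(c(path, paste0(path, ".patches.csv")))
})
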