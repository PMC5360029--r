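# Labeled volume meshes.
#
# The volume discretization is the hexahedral-voxel dialect: the watertight
# lumen surface is rasterized onto a uniform cubic grid and every cell whose
# center lies inside becomes a fluid cell. Boundary faces are partitioned into
# the opening patches declared on the surface (inlet, outlets) plus `wall`.
# Mesh geometry is stored in SI meters; surfaces remain in mm.

#' Build a labeled voxel volume mesh from a watertight surface
#'
#' @param surface a watertight `surface_mesh` (mm) whose `patches` component
#'   labels every opening (cap) with a patch name.
#' @param target_edge_length requested cell edge length (mm); voxel cells are
#'   cubes with exactly this edge.
#' @return An object of class `volume_mesh` with components
#'   \describe{
#'     \item{h}{cell edge (m)}
#'     \item{dims, origin}{grid shape and center of cell (1,1,1) (m)}
#'     \item{cells}{k x 3 integer voxel indices of fluid cells}
#'     \item{centers}{k x 3 cell centers (m)}
#'     \item{nb}{k x 6 fluid neighbor cell ids (0 at boundary faces), columns
#'       xm, xp, ym, yp, zm, zp}
#'     \item{faces}{boundary face table: cell, dir (1..6), patch, center (m),
#'       area (m^2)}
#'     \item{patch_info}{per-opening centroid, outward normal, radius}
#'     \item{quality}{edge length stats and cell count; dialect metadata}
#'   }
#' @export
mesh_volume <- function(surface, target_edge_length) {
  stopifnot(inherits(surface, "surface_mesh"), target_edge_length > 0)
  if (is.null(surface$patches) || length(surface$patches) == 0) {
    abort("surface has no labeled opening patches", "avflow_patch_error")
  }
  if (!is_watertight(surface)) {
    abort("volume meshing requires a watertight surface",
          "avflow_topology_error")
  }
  h <- target_edge_length
  vox <- voxelize_surface(surface, h)
  if (sum(vox$mask) == 0) {
    abort("no cell centers fall inside the surface; reduce target edge length",
          "avflow_sizing_error")
  }
  mask <- largest_component_6(vox$mask)
  dims <- dim(mask)
  cid <- array(0L, dims)
  k <- sum(mask)
  cid[mask] <- seq_len(k)
  idx <- which(mask, arr.ind = TRUE)
  centers_mm <- sweep((idx - 1) * h, 2, vox$origin, "+")
  nb <- matrix(0L, k, 6)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (d in 1:6) {
    ngh <- sweep(idx, 2, off[d, ], "+")
    ok <- ngh[, 1] >= 1 & ngh[, 1] <= dims[1] &
      ngh[, 2] >= 1 & ngh[, 2] <= dims[2] &
      ngh[, 3] >= 1 & ngh[, 3] <= dims[3]
    nb[ok, d] <- cid[ngh[ok, , drop = FALSE]]
  }
  # boundary faces
  bcell <- integer(0); bdir <- integer(0)
  for (d in 1:6) {
    open <- which(nb[, d] == 0L)
    bcell <- c(bcell, open)
    bdir <- c(bdir, rep.int(d, length(open)))
  }
  fc_mm <- centers_mm[bcell, , drop = FALSE] +
    (h / 2) * off[bdir, , drop = FALSE]
  patch <- assign_patches(surface, fc_mm, bdir, h)
  for (nm in names(surface$patches)) {
    if (!any(patch == nm)) {
      abort(sprintf("opening patch '%s' received no boundary faces", nm),
            "avflow_patch_error")
    }
  }
  patch_info <- lapply(names(surface$patches), function(nm) {
    tri <- surface$patches[[nm]]
    cent <- triangle_centroids(surface)[tri, , drop = FALSE]
    ar <- triangle_areas(surface)[tri]
    p1 <- surface$vertices[surface$triangles[tri, 1], , drop = FALSE]
    p2 <- surface$vertices[surface$triangles[tri, 2], , drop = FALSE]
    p3 <- surface$vertices[surface$triangles[tri, 3], , drop = FALSE]
    n <- vcross(p2 - p1, p3 - p1)
    nsum <- colSums(n) / 2
    centroid <- colSums(cent * ar) / sum(ar)
    faces_here <- which(patch == nm)
    radius <- if (length(faces_here)) {
      max(sqrt(rowSums(sweep(fc_mm[faces_here, , drop = FALSE], 2,
                             centroid)^2))) + h / 2
    } else max(sqrt(rowSums(sweep(cent, 2, centroid)^2)))
    list(name = nm, centroid = mm_to_m(centroid),
         normal = normalize(nsum), area = sum(ar) * 1e-6,
         radius = mm_to_m(radius))
  })
  names(patch_info) <- names(surface$patches)
  structure(list(
    h = mm_to_m(h), dims = dims, origin = mm_to_m(vox$origin),
    cells = idx, cid = cid, centers = mm_to_m(centers_mm), nb = nb,
    faces = list(cell = bcell, dir = bdir, patch = patch,
                 center = mm_to_m(fc_mm),
                 area = rep(mm_to_m(h)^2, length(bcell))),
    patch_info = patch_info,
    quality = list(dialect = "hexahedral-voxel", n_cells = k,
                   edge_mean = mm_to_m(h), edge_min = mm_to_m(h),
                   edge_max = mm_to_m(h),
                   cell_volume = mm_to_m(h)^3)),
    class = "volume_mesh")
}

#' @method print volume_mesh
#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf(
    "volume_mesh (%s): %d cells, edge %.3g mm, patches: %s\n",
    x$quality$dialect, x$quality$n_cells, m_to_mm(x$h),
    paste(unique(x$faces$patch), collapse = ", ")))
  invisible(x)
}

#' Total fluid volume of a volume mesh
#' @param mesh a `volume_mesh`.
#' @return Volume in m^3.
#' @export
mesh_total_volume <- function(mesh) {
  mesh$quality$n_cells * mesh$quality$cell_volume
}

# Rasterize a closed surface: cells whose center is inside (ray parity along
# z). Returns mask + grid origin (mm, center of cell (1,1,1)).
voxelize_surface <- function(surface, h) {
  v <- surface$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  # tiny irrational offset avoids rays through triangle edges
  origin <- lo + h / 2 + h * 1e-4 * c(sqrt(2) - 1, sqrt(3) - 1, sqrt(5) - 2)
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / h + 0.5)))
  xs <- origin[1] + (seq_len(dims[1]) - 1) * h
  ys <- origin[2] + (seq_len(dims[2]) - 1) * h
  tri <- surface$triangles
  p1 <- v[tri[, 1], , drop = FALSE]
  p2 <- v[tri[, 2], , drop = FALSE]
  p3 <- v[tri[, 3], , drop = FALSE]
  col_id <- integer(0); zc <- numeric(0)
  acc_col <- vector("list", nrow(tri)); acc_z <- vector("list", nrow(tri))
  for (t in seq_len(nrow(tri))) {
    a <- p1[t, ]; b <- p2[t, ]; c_ <- p3[t, ]
    ix <- which(xs >= min(a[1], b[1], c_[1]) & xs <= max(a[1], b[1], c_[1]))
    iy <- which(ys >= min(a[2], b[2], c_[2]) & ys <= max(a[2], b[2], c_[2]))
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    d <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(d) < .Machine$double.eps * 100) next
    w1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / d
    w2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / d
    w3 <- 1 - w1 - w2
    ins <- w1 > 0 & w2 > 0 & w3 > 0
    if (!any(ins)) next
    z <- w1[ins] * a[3] + w2[ins] * b[3] + w3[ins] * c_[3]
    cols <- (rep(ix, times = length(iy)) - 1L)[ins] +
      dims[1] * (rep(iy, each = length(ix)) - 1L)[ins]
    acc_col[[t]] <- cols
    acc_z[[t]] <- z
  }
  col_id <- unlist(acc_col); zc <- unlist(acc_z)
  mask <- array(FALSE, dims)
  if (length(col_id)) {
    ord <- order(col_id, zc)
    col_id <- col_id[ord]; zc <- zc[ord]
    n_per <- table(col_id)
    starts <- c(1, cumsum(as.integer(n_per)) + 1)
    cols <- as.integer(names(n_per))
    z0 <- origin[3]
    for (ci in seq_along(cols)) {
      z_here <- zc[starts[ci]:(starts[ci + 1] - 1)]
      m <- length(z_here)
      if (m < 2) next
      for (q in seq(1, m - 1, by = 2)) {
        klo <- ceiling((z_here[q] - z0) / h)
        khi <- floor((z_here[q + 1] - z0) / h)
        if (khi < klo) next
        klo <- max(klo, 0); khi <- min(khi, dims[3] - 1)
        if (khi < klo) next
        i <- cols[ci] %% dims[1] + 1L
        j <- cols[ci] %/% dims[1] + 1L
        mask[i, j, (klo + 1):(khi + 1)] <- TRUE
      }
    }
  }
  list(mask = mask, origin = origin)
}

# largest 6-connected component of a logical array
largest_component_6 <- function(mask) {
  dims <- dim(mask)
  lin <- which(mask)
  if (!length(lin)) return(mask)
  id <- array(0L, dims)
  id[lin] <- seq_along(lin)
  edges <- list()
  arr <- which(mask, arr.ind = TRUE)
  for (d in 1:3) {
    ngh <- arr
    ngh[, d] <- ngh[, d] + 1L
    ok <- ngh[, d] <= dims[d]
    a <- id[arr[ok, , drop = FALSE]]
    b <- id[ngh[ok, , drop = FALSE]]
    sel <- b > 0
    edges[[d]] <- cbind(a[sel], b[sel])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  out <- array(FALSE, dims)
  out[lin[keep]] <- TRUE
  out
}

# Assign boundary faces to opening patches by proximity to the cap planes;
# everything else is wall.
assign_patches <- function(surface, fc_mm, bdir, h) {
  patch <- rep("wall", length(bdir))
  cent_all <- triangle_centroids(surface)
  ar_all <- triangle_areas(surface)
  for (nm in names(surface$patches)) {
    tri <- surface$patches[[nm]]
    ar <- ar_all[tri]
    centroid <- colSums(cent_all[tri, , drop = FALSE] * ar) / sum(ar)
    p1 <- surface$vertices[surface$triangles[tri, 1], , drop = FALSE]
    p2 <- surface$vertices[surface$triangles[tri, 2], , drop = FALSE]
    p3 <- surface$vertices[surface$triangles[tri, 3], , drop = FALSE]
    nrm <- normalize(colSums(vcross(p2 - p1, p3 - p1)))
    vids <- unique(as.vector(surface$triangles[tri, ]))
    rmax <- max(sqrt(rowSums(sweep(surface$vertices[vids, , drop = FALSE],
                                   2, centroid)^2)))
    rel <- sweep(fc_mm, 2, centroid)
    dn <- abs(rel %*% nrm)
    radial <- sqrt(pmax(rowSums(rel^2) - dn^2, 0))
    sel <- dn < 0.72 * h & radial < rmax + h & patch == "wall"
    patch[sel] <- nm
  }
  patch
}

#' Export a volume mesh (and optional cell data) as legacy ASCII VTK
#'
#' Unstructured grid of VTK_VOXEL cells; boundary patch labels are written as
#' a companion CSV (`<path>.patches.csv`) of face cell/direction/patch rows.
#'
#' @param mesh a `volume_mesh`.
#' @param path output `.vtk` file.
#' @param cell_data named list of per-cell numeric vectors (or 3-column
#'   matrices for vectors).
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = list()) {
  k <- mesh$quality$n_cells
  idx <- mesh$cells
  # node ids: corner (i,j,k) of cell = grid node index
  nd <- mesh$dims + 1L
  corner <- function(di, dj, dk) {
    (idx[, 1] - 1 + di) + nd[1] * (idx[, 2] - 1 + dj) +
      nd[1] * nd[2] * (idx[, 3] - 1 + dk)
  }
  corners <- cbind(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0),
                   corner(1, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
                   corner(0, 1, 1), corner(1, 1, 1))
  un <- sort(unique(as.vector(corners)))
  remap <- match(corners, un)
  dim(remap) <- dim(corners)
  i <- un %% nd[1]; j <- (un %/% nd[1]) %% nd[2]; kk <- un %/% (nd[1] * nd[2])
  pts <- cbind(mesh$origin[1] + (i - 0.5) * mesh$h,
               mesh$origin[2] + (j - 0.5) * mesh$h,
               mesh$origin[3] + (kk - 0.5) * mesh$h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "avflow volume mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("CELLS %d %d", k, 9 * k), con)
  writeLines(paste(8, remap[, 1] - 1, remap[, 2] - 1, remap[, 3] - 1,
                   remap[, 4] - 1, remap[, 5] - 1, remap[, 6] - 1,
                   remap[, 7] - 1, remap[, 8] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", k), con)
  writeLines(rep("11", k), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", k), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  utils::write.csv(
    data.frame(cell = mesh$faces$cell, dir = mesh$faces$dir,
               patch = mesh$faces$patch),
    paste0(path, ".patches.csv"), row.names = FALSE)
  invisible(path)
}
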