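# Triangulated lumen surfaces.
#
# Surfaces are produced by a marching-tetrahedra triangulation (each grid cube
# split into the six Kuhn tetrahedra, which is conforming across cubes, hence
# watertight by construction) of either the phantom's implicit level function
# or the signed distance field of a segmentation mask. Coordinates in mm.

#' Construct a surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of vertex indices (1-based),
#'   consistently oriented with outward normals.
#' @param patches optional named list mapping patch names (e.g. `inlet`) to
#'   triangle indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, patches = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  structure(list(vertices = vertices, triangles = triangles,
                 patches = patches),
            class = "surface_mesh")
}

#' @method print surface_mesh
#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles", nrow(x$vertices),
              nrow(x$triangles)))
  if (!is.null(x$patches)) {
    cat(sprintf(", patches: %s", paste(names(x$patches), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# -- marching tetrahedra ------------------------------------------------------

# Kuhn decomposition of the unit cube (corner codes c = x + 2y + 4z) into six
# tetrahedra sharing the main diagonal 0-7; conforming across neighbor cubes.
KUHN_TETS <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

#' Triangulate an isosurface of a gridded scalar field
#'
#' Marching tetrahedra on a regular (possibly anisotropic) grid of node
#' values. The returned surface is closed and consistently oriented with
#' outward normals (pointing from values above `level` to values below).
#'
#' @param vals 3D numeric array of node values.
#' @param axes list of three coordinate vectors (mm), one per axis.
#' @param level iso level.
#' @return A `surface_mesh` (possibly with zero triangles if no crossing).
#' @export
marching_tetrahedra <- function(vals, axes, level = 0) {
  dims <- dim(vals)
  stopifnot(length(dims) == 3,
            all(lengths(axes) == dims))
  v <- as.numeric(vals)
  scale <- max(abs(v[is.finite(v)]), 1)
  v[which(v == level)] <- level + 1e-9 * scale
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # linear index of node (i,j,k): i + (j-1)nx + (k-1)nxny
  corner_off <- integer(8)
  for (c in 0:7) {
    corner_off[c + 1] <- (c %% 2) + ((c %/% 2) %% 2) * nx + (c %/% 4) * nx * ny
  }
  # active cubes: sign change among the 8 corners
  ci <- seq_len(nx - 1); cj <- seq_len(ny - 1); ck <- seq_len(nz - 1)
  base <- outer(outer(ci, (cj - 1) * nx, "+"), (ck - 1) * nx * ny, "+")
  base <- as.integer(base)
  inside0 <- v > level  # NA nodes (undefined field) suppress their cubes
  n_in <- integer(length(base))
  for (c in 1:8) n_in <- n_in + inside0[base + corner_off[c]]
  base <- base[which(n_in > 0 & n_in < 8)]
  if (length(base) == 0) {
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  }

  ea <- eb <- list(); anchor_in <- anchor_out <- list(); out_i <- 1L
  emit <- function(gA1, gB1, gA2, gB2, gA3, gB3, cin, cout) {
    # one triangle batch: vertex k lies on edge (gAk, gBk); cin/cout are
    # matrices of inside/outside tet-node indices for orientation
    ea[[out_i]] <<- cbind(gA1, gA2, gA3)
    eb[[out_i]] <<- cbind(gB1, gB2, gB3)
    anchor_in[[out_i]] <<- cin
    anchor_out[[out_i]] <<- cout
    out_i <<- out_i + 1L
  }

  for (t in seq_len(nrow(KUHN_TETS))) {
    g <- sapply(KUHN_TETS[t, ] + 1L, function(c) base + corner_off[c])
    g <- matrix(g, ncol = 4)
    ins <- matrix(inside0[g], ncol = 4)
    code <- ins %*% c(1L, 2L, 4L, 8L)
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (length(sel) == 0) next
      I <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0)
      O <- setdiff(1:4, I)
      gs <- g[sel, , drop = FALSE]
      if (length(I) == 1) {
        a <- gs[, I]
        emit(a, gs[, O[1]], a, gs[, O[2]], a, gs[, O[3]],
             cbind(a), gs[, O, drop = FALSE])
      } else if (length(I) == 3) {
        d <- gs[, O]
        emit(d, gs[, I[1]], d, gs[, I[2]], d, gs[, I[3]],
             gs[, I, drop = FALSE], cbind(d))
      } else { # two in, two out: quad -> two triangles
        a <- gs[, I[1]]; b <- gs[, I[2]]
        c_ <- gs[, O[1]]; d_ <- gs[, O[2]]
        cin <- cbind(a, b); cout <- cbind(c_, d_)
        emit(a, c_, a, d_, b, d_, cin, cout)
        emit(a, c_, b, d_, b, c_, cin, cout)
      }
    }
  }
  EA <- do.call(rbind, ea); EB <- do.call(rbind, eb)
  ntri <- nrow(EA)
  # canonical edge keys -> welded vertices
  lo <- pmin(EA, EB); hi <- pmax(EA, EB)
  key <- (lo - 1) * (as.double(nx) * ny * nz) + hi
  ukey <- sort(unique(as.vector(key)))
  vid <- matrix(match(key, ukey), ncol = 3)
  ulo <- (ukey - 1) %/% (as.double(nx) * ny * nz) + 1
  uhi <- ukey - (ulo - 1) * (as.double(nx) * ny * nz)
  tfrac <- (level - v[ulo]) / (v[uhi] - v[ulo])
  Plo <- node_coords(ulo, dims, axes)
  Phi <- node_coords(uhi, dims, axes)
  verts <- Plo + tfrac * (Phi - Plo)
  # orientation: outward = from inside-anchor centroid to outside-anchor
  AIN <- do.call(rbind, lapply(anchor_in, function(m) {
    cbind(rowMeans(matrix(node_coords(as.vector(m), dims, axes)[, 1],
                          nrow = nrow(m))),
          rowMeans(matrix(node_coords(as.vector(m), dims, axes)[, 2],
                          nrow = nrow(m))),
          rowMeans(matrix(node_coords(as.vector(m), dims, axes)[, 3],
                          nrow = nrow(m))))
  }))
  AOUT <- do.call(rbind, lapply(anchor_out, function(m) {
    cbind(rowMeans(matrix(node_coords(as.vector(m), dims, axes)[, 1],
                          nrow = nrow(m))),
          rowMeans(matrix(node_coords(as.vector(m), dims, axes)[, 2],
                          nrow = nrow(m))),
          rowMeans(matrix(node_coords(as.vector(m), dims, axes)[, 3],
                          nrow = nrow(m))))
  }))
  p1 <- verts[vid[, 1], , drop = FALSE]
  p2 <- verts[vid[, 2], , drop = FALSE]
  p3 <- verts[vid[, 3], , drop = FALSE]
  nrm <- vcross(p2 - p1, p3 - p1)
  w <- AOUT - AIN
  flip <- rowSums(nrm * w) < 0
  tri <- vid
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  stopifnot(ntri == nrow(tri))
  # crossings that land (numerically) on a shared grid node produce coincident
  # vertices under distinct edge keys; weld them by position and drop the
  # collapsed zero-area triangles so the mesh is a clean closed manifold
  tol <- 1e-7 * max(diff(range(axes[[1]])), diff(range(axes[[2]])),
                    diff(range(axes[[3]])))
  pos_key <- paste(round(verts[, 1] / tol), round(verts[, 2] / tol),
                   round(verts[, 3] / tol))
  new_id <- match(pos_key, pos_key)  # first occurrence wins
  tri <- matrix(new_id[tri], ncol = 3)
  keep <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  tri <- tri[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  tri <- matrix(match(tri, used), ncol = 3)
  surface_mesh(verts[used, , drop = FALSE], tri)
}

node_coords <- function(lin, dims, axes) {
  lin0 <- lin - 1
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(axes[[1]][i + 1], axes[[2]][j + 1], axes[[3]][k + 1])
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# -- surface measures and checks ---------------------------------------------

#' Enclosed volume of a closed oriented surface
#'
#' Divergence-theorem volume; positive for outward orientation.
#' @param surface a `surface_mesh`.
#' @return Volume in mm^3.
#' @export
surface_enclosed_volume <- function(surface) {
  p1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  p2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  p3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  sum(rowSums(p1 * vcross(p2, p3))) / 6
}

#' Total area of a triangulated surface
#' @param surface a `surface_mesh`.
#' @param triangles optional triangle index subset.
#' @return Area in mm^2.
#' @export
surface_area <- function(surface, triangles = NULL) {
  tri <- surface$triangles
  if (!is.null(triangles)) tri <- tri[triangles, , drop = FALSE]
  p1 <- surface$vertices[tri[, 1], , drop = FALSE]
  p2 <- surface$vertices[tri[, 2], , drop = FALSE]
  p3 <- surface$vertices[tri[, 3], , drop = FALSE]
  sum(sqrt(rowSums(vcross(p2 - p1, p3 - p1)^2))) / 2
}

triangle_centroids <- function(surface) {
  (surface$vertices[surface$triangles[, 1], , drop = FALSE] +
     surface$vertices[surface$triangles[, 2], , drop = FALSE] +
     surface$vertices[surface$triangles[, 3], , drop = FALSE]) / 3
}

triangle_areas <- function(surface) {
  p1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  p2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  p3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  sqrt(rowSums(vcross(p2 - p1, p3 - p1)^2)) / 2
}

#' Check that a surface is watertight and consistently oriented
#'
#' Every undirected edge must be shared by exactly two triangles and appear
#' once in each direction.
#' @param surface a `surface_mesh`.
#' @return Logical.
#' @export
is_watertight <- function(surface) {
  tri <- surface$triangles
  if (nrow(tri) == 0) return(FALSE)
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  nv <- nrow(surface$vertices)
  dir_key <- (e[, 1] - 1) * as.double(nv) + e[, 2]
  und_key <- (pmin(e[, 1], e[, 2]) - 1) * as.double(nv) + pmax(e[, 1], e[, 2])
  if (anyDuplicated(dir_key) > 0) return(FALSE)
  all(table(und_key) == 2)
}

#' Euler characteristic V - E + F of a surface mesh
#' @param surface a `surface_mesh`.
#' @return Integer.
#' @export
euler_characteristic <- function(surface) {
  tri <- surface$triangles
  nv <- length(unique(as.vector(tri)))
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ne <- length(unique((pmin(e[, 1], e[, 2]) - 1) *
                        as.double(nrow(surface$vertices)) +
                        pmax(e[, 1], e[, 2])))
  nv - ne + nrow(tri)
}

# -- extraction from masks ----------------------------------------------------

#' Reconstruct a closed lumen surface from a segmentation mask
#'
#' Marching-tetrahedra isosurface of the mask at the 0.5 level. To place
#' surface vertices with sub-voxel accuracy the binary mask is represented by
#' its signed Euclidean distance field before triangulation, whose zero level
#' coincides with the 0.5 level of the indicator (midway between adjacent
#' inside/outside voxel centers). Output in physical mm, honoring anisotropic
#' spacing.
#'
#' @param mask a [lumen_mask()], not touching the grid boundary (see
#'   [pad_mask()]).
#' @param relax_iterations passes of low-shrinkage (Taubin) vertex relaxation
#'   applied to remove the voxel-lattice ripple of the raw triangulation;
#'   0 returns the raw staircase-like isosurface. The relaxation changes
#'   enclosed volume by well under 1 percent.
#' @return A `surface_mesh`.
#' @export
extract_surface <- function(mask, relax_iterations = 20) {
  stopifnot(inherits(mask, "lumen_mask"))
  if (mask_touches_boundary(mask$labels)) {
    abort("mask touches the grid boundary; pad the mask first (pad_mask)",
          "avflow_open_surface_error")
  }
  phi <- signed_distance(mask$labels, mask$spacing)
  ax <- grid_axes(dim(mask$labels), mask$spacing, mask$origin)
  surf <- marching_tetrahedra(phi, ax, level = 0)
  if (relax_iterations > 0 && nrow(surf$triangles) > 0) {
    surf <- suppressWarnings(smooth_surface(surf, relax_iterations))
  }
  surf
}

# -- smoothing ----------------------------------------------------------------

#' Smooth a surface with low shrinkage
#'
#' Two-step Taubin smoothing (a positive Laplacian step followed by a
#' slightly larger negative step), which reduces staircase artifacts while
#' keeping the enclosed volume within about 2 percent. Mesh topology is
#' unchanged.
#'
#' @param surface a watertight `surface_mesh`.
#' @param iterations number of lambda/mu passes (0 returns the input).
#' @param relaxation positive step size lambda in (0, 1); the negative step is
#'   `-relaxation / (1 - 0.1 * relaxation)`.
#' @return The smoothed `surface_mesh` (patches preserved).
#' @export
smooth_surface <- function(surface, iterations = 10, relaxation = 0.5) {
  stopifnot(inherits(surface, "surface_mesh"), iterations >= 0,
            relaxation > 0, relaxation < 1)
  if (!is_watertight(surface)) {
    abort("smoothing requires a watertight surface", "avflow_topology_error")
  }
  if (iterations == 0) return(surface)
  lambda <- relaxation
  mu <- -relaxation / (1 - 0.1 * relaxation)
  v0 <- surface_enclosed_volume(surface)
  tri <- surface$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  x <- surface$vertices
  deg <- tabulate(e[, 1], nbins = nrow(x))
  lap <- function(x) {
    nbmean <- cbind(
      rowsum(x[e[, 2], 1], e[, 1], reorder = TRUE),
      rowsum(x[e[, 2], 2], e[, 1], reorder = TRUE),
      rowsum(x[e[, 2], 3], e[, 1], reorder = TRUE)) / deg
    nbmean - x
  }
  for (it in seq_len(iterations)) {
    x <- x + lambda * lap(x)
    x <- x + mu * lap(x)
  }
  out <- surface_mesh(x, tri, surface$patches)
  drift <- abs(surface_enclosed_volume(out) - v0) / abs(v0)
  if (drift > 0.02) {
    warning(sprintf("smoothing changed enclosed volume by %.1f%%",
                    100 * drift))
  }
  out
}

# -- STL and patch sidecar I/O -----------------------------------------------

#' Write a surface mesh as STL
#'
#' @param surface a `surface_mesh`.
#' @param path output file.
#' @param binary write binary STL (default ASCII).
#' @param name solid name for ASCII output.
#' @export
write_stl <- function(surface, path, binary = FALSE, name = "avflow") {
  tri <- surface$triangles
  p1 <- surface$vertices[tri[, 1], , drop = FALSE]
  p2 <- surface$vertices[tri[, 2], , drop = FALSE]
  p3 <- surface$vertices[tri[, 3], , drop = FALSE]
  n <- vcross(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
    dat <- t(cbind(n, p1, p2, p3))
    for (i in seq_len(nrow(tri))) {
      writeBin(dat[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    body <- sprintf(
      paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
             "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
             "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
      n[, 1], n[, 2], n[, 3], p1[, 1], p1[, 2], p1[, 3],
      p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
    writeLines(body, con)
    writeLines(sprintf("endsolid %s", name), con)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary)
#'
#' Vertices are welded by exact coordinate match.
#' @param path STL file path.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid") && {
    txt <- readLines(path, n = 2, warn = FALSE)
    length(txt) >= 2 && grepl("facet|endsolid", txt[2])
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    nums <- matrix(0, nt * 3, 3)
    for (i in seq_len(nt)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      nums[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, byrow = TRUE)
      readBin(con, "raw", n = 2)
    }
  }
  key <- apply(nums, 1, function(r) paste(r, collapse = "|"))
  uk <- unique(key)
  vid <- match(key, uk)
  verts <- nums[!duplicated(key), , drop = FALSE]
  surface_mesh(verts, matrix(vid, ncol = 3, byrow = TRUE))
}

#' Write/read the sidecar patch file for a labeled surface
#'
#' STL carries no patch labels; opening patches are stored as a JSON sidecar
#' mapping patch name to 1-based triangle indices.
#' @param patches named list of triangle index vectors.
#' @param path sidecar file path.
#' @export
write_patches <- function(patches, path) {
  jsonlite::write_json(patches, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.integer)
}
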