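# Centerline extraction and cross-sectional area profiling.
#
# The centerline is the maximal-inscribed-sphere path: an interior
# distance-to-wall field is computed on a voxelization of the lumen, and the
# centerline is the shortest path between opening centroids under a cost that
# strongly favors voxels far from the wall, then smoothed and resampled at a
# fixed arclength interval (0.1 mm by default). All coordinates in mm.

#' Extract the lumen centerline
#'
#' @param x a `surface_mesh` with labeled opening patches, or a
#'   [lumen_mask()] (at least 2 openings are required for a surface; a mask
#'   yields a single path between the two most distant deep voxels is not
#'   supported -- supply a surface).
#' @param interval arclength sampling interval (mm).
#' @param voxel internal voxelization edge (mm); default adapts to the
#'   smallest opening radius.
#' @return An object of class `centerline`: a list of branches, each with
#'   `points` (n x 3 mm), `s` (arclength from the junction/anchor, mm),
#'   `tangents` (unit vectors), plus `junction` (coords or NULL), `interval`,
#'   and `wall_distance` (mm, the inscribed-sphere radius along the branch).
#' @export
extract_centerline <- function(x, interval = 0.1, voxel = NULL) {
  stopifnot(inherits(x, "surface_mesh"))
  if (is.null(x$patches) || length(x$patches) < 2) {
    abort("centerline extraction needs at least 2 labeled openings",
          "avflow_topology_error")
  }
  openings <- lapply(names(x$patches), function(nm) {
    tri <- x$patches[[nm]]
    ar <- triangle_areas(x)[tri]
    cent <- triangle_centroids(x)[tri, , drop = FALSE]
    list(name = nm, centroid = colSums(cent * ar) / sum(ar),
         radius = sqrt(sum(ar) / pi))
  })
  rmin <- min(vapply(openings, function(o) o$radius, numeric(1)))
  h <- voxel %||% max(rmin / 5, 0.02)
  vox <- voxelize_surface(x, h)
  mask <- largest_component_6(vox$mask)
  dwall <- distance_transform(mask, rep(h, 3))
  dims <- dim(mask)
  lin <- which(mask)
  id <- array(0L, dims)
  id[lin] <- seq_along(lin)
  arr <- which(mask, arr.ind = TRUE)
  coords <- sweep((arr - 1) * h, 2, vox$origin, "+")
  dvals <- dwall[lin]
  # 26-neighborhood graph, cost = edge length / (mean wall distance)^2
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  ea <- list(); eb <- list(); ew <- list()
  for (r in seq_len(nrow(offs))) {
    ngh <- sweep(arr, 2, offs[r, ], "+")
    ok <- ngh[, 1] >= 1 & ngh[, 1] <= dims[1] &
      ngh[, 2] >= 1 & ngh[, 2] <= dims[2] &
      ngh[, 3] >= 1 & ngh[, 3] <= dims[3]
    b <- integer(nrow(arr)); b[ok] <- id[ngh[ok, , drop = FALSE]]
    sel <- b > 0
    len <- sqrt(sum((offs[r, ] * h)^2))
    ea[[r]] <- which(sel); eb[[r]] <- b[sel]
    ew[[r]] <- len / (((dvals[which(sel)] + dvals[b[sel]]) / 2 + 1e-6)^2)
  }
  g <- igraph::graph_from_edgelist(cbind(unlist(ea), unlist(eb)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  wts <- unlist(ew)
  # terminal voxels: deepest voxel near each opening centroid
  term <- vapply(openings, function(o) {
    d2 <- rowSums(sweep(coords, 2, o$centroid)^2)
    near <- which(d2 < (o$radius + 2 * h)^2)
    if (!length(near)) near <- which.min(d2)
    near[which.max(dvals[near])]
  }, integer(1))
  root <- term[1]
  paths <- igraph::shortest_paths(g, from = root, to = term[-1],
                                  weights = wts)$vpath
  # span the full lumen: paths run between opening centroids
  raw <- lapply(seq_along(paths), function(q) {
    rbind(openings[[1]]$centroid,
          coords[as.integer(paths[[q]]), , drop = FALSE],
          openings[[q + 1]]$centroid)
  })
  names(raw) <- vapply(openings[-1], function(o) o$name, character(1))

  if (length(raw) == 1) {
    br <- resample_polyline(smooth_polyline(raw[[1]], h), interval)
    branches <- list(main = br)
    junction <- NULL
    branches$main$s <- br$s  # anchor at the first opening
  } else {
    # junction = last common point of all root-to-outlet paths
    common <- raw[[1]]
    for (q in raw[-1]) {
      nmin <- min(nrow(common), nrow(q))
      same <- rowSums(abs(common[seq_len(nmin), , drop = FALSE] -
                            q[seq_len(nmin), , drop = FALSE])) == 0
      ncom <- if (all(same)) nmin else which(!same)[1] - 1
      common <- common[seq_len(max(ncom, 1)), , drop = FALSE]
    }
    jn_idx <- nrow(common)
    junction <- common[jn_idx, ]
    branches <- list()
    # trunk: root -> junction (reversed so s runs from the junction)
    trunk <- raw[[1]][seq_len(jn_idx), , drop = FALSE]
    branches[[paste0("to_", openings[[1]]$name)]] <-
      resample_polyline(smooth_polyline(trunk[rev(seq_len(nrow(trunk))), ,
                                              drop = FALSE], h), interval)
    for (nm in names(raw)) {
      limb <- raw[[nm]][jn_idx:nrow(raw[[nm]]), , drop = FALSE]
      branches[[paste0("to_", nm)]] <-
        resample_polyline(smooth_polyline(limb, h), interval)
    }
  }
  # refine: move points to perpendicular-section centroids (twice), which
  # removes the lattice wander of the shortest-path seed
  for (nm in names(branches)) {
    branches[[nm]] <- recenter_branch(branches[[nm]], x)
    branches[[nm]] <- recenter_branch(branches[[nm]], x)
  }
  # wall distance along each branch (interiority diagnostic)
  for (nm in names(branches)) {
    p <- branches[[nm]]$points
    ii <- pmin(pmax(round(sweep(p, 2, vox$origin) / h) + 1, 1),
               matrix(dims, nrow(p), 3, byrow = TRUE))
    branches[[nm]]$wall_distance <- dwall[cbind(ii[, 1], ii[, 2], ii[, 3])]
  }
  structure(list(branches = branches, junction = junction,
                 interval = interval, openings = openings),
            class = "centerline")
}

#' @method print centerline
#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d branch(es) at %.3g mm interval%s\n",
              length(x$branches), x$interval,
              if (!is.null(x$junction)) " with junction" else ""))
  invisible(x)
}

# moving-average smoothing of a voxel path (window scaled to the local
# inscribed radius would over-smooth bends; a fixed ~6-voxel window removes
# the lattice zigzag)
smooth_polyline <- function(p, h, window = NULL) {
  n <- nrow(p)
  w <- window %||% min(max(3L, as.integer(round(0.6 / h))), max(n %/% 4, 1L))
  if (n < 5 || w < 2) return(p)
  out <- p
  for (c in 1:3) {
    out[, c] <- stats::filter(p[, c], rep(1 / (2 * w + 1), 2 * w + 1),
                              sides = 2)
    # keep endpoints anchored, fill the filter's NA margin
    na <- which(is.na(out[, c]))
    out[na, c] <- p[na, c]
  }
  out
}

resample_polyline <- function(p, interval) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-12)
  p <- p[keep, , drop = FALSE]
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  ns <- max(2L, floor(L / interval) + 1L)
  si <- seq(0, by = interval, length.out = ns)
  pts <- cbind(stats::approx(s, p[, 1], xout = si)$y,
               stats::approx(s, p[, 2], xout = si)$y,
               stats::approx(s, p[, 3], xout = si)$y)
  tg <- rbind(pts[2, ] - pts[1, ],
              (pts[-(1:2), , drop = FALSE] -
                 pts[seq_len(ns - 2), , drop = FALSE]) / 2,
              pts[ns, ] - pts[ns - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, s = si, tangents = tg)
}

#' Perpendicular cross-sectional area profile along a centerline
#'
#' At each centerline sample the surface is cut by the plane normal to the
#' local tangent; the area of the connected intersection loop containing the
#' centerline point is recorded. Samples whose cutting plane yields no
#' enclosing loop (typically near the open ends) are dropped and counted.
#'
#' @param centerline a `centerline`.
#' @param surface the `surface_mesh` the centerline was extracted from.
#' @return An object of class `area_profile`: data.frame with columns
#'   `branch`, `s_mm` (0 at the junction/anchor), `area_mm2`, `area_um2`;
#'   attribute `n_dropped` counts trimmed samples.
#' @export
area_profile <- function(centerline, surface) {
  stopifnot(inherits(centerline, "centerline"),
            inherits(surface, "surface_mesh"))
  rows <- list()
  dropped <- 0L
  for (nm in names(centerline$branches)) {
    br <- centerline$branches[[nm]]
    for (i in seq_len(nrow(br$points))) {
      a <- plane_section_area(surface, br$points[i, ], br$tangents[i, ])
      if (is.na(a)) {
        dropped <- dropped + 1L
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          branch = nm, s_mm = br$s[i], area_mm2 = a, area_um2 = a * 1e6)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("area_profile", "data.frame")
  out
}

plane_section_area <- function(surface, p0, n) {
  sec <- plane_section(surface, p0, n)
  if (is.null(sec)) NA_real_ else sec$area
}

# intersection loop of surface with plane (p0, normal n) that encloses p0:
# polygon area and 3D centroid; NULL if no enclosing loop exists
plane_section <- function(surface, p0, n) {
  n <- normalize(n)
  v <- surface$vertices
  d <- as.vector(v %*% n) - sum(p0 * n)
  tri <- surface$triangles
  s1 <- d[tri[, 1]]; s2 <- d[tri[, 2]]; s3 <- d[tri[, 3]]
  cut <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(cut)) return(NA_real_)
  tcut <- tri[cut, , drop = FALSE]
  # for each cut triangle, the two crossed edges (keyed by vertex pair)
  segs <- matrix(0, sum(cut), 2)  # edge key per segment endpoint
  nv <- nrow(v)
  ekey <- function(a, b) (pmin(a, b) - 1) * as.double(nv) + pmax(a, b)
  e12 <- sign(d[tcut[, 1]]) != sign(d[tcut[, 2]])
  e23 <- sign(d[tcut[, 2]]) != sign(d[tcut[, 3]])
  e31 <- sign(d[tcut[, 3]]) != sign(d[tcut[, 1]])
  keys <- cbind(ifelse(e12, ekey(tcut[, 1], tcut[, 2]), NA),
                ifelse(e23, ekey(tcut[, 2], tcut[, 3]), NA),
                ifelse(e31, ekey(tcut[, 3], tcut[, 1]), NA))
  segs <- t(apply(keys, 1, function(r) r[!is.na(r)][1:2]))
  ukeys <- unique(as.vector(segs))
  a_id <- (ukeys - 1) %/% nv + 1
  b_id <- ukeys - (a_id - 1) * nv
  tfr <- d[a_id] / (d[a_id] - d[b_id])
  pts <- v[a_id, , drop = FALSE] +
    tfr * (v[b_id, , drop = FALSE] - v[a_id, , drop = FALSE])
  sa <- match(segs[, 1], ukeys)
  sb <- match(segs[, 2], ukeys)
  # chain segments into loops (each crossing point joins exactly 2 segments
  # on a watertight surface)
  nseg <- length(sa)
  adj <- cbind(sa, sb)
  # in-plane basis
  e1 <- normalize(if (abs(n[1]) < 0.9) vcross(matrix(n, 1),
                                              matrix(c(1, 0, 0), 1)) else
                                                vcross(matrix(n, 1),
                                                       matrix(c(0, 1, 0), 1)))
  e2 <- vcross(matrix(n, 1), matrix(e1, 1))
  P2 <- cbind(sweep(pts, 2, p0) %*% as.vector(e1),
              sweep(pts, 2, p0) %*% as.vector(e2))
  # vertex -> incident segments
  inc <- vector("list", length(ukeys))
  for (q in seq_len(nseg)) {
    inc[[sa[q]]] <- c(inc[[sa[q]]], q)
    inc[[sb[q]]] <- c(inc[[sb[q]]], q)
  }
  used <- rep(FALSE, nseg)
  for (start in seq_len(nseg)) {
    if (used[start]) next
    loop <- integer(0)
    cur_seg <- start
    cur_vtx <- sa[start]
    first_vtx <- sb[start]
    repeat {
      used[cur_seg] <- TRUE
      loop <- c(loop, cur_vtx)
      nxt_vtx <- if (sa[cur_seg] == cur_vtx) sb[cur_seg] else sa[cur_seg]
      if (nxt_vtx == first_vtx && length(loop) > 1) {
        loop <- c(loop, nxt_vtx)
        break
      }
      cand <- inc[[nxt_vtx]]
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        loop <- c(loop, nxt_vtx)
        break
      }
      cur_seg <- cand[1]
      cur_vtx <- nxt_vtx
      if (length(loop) > nseg + 1) break
    }
    if (length(loop) < 4) next
    poly <- P2[loop, , drop = FALSE]
    # winding test: does the loop enclose the in-plane origin (= p0)?
    ang <- atan2(poly[, 2], poly[, 1])
    dang <- diff(ang)
    dang <- (dang + pi) %% (2 * pi) - pi
    winding <- sum(dang) / (2 * pi)
    if (abs(winding) > 0.5) {
      xs <- poly[, 1]; ys <- poly[, 2]
      m <- nrow(poly)
      cross <- xs[-m] * ys[-1] - xs[-1] * ys[-m]
      area2 <- sum(cross)
      area <- abs(area2) / 2
      if (area < .Machine$double.eps) next
      cx <- sum((xs[-m] + xs[-1]) * cross) / (3 * area2)
      cy <- sum((ys[-m] + ys[-1]) * cross) / (3 * area2)
      centroid <- p0 + cx * as.vector(e1) + cy * as.vector(e2)
      return(list(area = area, centroid = centroid))
    }
  }
  NULL
}

# one pass of section-centroid recentering: each interior centerline point is
# moved to the centroid of its perpendicular cross-section
recenter_branch <- function(br, surface) {
  pts <- br$points
  n <- nrow(pts)
  if (n < 3) return(br)
  for (i in 2:(n - 1)) {
    # wide-stencil tangent: robust against residual lattice zigzag
    j1 <- max(1, i - 3); j2 <- min(n, i + 3)
    tg <- normalize(pts[j2, ] - pts[j1, ])
    sec <- plane_section(surface, pts[i, ], tg)
    if (!is.null(sec)) {
      step <- sec$centroid - pts[i, ]
      # cap the move at one section radius to reject degenerate loops
      rloc <- sqrt(sec$area / pi)
      if (sqrt(sum(step^2)) < rloc) pts[i, ] <- sec$centroid
    }
  }
  resample_polyline(pts, br$s[2] - br$s[1])
}

#' Windowed mean cross-sectional area over an arclength segment
#'
#' Mean and SD of all area samples in `[start_s, start_s + length]` along one
#' branch (about 41 samples for a 4 mm window at 0.1 mm interval).
#'
#' @param profile an `area_profile`.
#' @param start_s window start (mm, junction = 0).
#' @param length window length (mm); 4 mm matches the anatomically anchored
#'   averaging segment.
#' @param branch branch name; defaults to the first branch in the profile.
#' @return list with `mean_um2`, `sd_um2`, `mean_mm2`, `n`.
#' @export
segment_average_area <- function(profile, start_s = 0, length = 4,
                                 branch = NULL) {
  stopifnot(inherits(profile, "area_profile"))
  branch <- branch %||% profile$branch[1]
  p <- profile[profile$branch == branch, ]
  # endpoint samples may have been trimmed; allow one sample of slack
  step <- if (nrow(p) > 1) stats::median(diff(sort(p$s_mm))) else Inf
  if (!nrow(p) || min(p$s_mm) > start_s + step + 1e-9 ||
      max(p$s_mm) < start_s + length - step - 1e-9) {
    abort("averaging window exceeds the profile extent", "avflow_extent_error")
  }
  sel <- p$s_mm >= start_s - 1e-9 & p$s_mm <= start_s + length + 1e-9
  list(mean_um2 = mean(p$area_um2[sel]),
       sd_um2 = stats::sd(p$area_um2[sel]),
       mean_mm2 = mean(p$area_mm2[sel]),
       n = sum(sel))
}

#' Write an area profile as CSV (columns s_mm, area_um2, branch_id)
#' @param profile an `area_profile`.
#' @param path output file.
#' @export
write_area_profile <- function(profile, path) {
  utils::write.csv(
    data.frame(s_mm = profile$s_mm, area_um2 = profile$area_um2,
               branch_id = profile$branch),
    path, row.names = FALSE)
  invisible(path)
}
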