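# Wall and volumetric hemodynamic metrics from a solved field series.
#
# Wall metrics (WSS, its spatial gradient WSSg, OSI) live on the wall faces of
# the voxel mesh; volumetric metrics (vorticity, helicity, Q-criterion) live
# on cells. Internally SI; reported in the conventional units: WSS dyne/cm^2,
# WSSg dyne/cm^3, vorticity 1/s, helicity density cm/s^2, Q 1/s^2.

# -- geometric helpers ---------------------------------------------------------

# outward wall normals estimated from the signed distance field of the fluid
# region: smooth (non-staircase) normals, exact for tubes
wall_normal_field <- function(mesh, pad = 2L) {
  dims <- mesh$dims
  mask <- mesh$cid > 0L
  # pad with background so the outside is represented at the bbox edge
  maskp <- array(FALSE, dims + 2L * pad)
  maskp[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
        pad + seq_len(dims[3])] <- mask
  phi <- signed_distance(maskp, rep(1, 3))  # lattice units
  list(phi = phi, mask = mask, pad = pad)
}

# trilinear interpolation of per-cell values at physical points (m);
# non-fluid corners are dropped and the weights renormalized
interp_cells <- function(mesh, vals, pts) {
  vals <- as.matrix(vals)
  g <- sweep(pts, 2, mesh$origin) / mesh$h  # lattice coordinates, cell 1 at 0
  i0 <- floor(g)
  f <- g - i0
  out <- matrix(0, nrow(pts), ncol(vals))
  wsum <- numeric(nrow(pts))
  dims <- mesh$dims
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx + 1L; jj <- i0[, 2] + dy + 1L; kk <- i0[, 3] + dz + 1L
    ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] &
      kk >= 1 & kk <= dims[3]
    cell <- integer(nrow(pts))
    cell[ok] <- mesh$cid[cbind(ii[ok], jj[ok], kk[ok])]
    ok <- ok & cell > 0L
    w <- abs((1 - dx) - f[, 1]) * abs((1 - dy) - f[, 2]) *
      abs((1 - dz) - f[, 3])
    w[!ok] <- 0
    out <- out + w * vals[pmax(cell, 1L), , drop = FALSE] * (w > 0)
    wsum <- wsum + w
  }
  bad <- wsum < 1e-12
  out[!bad, ] <- out[!bad, , drop = FALSE] / wsum[!bad]
  out[bad, ] <- NA_real_
  out
}

# trilinear interpolation of a full-grid array at lattice coordinates
interp_grid <- function(arr, g) {
  dims <- dim(arr)
  i0 <- pmin(pmax(floor(g), 0), matrix(dims - 2, nrow(g), 3, byrow = TRUE))
  f <- g - i0
  out <- numeric(nrow(g))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- abs((1 - dx) - f[, 1]) * abs((1 - dy) - f[, 2]) *
      abs((1 - dz) - f[, 3])
    out <- out + w * arr[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L,
                               i0[, 3] + dz + 1L)]
  }
  out
}

# wall faces of a mesh plus smooth outward unit normals at their centers
wall_face_geometry <- function(mesh) {
  wf <- which(mesh$faces$patch == "wall")
  centers <- mesh$faces$center[wf, , drop = FALSE]
  nf <- wall_normal_field(mesh)
  glat <- sweep(centers, 2, mesh$origin) / mesh$h + nf$pad
  grad <- matrix(0, length(wf), 3)
  for (ax in 1:3) {
    e <- rep(0, 3); e[ax] <- 0.5
    gp <- interp_grid(nf$phi, sweep(glat, 2, -e))
    gm <- interp_grid(nf$phi, sweep(glat, 2, e))
    grad[, ax] <- gp - gm
  }
  nrm <- -grad / pmax(sqrt(rowSums(grad^2)), 1e-12)  # outward (phi > 0 inside)
  # signed distance (m) from the face center to the smooth wall surface:
  # positive when the zero level lies outward of the staircase face center
  phi_f <- interp_grid(nf$phi, glat) * mesh$h
  list(faces = wf, centers = centers, normals = nrm, wall_offset = phi_f,
       areas = mesh$faces$area[wf],
       cells = mesh$faces$cell[wf], dirs = mesh$faces$dir[wf])
}

# least-squares gradient of per-cell fields on a volume mesh. Per axis, a
# quadratic-through-the-origin model u(d) = a d + b d^2 is fitted over the
# first and second neighbors (and optionally no-slip wall faces at their
# axis-crossing distance), so the reconstruction is exact for fields that are
# quadratic along each axis (e.g. Poiseuille) and a fortiori for linear ones.
mesh_gradient <- function(mesh, vals, noslip_walls = FALSE) {
  vals <- as.matrix(vals)
  K <- nrow(vals)
  h <- mesh$h
  nbp <- mesh$nb
  nbp[nbp == 0L] <- K + 1L
  nbp_ext <- rbind(nbp, rep(K + 1L, 6))
  has <- matrix(as.numeric(mesh$nb > 0L), K, 6)
  wallm <- matrix(0, K, 6)
  dwall <- matrix(h / 2, K, 6)
  if (noslip_walls) {
    wf <- mesh$faces$patch == "wall"
    cells_w <- mesh$faces$cell[wf]
    dirs_w <- mesh$faces$dir[wf]
    wallm[cbind(cells_w, dirs_w)] <- 1
    # axis distance from the cell center to the smooth wall (zero crossing of
    # the signed distance field along this axis)
    nf <- wall_normal_field(mesh)
    li <- mesh$cells[cells_w, , drop = FALSE] + nf$pad
    off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
    lo <- li + off[dirs_w, , drop = FALSE]
    phi_c <- nf$phi[li]
    phi_o <- nf$phi[lo]
    frac <- phi_c / pmax(phi_c - phi_o, 1e-9)
    dwall[cbind(cells_w, dirs_w)] <- h * pmin(pmax(frac, 0.2), 1.3)
  }
  out <- vector("list", ncol(vals))
  for (c in seq_len(ncol(vals))) {
    phi <- vals[, c]
    pp <- c(phi, 0)
    g <- matrix(0, K, 3)
    for (ax in 1:3) {
      dm <- 2L * ax - 1L; dp <- 2L * ax
      S2 <- S3 <- S4 <- B1 <- B2 <- numeric(K)
      add_sample <- function(mask, d, dphi) {
        w <- mask / pmax(d^2, 1e-300)
        S2 <<- S2 + w * d^2
        S3 <<- S3 + w * d^3
        S4 <<- S4 + w * d^4
        B1 <<- B1 + w * d * dphi
        B2 <<- B2 + w * d^2 * dphi
      }
      for (side in c(dm, dp)) {
        sgn <- DIR_SGN[side]
        n1 <- nbp[, side]
        hs <- has[, side]
        add_sample(hs, rep(sgn * h, K), pp[n1] - phi)
        # second neighbor along the same axis (0 weight where absent)
        n2 <- nbp_ext[n1, side]
        hs2 <- hs * as.numeric(n2 <= K)
        add_sample(hs2, rep(sgn * 2 * h, K), pp[pmin(n2, K + 1L)] - phi)
        if (noslip_walls) {
          add_sample(wallm[, side], sgn * dwall[, side], -phi)
        }
      }
      det <- S2 * S4 - S3^2
      lin <- det <= 1e-10 * pmax(S2 * S4, 1e-300)
      a <- (S4 * B1 - S3 * B2) / ifelse(lin, Inf, det)
      a[lin] <- B1[lin] / pmax(S2[lin], 1e-300)
      g[, ax] <- a
    }
    out[[c]] <- g
  }
  out
}

# rowsum onto a fixed-length result (groups with no entries get 0)
rowsum_full <- function(x, grp, n) {
  out <- numeric(n)
  rs <- rowsum(x, grp)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# static geometry of the near-wall quadratic fits: for each wall face, the
# sample cells (within a 5^3 neighborhood, close to the wall and to the
# face's normal line), their wall distances s, and the accumulated moments
# of the constrained LSQ (a, b) ~ u(s) = a s + b s^2
wall_fit_weights <- function(mesh, wg) {
  nf <- wall_normal_field(mesh)
  h <- mesh$h
  nfaces <- length(wg$faces)
  idx3 <- mesh$cells[wg$cells, , drop = FALSE]
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  face_l <- list(); cell_l <- list(); s_l <- list()
  dims <- mesh$dims
  xw <- wg$centers + wg$wall_offset * wg$normals
  for (r in seq_len(nrow(offs))) {
    ngh <- sweep(idx3, 2, -offs[r, ])
    ok <- ngh[, 1] >= 1 & ngh[, 1] <= dims[1] &
      ngh[, 2] >= 1 & ngh[, 2] <= dims[2] &
      ngh[, 3] >= 1 & ngh[, 3] <= dims[3]
    cell <- integer(nfaces)
    cell[ok] <- mesh$cid[ngh[ok, , drop = FALSE]]
    ok <- ok & cell > 0L
    if (!any(ok)) next
    # wall distance of the sample cell: the center-to-center signed EDT
    # equals (true wall distance + h/2) at interior centers near a wall
    li <- ngh[ok, , drop = FALSE] + nf$pad
    s <- nf$phi[cbind(li[, 1], li[, 2], li[, 3])] * h - h / 2
    # keep near-wall samples close to the face's normal line
    rel <- mesh$centers[cell[ok], , drop = FALSE] - xw[ok, , drop = FALSE]
    along <- rowSums(rel * wg$normals[ok, , drop = FALSE])
    tang2 <- rowSums(rel^2) - along^2
    keep <- s > 0.05 * h & s < 2.6 * h & tang2 < (1.7 * h)^2
    if (!any(keep)) next
    face_l[[r]] <- which(ok)[keep]
    cell_l[[r]] <- cell[ok][keep]
    s_l[[r]] <- s[keep]
  }
  face <- unlist(face_l); cell <- unlist(cell_l); s <- unlist(s_l)
  w <- 1 / pmax(s, 0.2 * h)   # mild downweighting of far samples
  S2 <- rowsum_full(w * s^2, face, nfaces)
  S3 <- rowsum_full(w * s^3, face, nfaces)
  S4 <- rowsum_full(w * s^4, face, nfaces)
  det <- S2 * S4 - S3^2
  # faces with too few samples for the quadratic: fall back to linear fit
  # (b = 0): a = B1 / S2, realized by zeroing S3 and setting S4 = 1
  degenerate <- det <= 1e-12 * pmax(S2 * S4, 1e-300) | S4 == 0
  S3[degenerate] <- 0
  S4[degenerate] <- pmax(S2[degenerate], 1e-300) * 0 + 1
  det <- S2 * S4 - S3^2
  det[det <= 0] <- Inf
  list(face = face, cell = cell, s = s, w = w,
       S2 = S2, S3 = S3, S4 = S4, det = det)
}

# -- wall shear ----------------------------------------------------------------

#' Wall shear stress vectors over a field series
#'
#' The wall shear vector is the tangential viscous traction the blood exerts
#' on the wall. With the default no-slip treatment the velocity gradient at
#' the wall is obtained from a quadratic fit along the inward wall normal
#' through the wall value (zero) and two interpolated interior probes, using
#' smooth normals from the distance field of the lumen (this removes the
#' staircase bias of the voxel boundary). With `assume_noslip = FALSE` the
#' full symmetric-gradient traction is evaluated from the interior
#' cell-gradient instead (exact for linear fields; rigid-body rotation gives
#' zero shear).
#'
#' @param field_series a `field_series` from [solve_pulsatile()] or
#'   [solve_steady()], or a single K x 3 velocity matrix (m/s).
#' @param mesh the `volume_mesh` (defaults to the series' mesh).
#' @param mu dynamic viscosity (Pa.s); defaults to the series' fluid
#'   properties.
#' @param assume_noslip use the no-slip wall-probe gradient (default).
#' @return An object of class `wall_shear_series`: `times`, `tau` (list of
#'   F x 3 matrices, Pa), `centers`, `normals`, `areas`, `faces`, `mesh`.
#' @export
wall_shear_vectors <- function(field_series, mesh = NULL, mu = NULL,
                               assume_noslip = TRUE) {
  if (inherits(field_series, "field_series")) {
    mesh <- mesh %||% field_series$mesh
    mu <- mu %||% field_series$props$viscosity
    Ulist <- field_series$U
    times <- field_series$times
  } else {
    if (is.null(mesh) || is.null(mu)) {
      abort("mesh and mu are required for a bare velocity field",
            "avflow_config_error")
    }
    Ulist <- list(as.matrix(field_series))
    times <- 0
  }
  wg <- wall_face_geometry(mesh)
  h <- mesh$h
  tau <- vector("list", length(Ulist))
  if (assume_noslip) {
    # constrained quadratic fit along the wall normal: for each wall face,
    # u(s) = a s + b s^2 (u(0) = 0 at the wall) is fitted over nearby fluid
    # cells, s being each cell's wall distance from the signed distance
    # field. tau = mu * tangential(a). Exact for fully developed tube flow.
    fit <- wall_fit_weights(mesh, wg)
    for (i in seq_along(Ulist)) {
      U <- Ulist[[i]]
      g_in <- matrix(0, length(wg$faces), 3)
      for (c in 1:3) {
        uu <- U[fit$cell, c]
        B1 <- rowsum_full(fit$w * fit$s * uu, fit$face, length(wg$faces))
        B2 <- rowsum_full(fit$w * fit$s^2 * uu, fit$face, length(wg$faces))
        g_in[, c] <- (fit$S4 * B1 - fit$S3 * B2) / fit$det
      }
      gn <- rowSums(g_in * wg$normals)
      tau[[i]] <- mu * (g_in - gn * wg$normals)
    }
  } else {
    for (i in seq_along(Ulist)) {
      G <- mesh_gradient(mesh, Ulist[[i]])
      tt <- matrix(0, length(wg$faces), 3)
      cells <- wg$cells
      n <- wg$normals
      # t = mu (grad u + grad u^T) . n_in evaluated at the adjacent cell
      for (a in 1:3) {
        ta <- numeric(length(wg$faces))
        for (b in 1:3) {
          ta <- ta + (G[[a]][cells, b] + G[[b]][cells, a]) * (-n[, b])
        }
        tt[, a] <- mu * ta
      }
      tn <- rowSums(tt * n)
      tau[[i]] <- tt - tn * n
    }
  }
  structure(list(times = times, tau = tau, centers = wg$centers,
                 normals = wg$normals, areas = wg$areas, faces = wg$faces,
                 cells = wg$cells, mesh = mesh),
            class = "wall_shear_series")
}

#' @method print wall_shear_series
#' @export
print.wall_shear_series <- function(x, ...) {
  cat(sprintf("wall_shear_series: %d wall faces, %d stored times\n",
              nrow(x$tau[[1]]), length(x$times)))
  invisible(x)
}

#' Wall shear stress magnitude
#'
#' Per face and stored time, the Euclidean magnitude
#' `sqrt(tau_x^2 + tau_y^2 + tau_z^2)` of the wall shear vector, in dyne/cm^2.
#'
#' @param series a `wall_shear_series`.
#' @return A `wall_metric` object: `values` (faces x times matrix,
#'   dyne/cm^2), `times`, face geometry, `metric = "WSS"`,
#'   `reduction = "instantaneous"`.
#' @export
wss_magnitude <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  vals <- vapply(series$tau, function(tt) {
    pa_to_dyne_cm2(sqrt(rowSums(tt^2)))
  }, numeric(nrow(series$tau[[1]])))
  vals <- matrix(vals, nrow = nrow(series$tau[[1]]))
  wall_metric(vals, series, "WSS", "dyne/cm^2")
}

wall_metric <- function(values, series, metric, units,
                        reduction = "instantaneous") {
  structure(list(values = values, times = series$times,
                 centers = series$centers, areas = series$areas,
                 faces = series$faces, metric = metric, units = units,
                 reduction = reduction, mesh = series$mesh),
            class = "wall_metric")
}

#' @method print wall_metric
#' @export
print.wall_metric <- function(x, ...) {
  cat(sprintf("wall_metric %s (%s, %s): %d faces x %d times\n", x$metric,
              x$units, x$reduction, nrow(as.matrix(x$values)),
              ncol(as.matrix(x$values))))
  invisible(x)
}

#' Spatial wall shear stress gradient
#'
#' Combines the three axis-aligned derivatives of the matching shear
#' components: `sqrt((d tau_x/dx)^2 + (d tau_y/dy)^2 + (d tau_z/dz)^2)`
#' (diagonal terms only -- the definition is implemented exactly as printed
#' in the source formulation rather than as the full surface-gradient tensor
#' used elsewhere in the literature). Each derivative is a least-squares fit
#' over adjacent wall faces, restricted to the local tangent plane. Units
#' dyne/cm^3.
#'
#' @param series a `wall_shear_series`.
#' @return A `wall_metric` with `metric = "WSSg"`; faces with no neighbors
#'   carry `NA` and are excluded from region averages.
#' @export
wssg <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  mesh <- series$mesh
  h <- mesh$h
  x <- series$centers
  nf <- nrow(x)
  # neighbor search via cell-index hashing (wall faces of nearby cells)
  cellmap <- split(seq_len(nf), series$cells)
  idx3 <- mesh$cells[series$cells, , drop = FALSE]
  key <- function(ijk) {
    (ijk[, 1] + 1L) + (mesh$dims[1] + 2L) *
      ((ijk[, 2] + 1L) + (mesh$dims[2] + 2L) * (ijk[, 3] + 1L))
  }
  facekey <- key(idx3)
  keymap <- split(seq_len(nf), facekey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb_list <- vector("list", nf)
  cand <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    kk <- key(sweep(idx3, 2, -offs[r, ]))
    cand[[r]] <- keymap[as.character(kk)]
  }
  for (i in seq_len(nf)) {
    nbs <- unlist(lapply(cand, function(cc) cc[[i]]), use.names = FALSE)
    nbs <- nbs[nbs != i]
    d <- sqrt(rowSums(sweep(x[nbs, , drop = FALSE], 2, x[i, ])^2))
    nb_list[[i]] <- nbs[d < 1.6 * h & d > 1e-12]
  }
  # precompute per-face LSQ weight matrices (3 x n_nb), tangent-plane
  # restricted with ridge regularization for the rank-2 geometry
  Wt <- vector("list", nf)
  nrm <- wall_face_geometry(mesh)$normals
  for (i in seq_len(nf)) {
    nbs <- nb_list[[i]]
    if (length(nbs) < 2) next
    Dm <- sweep(x[nbs, , drop = FALSE], 2, x[i, ])
    Dm <- Dm - (Dm %*% nrm[i, ]) %*% t(nrm[i, ])  # tangential offsets
    Am <- crossprod(Dm) + diag(1e-4 * h^2, 3)
    Wt[[i]] <- solve(Am, t(Dm))
  }
  vals <- matrix(NA_real_, nf, length(series$times))
  for (ti in seq_along(series$times)) {
    tt <- series$tau[[ti]]
    g2 <- numeric(nf)
    ok <- !vapply(Wt, is.null, logical(1))
    for (i in which(ok)) {
      nbs <- nb_list[[i]]
      acc <- 0
      for (c in 1:3) {
        gc <- Wt[[i]] %*% (tt[nbs, c] - tt[i, c])
        acc <- acc + gc[c]^2
      }
      g2[i] <- acc
    }
    g2[!ok] <- NA_real_
    vals[, ti] <- pa_m_to_dyne_cm3(sqrt(g2))
  }
  wall_metric(vals, series, "WSSg", "dyne/cm^3")
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |int tau dt| / int |tau| dt)` over exactly one cycle, with
#' trapezoidal quadrature: 0 for unidirectional shear, 0.5 for perfect
#' zero-mean reversal. Faces with zero shear throughout get OSI 0.
#'
#' @param series a `wall_shear_series` spanning one period.
#' @return A `wall_metric` with `metric = "OSI"`, dimensionless, reduction
#'   `cycle`.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  times <- series$times
  if (length(times) < 2) {
    abort("OSI needs a series spanning one cycle", "avflow_config_error")
  }
  w <- trapezoid_weights(times)
  nf <- nrow(series$tau[[1]])
  vec_int <- matrix(0, nf, 3)
  mag_int <- numeric(nf)
  for (i in seq_along(times)) {
    vec_int <- vec_int + w[i] * series$tau[[i]]
    mag_int <- mag_int + w[i] * sqrt(rowSums(series$tau[[i]]^2))
  }
  val <- 0.5 * (1 - sqrt(rowSums(vec_int^2)) / pmax(mag_int, 1e-300))
  val[mag_int <= 1e-300] <- 0
  val <- pmin(pmax(val, 0), 0.5)
  out <- wall_metric(matrix(val, ncol = 1), series, "OSI", "-", "cycle")
  out$times <- NA_real_
  out
}

trapezoid_weights <- function(times) {
  n <- length(times)
  dt <- diff(times)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

# -- volumetric metrics --------------------------------------------------------

volume_metric <- function(values, mesh, metric, units,
                          reduction = "instantaneous", total = NULL) {
  structure(list(values = values, mesh = mesh, metric = metric,
                 units = units, reduction = reduction, total = total),
            class = "volume_metric")
}

#' @method print volume_metric
#' @export
print.volume_metric <- function(x, ...) {
  cat(sprintf("volume_metric %s (%s, %s)\n", x$metric, x$units, x$reduction))
  invisible(x)
}

# extract a K x 3 velocity matrix (single snapshot) or list from input
as_velocity_list <- function(field, mesh) {
  if (inherits(field, "field_series")) {
    list(U = field$U, times = field$times, mesh = field$mesh)
  } else {
    list(U = list(as.matrix(field)), times = 0, mesh = mesh)
  }
}

#' Vorticity field
#'
#' `Omega = curl u` per cell from least-squares gradient reconstruction
#' (exact for globally linear fields). Magnitude in 1/s.
#'
#' @param field a `field_series` or a K x 3 velocity matrix (m/s).
#' @param mesh required if `field` is a bare matrix.
#' @param noslip_walls include zero-velocity wall-face samples in the
#'   gradient stencils (improves near-wall accuracy on solver output;
#'   disable for synthetic whole-domain fields).
#' @return A `volume_metric` with `values = list(vector = K x 3, magnitude)`
#'   per stored time, in 1/s.
#' @export
vorticity <- function(field, mesh = NULL, noslip_walls = FALSE) {
  fv <- as_velocity_list(field, mesh)
  mesh <- fv$mesh
  out <- lapply(fv$U, function(U) {
    G <- mesh_gradient(mesh, U, noslip_walls)
    om <- cbind(G[[3]][, 2] - G[[2]][, 3],
                G[[1]][, 3] - G[[3]][, 1],
                G[[2]][, 1] - G[[1]][, 2])
    list(vector = om, magnitude = sqrt(rowSums(om^2)))
  })
  volume_metric(out, mesh, "vorticity", "1/s")
}

#' Helicity density and total helicity
#'
#' Density `h = u . (curl u)` per cell (reported in cm/s^2; positive =
#' right-handed helical flow) and its volume integral (the total helicity,
#' reported in cm^4/s^2).
#'
#' @inheritParams vorticity
#' @return A `volume_metric`: per time, `density` (cm/s^2) and scalar
#'   `total` (cm^4/s^2).
#' @export
helicity <- function(field, mesh = NULL, noslip_walls = FALSE) {
  fv <- as_velocity_list(field, mesh)
  mesh <- fv$mesh
  Vc <- mesh$quality$cell_volume
  out <- lapply(fv$U, function(U) {
    G <- mesh_gradient(mesh, U, noslip_walls)
    om <- cbind(G[[3]][, 2] - G[[2]][, 3],
                G[[1]][, 3] - G[[3]][, 1],
                G[[2]][, 1] - G[[1]][, 2])
    dens_si <- rowSums(U * om)              # m/s^2
    list(density = dens_si * CM_PER_M,      # cm/s^2
         total = sum(dens_si * Vc) * CM_PER_M^4)  # cm^4/s^2
  })
  volume_metric(out, mesh, "helicity", "cm/s^2 (density), cm^4/s^2 (total)")
}

#' Q-criterion field
#'
#' `Q = (|W|_F^2 - |S|_F^2) / 2` with `W` and `S` the antisymmetric and
#' symmetric parts of the velocity gradient (squared Frobenius norms).
#' Positive Q marks vortex regions (rotation exceeding strain); simple shear
#' gives exactly zero. Also reports the strain-rate magnitude `|S|_F` (1/s).
#'
#' @inheritParams vorticity
#' @return A `volume_metric`: per time, `q` (1/s^2) and `strain_rate` (1/s).
#' @export
q_criterion <- function(field, mesh = NULL, noslip_walls = FALSE) {
  fv <- as_velocity_list(field, mesh)
  mesh <- fv$mesh
  out <- lapply(fv$U, function(U) {
    G <- mesh_gradient(mesh, U, noslip_walls)
    s2 <- 0; w2 <- 0
    for (a in 1:3) for (b in 1:3) {
      Sab <- 0.5 * (G[[a]][, b] + G[[b]][, a])
      Wab <- 0.5 * (G[[a]][, b] - G[[b]][, a])
      s2 <- s2 + Sab^2
      w2 <- w2 + Wab^2
    }
    list(q = 0.5 * (w2 - s2), strain_rate = sqrt(s2))
  })
  volume_metric(out, mesh, "Q-criterion", "1/s^2")
}

# -- reductions ----------------------------------------------------------------

#' Cycle-average (and systole/diastole snapshots) of a metric series
#'
#' Time-weighted trapezoidal mean over the stored cycle. When an inlet
#' waveform is supplied, the snapshots nearest the waveform's peak (systole)
#' and minimum (diastole) are also returned.
#'
#' @param metric a `wall_metric` with instantaneous values, or a
#'   `volume_metric`.
#' @param inlet_waveform optional [make_waveform()] for systole/diastole
#'   timing (argmax/argmin of the resampled waveform).
#' @return For wall metrics: a `wall_metric` with `reduction =
#'   "cycle_average"`, plus `systole`/`diastole` value vectors when timing is
#'   available. For volume metrics: the analogous reduced object (each
#'   numeric entry averaged).
#' @export
cycle_average <- function(metric, inlet_waveform = NULL) {
  sys_dia <- function(times) {
    if (is.null(inlet_waveform)) return(NULL)
    rs <- resample_waveform(inlet_waveform, 0.25)
    t_sys <- rs$t_ms[which.max(rs$v_cm_s)] / 1000
    t_dia <- rs$t_ms[which.min(rs$v_cm_s)] / 1000
    list(systole = which.min(abs(times - t_sys)),
         diastole = which.min(abs(times - t_dia)))
  }
  if (inherits(metric, "wall_metric")) {
    v <- as.matrix(metric$values)
    if (ncol(v) == 1) return(metric)  # already reduced
    w <- trapezoid_weights(metric$times)
    avg <- as.vector(v %*% w) / sum(w)
    out <- metric
    out$values <- matrix(avg, ncol = 1)
    out$reduction <- "cycle_average"
    sd_idx <- sys_dia(metric$times)
    if (!is.null(sd_idx)) {
      out$systole <- v[, sd_idx$systole]
      out$diastole <- v[, sd_idx$diastole]
    }
    return(out)
  }
  if (inherits(metric, "volume_metric")) {
    vals <- metric$values
    if (length(vals) == 1) return(metric)
    w <- trapezoid_weights(seq_along(vals))  # equal spacing assumed
    w <- w / sum(w)
    nm <- names(vals[[1]])
    avg <- lapply(nm, function(n) {
      Reduce(`+`, Map(function(v, wi) wi * v[[n]], vals, w))
    })
    names(avg) <- nm
    out <- metric
    out$values <- list(avg)
    out$reduction <- "cycle_average"
    return(out)
  }
  abort("cycle_average expects a wall_metric or volume_metric",
        "avflow_config_error")
}

#' Area-weighted segment average of a wall metric
#'
#' Averages a (reduced) wall metric over the wall faces whose projection onto
#' a centerline branch falls within `[start_s, start_s + length]` mm of the
#' anastomosis anchor.
#'
#' @param metric a `wall_metric` (single-column values, e.g. after
#'   [cycle_average()]).
#' @param centerline a `centerline` (mm).
#' @param branch branch name (default: first branch).
#' @param start_s,length window along the branch (mm); the 4 mm default
#'   matches the anatomically anchored reporting segment.
#' @return list with `mean`, `sd`, `n_faces`, `area_mm2`.
#' @export
region_average <- function(metric, centerline, branch = NULL,
                           start_s = 0, length = 4) {
  stopifnot(inherits(metric, "wall_metric"),
            inherits(centerline, "centerline"))
  v <- as.matrix(metric$values)
  if (ncol(v) != 1) {
    abort("reduce the metric (cycle_average or single snapshot) first",
          "avflow_config_error")
  }
  branch <- branch %||% names(centerline$branches)[1]
  br <- centerline$branches[[branch]]
  fc_mm <- m_to_mm(metric$centers)
  # nearest centerline sample
  nn <- apply(fc_mm, 1, function(pt) {
    which.min(colSums((t(br$points) - pt)^2))
  })
  s <- br$s[nn]
  # faces must also be near the branch (exclude other limbs)
  d2 <- rowSums((fc_mm - br$points[nn, , drop = FALSE])^2)
  rloc <- pmax(br$wall_distance[nn] * 2.5, 1)
  sel <- s >= start_s & s <= start_s + length & d2 < rloc^2 & !is.na(v[, 1])
  if (!any(sel)) {
    abort("no wall faces project into the requested window",
          "avflow_extent_error")
  }
  a <- metric$areas[sel]
  x <- v[sel, 1]
  m <- sum(a * x) / sum(a)
  list(mean = m,
       sd = sqrt(sum(a * (x - m)^2) / sum(a)),
       n_faces = sum(sel), area_mm2 = sum(a) * 1e6)
}

#' Isosurface of a per-cell scalar field
#'
#' Cell values are interpolated to grid nodes and triangulated at `level`
#' (marching tetrahedra). The result may be empty when the level is never
#' crossed; a constant field equal to the level is flagged with a warning.
#'
#' @param mesh a `volume_mesh`.
#' @param cell_values numeric per-cell scalar.
#' @param level iso level (same units as the field).
#' @return A `surface_mesh` in mm coordinates.
#' @export
isosurface <- function(mesh, cell_values, level) {
  stopifnot(length(cell_values) == mesh$quality$n_cells)
  if (all(abs(cell_values - level) < .Machine$double.eps * 100)) {
    warning("field is constant at the iso level; returning empty surface")
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  }
  nd <- mesh$dims + 1L
  acc <- array(0, nd)
  cnt <- array(0, nd)
  idx <- mesh$cells
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- cbind(idx[, 1] + dx, idx[, 2] + dy, idx[, 3] + dz)
    # accumulate with tabulation over linear indices (duplicates possible)
    lin <- ii[, 1] + nd[1] * (ii[, 2] - 1L) + nd[1] * nd[2] * (ii[, 3] - 1L)
    acc_add <- rowsum(cell_values, lin)
    cnt_add <- rowsum(rep(1, length(lin)), lin)
    tgt <- as.integer(rownames(acc_add))
    acc[tgt] <- acc[tgt] + acc_add[, 1]
    cnt[tgt] <- cnt[tgt] + cnt_add[, 1]
  }
  vals <- acc
  vals[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  vals[cnt == 0] <- NA_real_  # undefined outside the lumen: no crossings
  axes <- lapply(1:3, function(a) {
    m_to_mm(mesh$origin[a] + (seq_len(nd[a]) - 1.5) * mesh$h)
  })
  marching_tetrahedra(vals, axes, level)
}
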