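# Pulsatile incompressible laminar Navier-Stokes solver.
#
# Cell-centered collocated finite volumes on the hexahedral-voxel mesh with
# Rhie-Chow momentum interpolation and SIMPLE pressure-velocity coupling.
# Convection is second-order upwind (deferred correction over a first-order
# upwind matrix), diffusion second-order central, time integration implicit
# BDF2 (backward Euler on the first step). Momentum systems are solved
# matrix-free with Jacobi-preconditioned BiCGSTAB on the 7-point stencil; the
# pressure-correction matrix is constant and factorized once (sparse
# Cholesky). All solver-internal quantities are SI (m, s, Pa).

DIR_AXIS <- c(1L, 1L, 2L, 2L, 3L, 3L)
DIR_SGN <- c(-1, 1, -1, 1, -1, 1)
DIR_OPP <- c(2L, 1L, 4L, 3L, 6L, 5L)

#' Fluid properties
#'
#' Defaults are whole blood at body temperature: density 1050 kg/m^3 and
#' dynamic viscosity 0.0035 Pa.s, with a 100 mmHg reference pressure that
#' enters only as a gauge offset (incompressible flow depends on the pressure
#' gradient only).
#'
#' @param density kg/m^3.
#' @param viscosity dynamic viscosity, Pa.s.
#' @param reference_pressure_mmHg gauge offset added when reporting absolute
#'   pressure.
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1050, viscosity = 0.0035,
                        reference_pressure_mmHg = 100) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity,
                 reference_pressure_mmHg = reference_pressure_mmHg),
            class = "fluid_props")
}

#' Solver configuration
#'
#' @param dt_ms time step (ms); 0.1 ms reproduces the reference protocol
#'   (about 1200 steps over a ~120 ms cardiac cycle).
#' @param cycles number of cardiac cycles; results are taken from the final
#'   cycle (default 3; the first cycles wash out the zero initial condition).
#' @param tol per-component (x, y, z momentum) scaled residual tolerance.
#' @param tol_total total (continuity) scaled residual tolerance.
#' @param max_inner maximum SIMPLE iterations per time step.
#' @param relax_u,relax_p under-relaxation factors for steady solves.
#' @param relax_u_transient,relax_p_transient relaxation factors used by the
#'   implicit time stepping, where the time term already dominates the
#'   diagonal and SIMPLEC-consistent coupling needs little damping.
#' @param convection `"second_order_upwind"` (default) or
#'   `"first_order_upwind"`.
#' @param store_every store every k-th step of the final cycle for
#'   post-processing (the cycle start and end are always stored).
#' @param pressure_subiters pressure-correction sub-iterations per momentum
#'   solve (PISO-style correctors; 1 = classic SIMPLE).
#' @param max_steady_iter iteration cap for steady solves.
#' @param inlet_shape velocity profile shape imposed on velocity patches.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt_ms = 0.1, cycles = 3, tol = 1e-5,
                          tol_total = 1e-5, max_inner = 50,
                          relax_u = 0.7, relax_p = 0.3,
                          relax_u_transient = 1, relax_p_transient = 0.8,
                          convection = c("second_order_upwind",
                                         "first_order_upwind"),
                          store_every = 10, pressure_subiters = 1,
                          max_steady_iter = 2000,
                          inlet_shape = c("parabolic", "plug")) {
  stopifnot(dt_ms > 0, cycles >= 1, tol > 0, tol_total > 0, max_inner >= 1,
            relax_u > 0, relax_u <= 1, relax_p > 0, relax_p <= 1)
  structure(list(dt_ms = dt_ms, cycles = cycles, tol = tol,
                 tol_total = tol_total, max_inner = max_inner,
                 relax_u = relax_u, relax_p = relax_p,
                 relax_u_transient = relax_u_transient,
                 relax_p_transient = relax_p_transient,
                 convection = match.arg(convection),
                 store_every = store_every,
                 pressure_subiters = pressure_subiters,
                 max_steady_iter = max_steady_iter,
                 inlet_shape = match.arg(inlet_shape),
                 time_scheme = "implicit_bdf2"),
            class = "solver_config")
}

#' Boundary condition constructors
#'
#' `velocity_bc` prescribes a pulsatile cross-section-averaged velocity on an
#' opening (direction `"in"` for flow entering the domain, `"out"` for a
#' prescribed outflow). `zero_stress_bc` is the traction-free outflow that
#' absorbs the flow imbalance; `no_slip_bc` is the rigid vessel wall.
#'
#' @param waveform a [make_waveform()] object (cm/s).
#' @param direction `"in"` or `"out"`.
#' @param shape velocity profile shape; `NULL` defers to the solver config.
#' @return A condition object for use in [boundary_spec()].
#' @export
velocity_bc <- function(waveform, direction = c("in", "out"), shape = NULL) {
  stopifnot(inherits(waveform, "flow_waveform"))
  structure(list(type = "velocity", waveform = waveform,
                 direction = match.arg(direction), shape = shape),
            class = "avflow_bc")
}

#' @rdname velocity_bc
#' @export
zero_stress_bc <- function() {
  structure(list(type = "zero_stress"), class = "avflow_bc")
}

#' @rdname velocity_bc
#' @export
no_slip_bc <- function() {
  structure(list(type = "no_slip_wall"), class = "avflow_bc")
}

#' Assemble and validate a boundary specification
#'
#' Exactly one opening must be zero-stress; the wall must be no-slip; every
#' opening patch of the mesh must have a condition; all waveforms must share
#' one period. Prescribed outlet fluxes must stay below the inlet flux at
#' every instant -- otherwise the incompressible problem is over-prescribed
#' and a configuration error is raised.
#'
#' @param ... named conditions, one per mesh patch (e.g.
#'   `inlet = velocity_bc(w), outlet = zero_stress_bc(), wall = no_slip_bc()`).
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(...) {
  conds <- list(...)
  if (is.null(names(conds)) || any(names(conds) == "")) {
    abort("all boundary conditions must be named by patch",
          "avflow_config_error")
  }
  types <- vapply(conds, function(c) c$type, character(1))
  if (sum(types == "zero_stress") != 1) {
    abort("exactly one zero-stress outlet is required", "avflow_config_error")
  }
  if (!any(types == "no_slip_wall")) {
    abort("a no-slip wall condition is required", "avflow_config_error")
  }
  pers <- unlist(lapply(conds[types == "velocity"],
                        function(c) c$waveform$period))
  if (length(pers) && diff(range(pers)) > 1e-9) {
    abort("all waveforms must share one period", "avflow_config_error")
  }
  structure(conds, class = "boundary_spec")
}

#' Reynolds number
#'
#' `Re = rho * U * D / mu`. A warning is emitted above 2000, where the
#' laminar assumption no longer holds (murine AVF flows sit at Re 3-60).
#'
#' @param props a [fluid_props()].
#' @param characteristic_velocity m/s.
#' @param characteristic_diameter m.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(props, characteristic_velocity,
                            characteristic_diameter) {
  stopifnot(characteristic_velocity >= 0, characteristic_diameter > 0)
  re <- props$density * characteristic_velocity * characteristic_diameter /
    props$viscosity
  if (re > 2000) warning("Re > 2000: laminar flow assumption breached")
  re
}

# -- solver context -----------------------------------------------------------

# Precompute everything that does not change between time steps.
build_context <- function(mesh, bcs, props, config, steady = FALSE) {
  stopifnot(inherits(mesh, "volume_mesh"), inherits(bcs, "boundary_spec"),
            inherits(props, "fluid_props"), inherits(config, "solver_config"))
  patches <- unique(mesh$faces$patch)
  for (p in patches) {
    if (!p %in% names(bcs)) {
      abort(sprintf("no boundary condition for patch '%s'", p),
            "avflow_config_error")
    }
  }
  K <- mesh$quality$n_cells
  h <- mesh$h
  A <- h^2; V <- h^3
  rho <- props$density; mu <- props$viscosity
  nb <- mesh$nb
  has_nb <- nb > 0L
  # boundary face bookkeeping on the K x 6 lattice
  btype <- matrix(0L, K, 6)   # 0 none/internal, 1 wall, 2 velocity, 3 zstress
  fidx <- matrix(0L, K, 6)    # row into mesh$faces
  nf <- length(mesh$faces$cell)
  for (q in seq_len(nf)) {
    cl <- mesh$faces$cell[q]; d <- mesh$faces$dir[q]
    fidx[cl, d] <- q
  }
  vel_patches <- list()
  for (nm in names(bcs)) {
    bc <- bcs[[nm]]
    faces <- which(mesh$faces$patch == nm)
    if (!length(faces)) next
    cells <- mesh$faces$cell[faces]
    dirs <- mesh$faces$dir[faces]
    code <- switch(bc$type, no_slip_wall = 1L, velocity = 2L,
                   zero_stress = 3L)
    btype[cbind(cells, dirs)] <- code
    if (bc$type == "velocity") {
      shape <- bc$shape %||% config$inlet_shape
      prof <- inlet_velocity_profile(1, mesh, nm, shape)  # unit mean velocity
      n_patch <- mesh$patch_info[[nm]]$normal
      edir <- DIR_SGN[dirs] * diag(3)[DIR_AXIS[dirs], , drop = FALSE]
      proj <- as.vector(edir %*% n_patch) *
        sign(sum(edir %*% n_patch))  # outward normals align with cap normal
      proj <- abs(proj)
      aproj <- sum(proj * mesh$faces$area[faces])
      w <- prof$weights
      w <- w * aproj / sum(w * proj * mesh$faces$area[faces])
      sgn <- if (bc$direction == "in") -1 else 1
      vel_patches[[nm]] <- list(
        faces = faces, cells = cells, dirs = dirs,
        nvec = t(n_patch * sgn)[rep(1, length(faces)), , drop = FALSE],
        w = w, proj = proj, area_proj = aproj,
        fun = resample_waveform(bc$waveform, config$dt_ms)$fun,
        direction = bc$direction)
    }
  }
  # over-prescription guard on the waveform grid
  if (length(vel_patches)) {
    period <- bcs[[which(vapply(bcs, function(b) b$type == "velocity",
                                logical(1)))[1]]]$waveform$period
    ts <- seq(0, period, length.out = 257)
    qin <- rep(0, length(ts)); qout <- rep(0, length(ts))
    for (v in vel_patches) {
      q <- vapply(ts, v$fun, numeric(1)) / 100 * v$area_proj  # m^3/s
      if (v$direction == "in") qin <- qin + q else qout <- qout + q
    }
    scale <- max(abs(qin), 1e-30)
    bad <- qout > qin - 1e-9 * scale & (abs(qin) + abs(qout) > 0)
    if (any(bad)) {
      abort(paste("prescribed outlet fluxes reach or exceed the inlet flux;",
                  "the zero-stress outlet would have to supply flow"),
            "avflow_config_error")
    }
  }
  # geometric diffusion/time coefficient and pressure-correction matrix
  n_int <- rowSums(has_nb)
  n_wall_like <- rowSums(btype > 0)
  c0 <- if (steady) 0 else 1.5
  n_dirichlet <- btype_count(btype, c(1L, 2L))
  aP_diff <- pmax(mu * A / h * n_int + mu * A / (h / 2) * n_dirichlet,
                  mu * A / h)
  if (steady) {
    # SIMPLE: d from the diffusion-dominated diagonal
    aP_geom <- aP_diff
  } else {
    # SIMPLEC: d = V / (aP - sum aN); interior diffusion cancels, leaving
    # the time term plus boundary (Dirichlet) diffusion -- constant in time,
    # so the pressure-correction matrix can be factorized once
    aP_geom <- rho * V * c0 / (config$dt_ms / 1000) +
      mu * A / (h / 2) * n_dirichlet
  }
  dP <- V / aP_geom
  # Rhie-Chow dissipation pair: face coefficient d_rc = V / aP(time + diff)
  # with memory coefficient beta = time-term / aP, so the effective steady
  # dissipation d_rc / (1 - beta) = V / aP_diffusion is independent of the
  # time step (transient-consistent Rhie-Chow)
  aP_full <- aP_diff + rho * V * c0 / (config$dt_ms / 1000)
  dRC <- V / aP_full
  betaP <- if (steady) numeric(K) else
    (rho * V * c0 / (config$dt_ms / 1000)) / aP_full
  # pressure-correction matrix (constant): internal faces + zero-stress pin
  ii <- list(); jj <- list(); xx <- list()
  diag_acc <- numeric(K)
  for (d in c(2L, 4L, 6L)) {
    sel <- which(has_nb[, d])
    Nn <- nb[sel, d]
    df <- 0.5 * (dP[sel] + dP[Nn])
    coef <- rho * A * df / h
    ii[[length(ii) + 1]] <- c(sel, Nn)
    jj[[length(jj) + 1]] <- c(Nn, sel)
    xx[[length(xx) + 1]] <- c(-coef, -coef)
    diag_acc[sel] <- diag_acc[sel] + coef
    diag_acc[Nn] <- diag_acc[Nn] + coef
  }
  zsel <- which(btype == 3L, arr.ind = TRUE)
  if (nrow(zsel)) {
    zc <- zsel[, 1]
    diag_acc[zc] <- diag_acc[zc] + rho * A * dP[zc] / (h / 2)
  }
  M <- Matrix::sparseMatrix(i = c(unlist(ii), seq_len(K)),
                            j = c(unlist(jj), seq_len(K)),
                            x = c(unlist(xx), diag_acc), dims = c(K, K))
  chol_M <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  # precomputed index structures for the hot loops (all constant in time)
  nbp <- nb
  nbp[nbp == 0L] <- K + 1L
  has_num <- matrix(as.numeric(has_nb), K, 6)
  pidx <- list()
  for (d in c(2L, 4L, 6L)) {
    sel <- which(has_nb[, d])
    Nn <- nb[sel, d]
    pidx[[as.character(d)]] <- list(
      d = d, sel = sel, Nn = Nn,
      liP = sel + (d - 1L) * K, liN = Nn + (d - 2L) * K,
      df = 0.5 * (dP[sel] + dP[Nn]),
      drc = 0.5 * (dRC[sel] + dRC[Nn]),
      beta = 0.5 * (betaP[sel] + betaP[Nn]))
  }
  zmask <- matrix(as.numeric(btype == 3L), K, 6)
  zlin <- which(btype == 3L)
  zarr <- which(btype == 3L, arr.ind = TRUE)
  vlin <- which(btype == 2L)
  nDb <- btype_count(btype, c(1L, 2L))
  list(mesh = mesh, bcs = bcs, props = props, config = config,
       steady = steady, K = K, h = h, A = A, V = V, rho = rho, mu = mu,
       nb = nb, has_nb = has_nb, btype = btype, fidx = fidx,
       vel_patches = vel_patches, dP = dP, chol_M = chol_M,
       nbp = nbp, has_num = has_num, pidx = pidx, zmask = zmask,
       zlin = zlin, zarr = zarr, vlin = vlin, nDb = nDb,
       dRC = dRC, betaP = betaP)
}

# y = aP x - sum_d aN[, d] x[nb_d]  (padded gather; x[K+1] := 0)
fv_matvec <- function(aP, aN, nbp, x) {
  xp <- c(x, 0)
  aP * x - aN[, 1] * xp[nbp[, 1]] - aN[, 2] * xp[nbp[, 2]] -
    aN[, 3] * xp[nbp[, 3]] - aN[, 4] * xp[nbp[, 4]] -
    aN[, 5] * xp[nbp[, 5]] - aN[, 6] * xp[nbp[, 6]]
}

btype_count <- function(btype, codes) {
  out <- 0
  for (cd in codes) out <- out + rowSums(btype == cd)
  out
}

# boundary velocity vectors (K x 6 normal speeds, outward positive, plus the
# full vector for momentum RHS) at time t (seconds)
boundary_velocity <- function(ctx, t) {
  ub_n <- matrix(0, ctx$K, 6)            # outward normal speed (m/s)
  ub_vec <- vector("list", 3)
  for (c in 1:3) ub_vec[[c]] <- matrix(0, ctx$K, 6)
  for (v in ctx$vel_patches) {
    speed <- cm_s_to_m_s(v$fun(t * 1000))  # cm/s -> m/s
    uu <- speed * v$w                      # per-face magnitude along nvec
    vecs <- uu * v$nvec
    edir_sign <- DIR_SGN[v$dirs]
    ax <- DIR_AXIS[v$dirs]
    nsp <- vecs[cbind(seq_along(ax), ax)] * edir_sign
    ub_n[cbind(v$cells, v$dirs)] <- nsp
    for (c in 1:3) {
      ub_vec[[c]][cbind(v$cells, v$dirs)] <- vecs[, c]
    }
  }
  list(n = ub_n, vec = ub_vec)
}

# Green-Gauss cell gradient of a cell scalar with boundary closure:
# zero-gradient at walls/velocity faces, zero value at zero-stress faces
green_gauss <- function(ctx, p) {
  g <- matrix(0, ctx$K, 3)
  pp <- c(p, 0)
  for (d in 1:6) {
    hn <- ctx$has_num[, d]
    pf <- (1 - 0.5 * hn) * p + 0.5 * hn * pp[ctx$nbp[, d]]
    pf <- pf * (1 - ctx$zmask[, d])
    ax <- DIR_AXIS[d]
    g[, ax] <- g[, ax] + DIR_SGN[d] * pf * ctx$A
  }
  g / ctx$V
}

# interior least-squares (central/one-sided difference) gradient of a cell
# field, linear-exact; used for the deferred second-order upwind correction
cell_gradient <- function(ctx, phi) {
  g <- matrix(0, ctx$K, 3)
  pp <- c(phi, 0)
  for (ax in 1:3) {
    dm <- 2L * ax - 1L; dp <- 2L * ax
    hm <- ctx$has_num[, dm]; hp <- ctx$has_num[, dp]
    vm <- (1 - hm) * phi + hm * pp[ctx$nbp[, dm]]
    vp <- (1 - hp) * phi + hp * pp[ctx$nbp[, dp]]
    den <- (hm + hp) * ctx$h
    den[den == 0] <- Inf
    g[, ax] <- (vp - vm) / den
  }
  g
}

# Rhie-Chow face fluxes (K x 6, outward positive, kg/s)
face_fluxes <- function(ctx, U, p, gp, ub, prev = NULL) {
  FL <- matrix(0, ctx$K, 6)
  for (px in ctx$pidx) {
    sel <- px$sel; Nn <- px$Nn
    ax <- DIR_AXIS[px$d]
    uf <- 0.5 * (U[sel, ax] + U[Nn, ax]) +
      px$drc * ((p[sel] - p[Nn]) / ctx$h + 0.5 * (gp[sel, ax] + gp[Nn, ax]))
    if (!is.null(prev)) {
      uf_prev <- prev$FL[px$liP] / (ctx$rho * ctx$A)
      ubar_prev <- 0.5 * (prev$U[sel, ax] + prev$U[Nn, ax])
      uf <- uf + px$beta * (uf_prev - ubar_prev)
    }
    FL[px$liP] <- ctx$rho * ctx$A * uf
    FL[px$liN] <- -ctx$rho * ctx$A * uf
  }
  # velocity faces: prescribed flux
  FL[ctx$vlin] <- ctx$rho * ctx$A * ub$n[ctx$vlin]
  # zero-stress faces: Rhie-Chow with p_face = 0 at half-cell distance
  zsel <- ctx$zarr
  if (nrow(zsel)) {
    zc <- zsel[, 1]; zd <- zsel[, 2]
    ax <- DIR_AXIS[zd]
    un <- U[cbind(zc, ax)] * DIR_SGN[zd]
    uf <- un + ctx$dRC[zc] * (p[zc] / (ctx$h / 2) +
                                DIR_SGN[zd] * gp[cbind(zc, ax)])
    if (!is.null(prev)) {
      beta_z <- ctx$betaP[zc]
      uf_prev <- prev$FL[ctx$zlin] / (ctx$rho * ctx$A)
      un_prev <- prev$U[cbind(zc, ax)] * DIR_SGN[zd]
      uf <- uf + beta_z * (uf_prev - un_prev)
    }
    FL[ctx$zlin] <- ctx$rho * ctx$A * uf
  }
  FL
}

# Jacobi-preconditioned BiCGSTAB on the 7-point stencil (matrix-free)
bicgstab <- function(amul, b, x, Mi, rtol = 1e-4, atol = 1e-300,
                     maxit = 300) {
  r <- b - amul(x)
  bnorm <- sqrt(sum(b^2))
  target <- max(rtol * bnorm, atol)
  if (sqrt(sum(r^2)) <= target) return(list(x = x, iters = 0))
  r0 <- r
  rho_old <- 1; alpha <- 1; omega <- 1
  v <- p <- numeric(length(b))
  for (it in seq_len(maxit)) {
    rho <- sum(r0 * r)
    if (abs(rho) < 1e-300) break
    beta <- (rho / rho_old) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    ph <- Mi * p
    v <- amul(ph)
    alpha <- rho / sum(r0 * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) <= target) {
      x <- x + alpha * ph
      return(list(x = x, iters = it))
    }
    sh <- Mi * s
    t <- amul(sh)
    omega <- sum(t * s) / max(sum(t * t), 1e-300)
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    if (sqrt(sum(r^2)) <= target) return(list(x = x, iters = it))
    rho_old <- rho
  }
  list(x = x, iters = maxit)
}

# One SIMPLE outer iteration: momentum predictor, pressure correction,
# velocity/flux/pressure update. Returns updated fields and residuals.
simple_iteration <- function(ctx, U, p, FLold, rhs_time, aP_time, ub,
                             prev = NULL, relax = TRUE) {
  K <- ctx$K; h <- ctx$h; A <- ctx$A; mu <- ctx$mu
  cfg <- ctx$config
  r_u <- if (ctx$steady) cfg$relax_u else cfg$relax_u_transient
  r_p <- if (ctx$steady) cfg$relax_p else cfg$relax_p_transient
  # upwind momentum coefficients from current fluxes (vectorized over K x 6)
  D <- mu * A / h
  Db <- mu * A / (h / 2)
  aN <- (D + pmax(-FLold, 0)) * ctx$has_num
  aPc <- aP_time + ctx$nDb * Db +
    rowSums((D + pmax(FLold, 0)) * ctx$has_num + pmax(FLold, 0) * ctx$zmask)
  gp <- green_gauss(ctx, p)
  resid <- numeric(3)
  Unew <- U
  sou <- cfg$convection == "second_order_upwind"
  mom_floor <- if (length(ctx$vlin)) {
    sum(abs(FLold[ctx$vlin])) * max(abs(ub$n[ctx$vlin]), 0)
  } else 0
  for (c in 1:3) {
    rhs <- rhs_time[, c] - gp[, c] * ctx$V
    ubc <- ub$vec[[c]]
    if (length(ctx$vlin)) {
      # diffusion to the prescribed face value + convected momentum flux
      add <- (Db - FLold[ctx$vlin]) * ubc[ctx$vlin]
      cellv <- ((ctx$vlin - 1L) %% K) + 1L
      rhs[cellv] <- rhs[cellv] + add
    }
    if (sou) {
      gphi <- cell_gradient(ctx, U[, c])
      for (px in ctx$pidx) {
        sel <- px$sel; Nn <- px$Nn
        ax <- DIR_AXIS[px$d]
        Fl <- FLold[px$liP]
        # phi_f(SOU) - phi_f(FOU) = grad_up . (x_f - x_up)
        dcorr <- ifelse(Fl >= 0, gphi[sel, ax], gphi[Nn, ax] * -1) * (h / 2)
        corr <- Fl * dcorr
        rhs[sel] <- rhs[sel] - corr
        nadd <- rowsum(corr, Nn, reorder = FALSE)
        rhs[as.integer(rownames(nadd))] <- rhs[as.integer(rownames(nadd))] +
          nadd[, 1]
      }
    }
    # scaled momentum residual of the unrelaxed system at the current field
    r <- rhs - fv_matvec(aPc, aN, ctx$nbp, U[, c])
    scale <- max(sum(abs(aPc * U[, c])), sum(abs(rhs)), mom_floor, 1e-30)
    resid[c] <- sum(abs(r)) / scale
    if (relax && r_u < 1) {
      aPr <- aPc / r_u
      rhs_r <- rhs + (aPr - aPc) * U[, c]
      sol <- bicgstab(function(x) fv_matvec(aPr, aN, ctx$nbp, x),
                      rhs_r, U[, c], 1 / aPr, rtol = 1e-7)
    } else {
      sol <- bicgstab(function(x) fv_matvec(aPc, aN, ctx$nbp, x),
                      rhs, U[, c], 1 / aPc, rtol = 1e-7)
    }
    Unew[, c] <- sol$x
  }
  # continuity: Rhie-Chow fluxes and pressure correction. A few corrector
  # sub-iterations (PISO-style) per momentum solve accelerate the mass
  # residual at the cost of cheap cached-Cholesky solves only.
  p_new <- p
  cont_res <- NA_real_
  imb0 <- NULL
  for (sub in seq_len(cfg$pressure_subiters)) {
    gps <- green_gauss(ctx, p_new)
    FL <- face_fluxes(ctx, Unew, p_new, gps, ub, prev)
    imb <- rowSums(FL)
    if (sub == 1) {
      inflow_scale <- sum(abs(FL[ctx$vlin]))
      cont_res <- if (inflow_scale > 1e-30) sum(abs(imb)) / inflow_scale else
        sum(abs(imb))
      imb0 <- imb
    }
    pc <- as.numeric(Matrix::solve(ctx$chol_M, -imb))
    p_new <- p_new + r_p * pc
    gpc <- green_gauss_pc(ctx, pc)
    Unew <- Unew - ctx$dP * gpc
    for (px in ctx$pidx) {
      dF <- ctx$rho * ctx$A * px$df * (pc[px$sel] - pc[px$Nn]) / h
      FL[px$liP] <- FL[px$liP] + dF
      FL[px$liN] <- FL[px$liN] - dF
    }
    if (nrow(ctx$zarr)) {
      zc <- ctx$zarr[, 1]
      FL[ctx$zlin] <- FL[ctx$zlin] + ctx$rho * ctx$A * ctx$dP[zc] * pc[zc] /
        (h / 2)
    }
  }
  list(U = Unew, p = p_new, FL = FL,
       resid = c(resid, cont_res), imbalance = imb0)
}

# gradient of the pressure correction: p'_face = 0 on zero-stress faces,
# zero-gradient elsewhere on the boundary
green_gauss_pc <- green_gauss

#' Advance the flow state by one implicit time step
#'
#' Runs SIMPLE inner iterations until all scaled residuals (x-, y-,
#' z-momentum and continuity) fall below their tolerances or `max_inner` is
#' reached (the step is then flagged non-converged). Exposed mainly for
#' testing; [solve_pulsatile()] drives it.
#'
#' @param state list with `U` (K x 3 m/s), `p` (Pa, gauge), `U_n`, `U_nm1`
#'   (previous steps; `NULL` at start), `FL` (face fluxes).
#' @param ctx solver context from the internal builder (see
#'   [solve_pulsatile()]); or pass `mesh`, `bcs`, `props`, `config` to have
#'   one built.
#' @param t_new new time (s).
#' @param mesh,bcs,props,config used when `ctx` is `NULL`.
#' @return Updated state with `residuals` (x, y, z, continuity), `converged`,
#'   `inner_iterations`.
#' @export
simple_step <- function(state, t_new, ctx = NULL, mesh = NULL, bcs = NULL,
                        props = NULL, config = NULL) {
  if (is.null(ctx)) {
    ctx <- build_context(mesh, bcs, props, config)
  }
  cfg <- ctx$config
  K <- ctx$K
  dt <- cfg$dt_ms / 1000
  rhoV <- ctx$rho * ctx$V
  if (is.null(state$U)) state$U <- matrix(0, K, 3)
  if (is.null(state$p)) state$p <- numeric(K)
  # state$U is u^n (the newest solved level), state$U_n is u^{n-1}
  bdf2 <- !is.null(state$U_n)
  if (ctx$steady) {
    aP_time <- numeric(K)
    rhs_time <- matrix(0, K, 3)
  } else if (bdf2) {
    aP_time <- rep(rhoV * 1.5 / dt, K)
    rhs_time <- rhoV * (2 * state$U - 0.5 * state$U_n) / dt
  } else {
    aP_time <- rep(rhoV / dt, K)
    rhs_time <- rhoV * state$U / dt
  }
  ub <- boundary_velocity(ctx, t_new)
  prev <- if (!is.null(state$FL) && !ctx$steady) {
    list(FL = state$FL, U = state$U)
  } else NULL
  # second-order predictor as the initial guess for the coupled iteration
  if (bdf2) {
    U <- 2 * state$U - state$U_n
    p <- if (!is.null(state$p_n)) 2 * state$p - state$p_n else state$p
  } else {
    U <- state$U; p <- state$p
  }
  gp <- green_gauss(ctx, p)
  FL <- face_fluxes(ctx, U, p, gp, ub, prev)
  residuals <- c(Inf, Inf, Inf, Inf)
  iters <- 0L
  for (it in seq_len(cfg$max_inner)) {
    out <- simple_iteration(ctx, U, p, FL, rhs_time, aP_time, ub, prev)
    U <- out$U; p <- out$p; FL <- out$FL
    residuals <- out$resid
    iters <- it
    if (all(residuals[1:3] <= cfg$tol) && residuals[4] <= cfg$tol_total) break
  }
  list(U = U, p = p, FL = FL,
       U_n = state$U, p_n = state$p,
       residuals = residuals,
       converged = all(residuals[1:3] <= cfg$tol) &&
         residuals[4] <= cfg$tol_total,
       inner_iterations = iters,
       imbalance = out$imbalance)
}

#' Solve pulsatile flow over repeated cardiac cycles
#'
#' Runs `config$cycles` cycles from a quiescent start (zero velocity,
#' reference pressure) and returns fields stored over the final cycle only,
#' along with per-step residual history and the cycle-to-cycle periodicity
#' error (relative L2 difference of the end-of-cycle velocity between the
#' last two cycles).
#'
#' @param mesh a [mesh_volume()] mesh.
#' @param bcs a [boundary_spec()].
#' @param props a [fluid_props()].
#' @param config a [solver_config()].
#' @param quiet suppress progress output.
#' @return An object of class `field_series`: `times` (s, relative to the
#'   final cycle start, spanning `[0, period]`), `U` (list of K x 3 m/s),
#'   `p` (list, Pa gauge), `mesh`, `residual_history`, `periodicity_error`,
#'   `converged_all`, `inlet_waveform`.
#' @export
solve_pulsatile <- function(mesh, bcs, props = fluid_props(),
                            config = solver_config(), quiet = TRUE) {
  ctx <- build_context(mesh, bcs, props, config)
  vel_idx <- which(vapply(bcs, function(b) b$type == "velocity", logical(1)))
  if (!length(vel_idx)) {
    abort("pulsatile solve needs at least one velocity boundary",
          "avflow_config_error")
  }
  inlets <- vel_idx[vapply(bcs[vel_idx], function(b) b$direction == "in",
                           logical(1))]
  inlet_wf <- bcs[[if (length(inlets)) inlets[1] else vel_idx[1]]]$waveform
  period <- inlet_wf$period / 1000
  dt <- config$dt_ms / 1000
  nstep <- max(1L, round(period / dt))
  state <- list(U = matrix(0, ctx$K, 3), p = numeric(ctx$K))
  res_hist <- list()
  cyc_end <- list()
  times <- numeric(0); Us <- list(); ps <- list(); flux_bal <- list()
  for (cyc in seq_len(config$cycles)) {
    final <- cyc == config$cycles
    if (final) {
      times <- 0; Us <- list(state$U); ps <- list(state$p)
    }
    for (k in seq_len(nstep)) {
      t_new <- (cyc - 1) * period + k * dt
      state <- simple_step(state, t_new, ctx = ctx)
      res_hist[[length(res_hist) + 1]] <- c(
        cycle = cyc, step = k, state$residuals,
        converged = as.numeric(state$converged))
      if (final && (k %% config$store_every == 0 || k == nstep)) {
        times <- c(times, k * dt)
        Us[[length(Us) + 1]] <- state$U
        ps[[length(ps) + 1]] <- state$p
        boundary <- ctx$btype > 0L
        flux_bal[[length(flux_bal) + 1]] <- c(
          time = k * dt,
          net_boundary_flux = sum(state$FL[boundary]),
          inflow_scale = sum(abs(state$FL[ctx$vlin])))
      }
      if (!quiet && k %% 50 == 0) {
        message(sprintf("cycle %d step %d/%d resid %.2e", cyc, k, nstep,
                        max(state$residuals)))
      }
    }
    cyc_end[[cyc]] <- state$U
  }
  periodicity <- NA_real_
  if (config$cycles >= 2) {
    a <- cyc_end[[config$cycles]]; b <- cyc_end[[config$cycles - 1]]
    periodicity <- sqrt(sum((a - b)^2)) / max(sqrt(sum(a^2)), 1e-30)
  }
  rh <- do.call(rbind, res_hist)
  colnames(rh) <- c("cycle", "step", "res_x", "res_y", "res_z",
                    "res_continuity", "converged")
  structure(list(times = times, U = Us, p = ps, mesh = mesh,
                 residual_history = as.data.frame(rh),
                 boundary_flux = as.data.frame(do.call(rbind, flux_bal)),
                 periodicity_error = periodicity,
                 converged_all = all(rh[, "converged"] == 1),
                 inlet_waveform = inlet_wf,
                 props = props, config = config),
            class = "field_series")
}

#' @method print field_series
#' @export
print.field_series <- function(x, ...) {
  cat(sprintf(
    "field_series: %d stored steps over %.3g ms, periodicity err %.2e\n",
    length(x$times), 1000 * diff(range(x$times)), x$periodicity_error))
  invisible(x)
}

#' Solve steady flow
#'
#' SIMPLE iteration without time terms, with boundary waveforms evaluated at
#' `t_eval`. Used for steady benchmarks (Poiseuille) and as the steady limit
#' of the pulsatile solver.
#'
#' @inheritParams solve_pulsatile
#' @param t_eval time (s) at which waveforms are evaluated.
#' @return A single-snapshot `field_series`.
#' @export
solve_steady <- function(mesh, bcs, props = fluid_props(),
                         config = solver_config(), t_eval = 0,
                         quiet = TRUE) {
  ctx <- build_context(mesh, bcs, props, config, steady = TRUE)
  K <- ctx$K
  ub <- boundary_velocity(ctx, t_eval)
  U <- matrix(0, K, 3); p <- numeric(K)
  gp <- green_gauss(ctx, p)
  FL <- face_fluxes(ctx, U, p, gp, ub)
  vsel <- which(ctx$btype == 2L)
  FL[vsel] <- ctx$rho * ctx$A * ub$n[vsel]
  aP_time <- numeric(K)
  rhs_time <- matrix(0, K, 3)
  res <- c(Inf, Inf, Inf, Inf)
  hist <- list()
  for (it in seq_len(ctx$config$max_steady_iter)) {
    out <- simple_iteration(ctx, U, p, FL, rhs_time, aP_time, ub)
    U <- out$U; p <- out$p; FL <- out$FL
    res <- out$resid
    hist[[it]] <- res
    if (!quiet && it %% 100 == 0) {
      message(sprintf("steady iter %d resid %.2e", it, max(res)))
    }
    if (all(res[1:3] <= ctx$config$tol) &&
        res[4] <= ctx$config$tol_total) break
  }
  rh <- do.call(rbind, hist)
  colnames(rh) <- c("res_x", "res_y", "res_z", "res_continuity")
  structure(list(times = 0, U = list(U), p = list(p), mesh = mesh,
                 residual_history = as.data.frame(rh),
                 periodicity_error = 0,
                 converged_all = all(res[1:3] <= ctx$config$tol) &&
                   res[4] <= ctx$config$tol_total,
                 inlet_waveform = NULL, props = props, config = ctx$config),
            class = "field_series")
}

# -- Womersley analytic reference ---------------------------------------------

# complex Bessel J0/J1 by power series (adequate for |z| <~ 15, i.e. alpha
# well beyond the murine range)
cbessel_j0 <- function(z) {
  term <- complex(real = rep(1, length(z)))
  s <- term
  for (k in 1:40) {
    term <- term * (-(z / 2)^2) / k^2
    s <- s + term
  }
  s
}

cbessel_j1 <- function(z) {
  term <- z / 2
  s <- term
  for (k in 1:40) {
    term <- term * (-(z / 2)^2) / (k * (k + 1))
    s <- s + term
  }
  s
}

#' Analytic Womersley solution for oscillatory tube flow
#'
#' Fully developed laminar flow in a rigid circular tube driven by an
#' oscillatory pressure gradient `G cos(omega t)` (Pa/m amplitude). Returns
#' the Womersley number `alpha = R sqrt(omega rho / mu)` and evaluator
#' functions for the velocity profile.
#'
#' @param props a [fluid_props()].
#' @param radius tube radius (m).
#' @param angular_frequency omega (rad/s).
#' @param pressure_amplitude G (Pa/m).
#' @return list with `alpha`, `u(r, t)` (m/s), and `mean_velocity(t)`
#'   (cross-section average, m/s).
#' @export
womersley_reference <- function(props, radius, angular_frequency,
                                pressure_amplitude) {
  stopifnot(radius > 0, angular_frequency > 0)
  rho <- props$density; mu <- props$viscosity
  omega <- angular_frequency
  alpha <- radius * sqrt(omega * rho / mu)
  beta <- complex(real = -1 / sqrt(2), imaginary = 1 / sqrt(2)) * alpha
  # u_hat(r) = (i G / (rho omega)) (1 - J0(beta r/R)/J0(beta)), u = Re[u_hat e^{i w t}]
  G <- pressure_amplitude
  j0b <- cbessel_j0(beta)
  coef <- 1i * G / (rho * omega)
  u <- function(r, t) {
    prof <- coef * (1 - cbessel_j0(beta * r / radius) / j0b)
    Re(outer(prof, exp(1i * omega * t)))
  }
  mean_hat <- coef * (1 - 2 * cbessel_j1(beta) / (beta * j0b))
  mean_velocity <- function(t) Re(mean_hat * exp(1i * omega * t))
  list(alpha = alpha, u = u, mean_velocity = mean_velocity,
       radius = radius, omega = omega)
}

#' Womersley velocity profile for a prescribed sinusoidal mean velocity
#'
#' Convenience oracle: the analytic profile whose instantaneous
#' cross-section-averaged velocity equals
#' `U0 + U1 sin(omega t)`, combining steady Poiseuille (for `U0`) with the
#' oscillatory Womersley component (for `U1`).
#'
#' @param props a [fluid_props()].
#' @param radius tube radius (m).
#' @param period cycle length (s).
#' @param U0 steady mean velocity (m/s).
#' @param U1 oscillatory mean-velocity amplitude (m/s).
#' @return function `u(r, t)` (m/s) plus attribute `"alpha"`.
#' @export
womersley_profile_from_mean <- function(props, radius, period, U0, U1) {
  omega <- 2 * pi / period
  alpha <- radius * sqrt(omega * props$density / props$viscosity)
  beta <- complex(real = -1 / sqrt(2), imaginary = 1 / sqrt(2)) * alpha
  j0b <- cbessel_j0(beta)
  denom_mean <- 1 - 2 * cbessel_j1(beta) / (beta * j0b)
  fn <- function(r, t) {
    steady <- 2 * U0 * (1 - (r / radius)^2)
    prof <- (1 - cbessel_j0(beta * r / radius) / j0b) / denom_mean
    osc <- Re(outer(prof, -1i * U1 * exp(1i * omega * t)))
    sweep(osc, 1, steady, "+")
  }
  attr(fn, "alpha") <- alpha
  fn
}
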