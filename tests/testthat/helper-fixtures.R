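# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tube_surface_05 <- function() {
  fixture("tube_surface_05", function() {
    generate_phantom_surface(tube_spec(0.5, 5))
  })
}

tube_mesh_05 <- function() {
  fixture("tube_mesh_05", function() mesh_volume(tube_surface_05(), 0.1))
}

tube_surface_07 <- function() {
  fixture("tube_surface_07", function() {
    generate_phantom_surface(tube_spec(0.7, 5))
  })
}

poiseuille_bcs <- function(v_cm_s = 10) {
  boundary_spec(inlet = velocity_bc(make_waveform(rep(v_cm_s, 8)), "in"),
                outlet = zero_stress_bc(),
                wall = no_slip_bc())
}

# steady Poiseuille solution on the R = 0.5 mm tube (used by several files)
poiseuille_solution <- function() {
  fixture("poiseuille_solution", function() {
    solve_steady(tube_mesh_05(), poiseuille_bcs(), fluid_props(),
                 solver_config())
  })
}

# pulsatile Womersley benchmark: sinusoidal mean velocity 10 + 5 sin
# (cm/s) over a 120 ms cycle in an R = 0.5 mm, L = 3 mm tube
womersley_case <- function() {
  fixture("womersley_case", function() {
    surf <- generate_phantom_surface(tube_spec(0.5, 3), resolution = 0.05)
    mesh <- mesh_volume(surf, 0.1)
    wf <- make_waveform(10 + 5 * sin(2 * pi * (0:7) / 8), period_ms = 120)
    bcs <- boundary_spec(inlet = velocity_bc(wf, "in"),
                         outlet = zero_stress_bc(), wall = no_slip_bc())
    cfg <- solver_config(dt_ms = 0.5, cycles = 3, store_every = 12)
    fs <- solve_pulsatile(mesh, bcs, fluid_props(), cfg)
    list(surface = surf, mesh = mesh, waveform = wf, bcs = bcs,
         config = cfg, fs = fs)
  })
}

# analytic Poiseuille velocity sampled at the cell centers of a tube mesh
poiseuille_field <- function(mesh, U = 0.1, R = 0.5e-3) {
  cm <- mesh$centers
  yb <- mean(cm[, 2]); zb <- mean(cm[, 3])
  r2 <- (cm[, 2] - yb)^2 + (cm[, 3] - zb)^2
  cbind(2 * U * pmax(1 - r2 / R^2, 0), 0, 0)
}

# a synthetic wall-shear series on one face, for the OSI limit checks
single_face_series <- function(times, tau_x) {
  structure(list(
    times = times,
    tau = lapply(tau_x, function(v) matrix(c(v, 0, 0), 1)),
    centers = matrix(0, 1, 3), normals = matrix(c(0, 0, 1), 1),
    areas = 1, faces = 1L, cells = 1L, mesh = NULL),
    class = "wall_shear_series")
}

# cylinder voxel mask with a generic (non-lattice-aligned) axis offset
cylinder_mask <- function(r = 0.7, L = 5, h = 0.1, hz = h,
                          off = c(0.033, 0.071)) {
  ax <- list(seq(-r - 0.4, r + 0.4, by = h) + off[1],
             seq(-r - 0.4, r + 0.4, by = h) + off[2],
             seq(-0.5, L + 0.5, by = hz))
  g <- expand.grid(ax[[1]], ax[[2]], ax[[3]])
  m <- array(sqrt(g[, 1]^2 + g[, 2]^2) < r & g[, 3] > 0 & g[, 3] < L,
             vapply(ax, length, integer(1)))
  lumen_mask(m, c(h, h, hz), vapply(ax, min, numeric(1)))
}
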