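test_that("Reynolds number follows rho U D / mu with a laminar warning", {
  props <- fluid_props()
  expect_equal(reynolds_number(props, 0.1, 1e-3), 30)
  expect_equal(reynolds_number(props, 0, 1e-3), 0)
  expect_equal(reynolds_number(props, 0.2, 2e-3),
               4 * reynolds_number(props, 0.1, 1e-3))
  expect_warning(reynolds_number(props, 10, 1e-2), "laminar")
})

test_that("zero inflow keeps the null solution at round-off", {
  surf <- generate_phantom_surface(tube_spec(0.5, 2), resolution = 0.08)
  mesh <- mesh_volume(surf, 0.2)
  bcs <- boundary_spec(inlet = velocity_bc(make_waveform(rep(0, 8)), "in"),
                       outlet = zero_stress_bc(), wall = no_slip_bc())
  ctx <- avflow:::build_context(mesh, bcs, fluid_props(),
                                solver_config(dt_ms = 0.5))
  state <- list(U = matrix(0, ctx$K, 3), p = numeric(ctx$K))
  for (k in 1:3) state <- simple_step(state, k * 5e-4, ctx = ctx)
  expect_lt(max(abs(state$U)), 1e-12)
  expect_true(state$converged)
})

test_that("steady plug inflow develops the Poiseuille centerline velocity", {
  fs <- poiseuille_solution()
  expect_true(fs$converged_all)
  mesh <- fs$mesh
  cm <- mesh$centers
  ctr <- c(mean(cm[, 2]), mean(cm[, 3]))
  r <- sqrt((cm[, 2] - ctr[1])^2 + (cm[, 3] - ctr[2])^2)
  # mid-tube, beyond the entrance length
  sel <- abs(cm[, 1] - 3e-3) < 2.6e-4 & r < 0.8e-4
  expect_lt(abs(mean(fs$U[[1]][sel, 1]) / 0.2 - 1), 0.05)
})

test_that("converged steps satisfy discrete continuity", {
  fs <- poiseuille_solution()
  last <- utils::tail(fs$residual_history, 1)
  expect_lte(last$res_continuity, 1e-5)
  # recompute the cell imbalance from the final state directly
  mesh <- fs$mesh
  bcs <- poiseuille_bcs()
  ctx <- avflow:::build_context(mesh, bcs, fluid_props(), solver_config(),
                                steady = TRUE)
  ub <- avflow:::boundary_velocity(ctx, 0)
  gp <- avflow:::green_gauss(ctx, fs$p[[1]])
  FL <- avflow:::face_fluxes(ctx, fs$U[[1]], fs$p[[1]], gp, ub)
  inflow <- sum(abs(FL[ctx$btype == 2L]))
  expect_lt(sum(abs(rowSums(FL))) / inflow, 1e-4)
  # net boundary flux (inlet vs all outlets) balances
  net <- sum(FL[ctx$btype > 1L])
  expect_lt(abs(net) / inflow, 1e-5)
})

test_that("a constant waveform reproduces the steady solution", {
  surf <- generate_phantom_surface(tube_spec(0.5, 2), resolution = 0.08)
  mesh <- mesh_volume(surf, 0.2)
  bcs <- boundary_spec(inlet = velocity_bc(make_waveform(rep(10, 8),
                                                         period_ms = 120),
                                           "in"),
                       outlet = zero_stress_bc(), wall = no_slip_bc())
  cfg <- solver_config(dt_ms = 1, cycles = 2, store_every = 60)
  fs <- solve_pulsatile(mesh, bcs, fluid_props(), cfg)
  st <- solve_steady(mesh, bcs, fluid_props(), solver_config())
  rel <- sqrt(sum((fs$U[[length(fs$U)]] - st$U[[1]])^2)) /
    sqrt(sum(st$U[[1]]^2))
  expect_lt(rel, 0.01)
  expect_lt(fs$periodicity_error, 0.01)
})

test_that("a 120 ms cycle at 0.1 ms steps takes exactly 1200 steps", {
  wf <- make_waveform(rep(1, 8), period_ms = 120)
  period_s <- wf$period / 1000
  cfg <- solver_config(dt_ms = 0.1)
  expect_equal(round(period_s / (cfg$dt_ms / 1000)), 1200)
  # and the 8 x 16 ms native acquisition window gives 1280
  expect_equal(round(make_waveform(rep(1, 8))$period / cfg$dt_ms), 1280)
})

test_that("the pulsatile solve matches the analytic Womersley profile", {
  wc <- womersley_case()
  fs <- wc$fs
  expect_true(fs$converged_all)
  props <- fluid_props()
  uan <- womersley_profile_from_mean(props, 0.5e-3, 0.12, 0.1, 0.05)
  expect_lt(abs(attr(uan, "alpha") - 1.98), 0.01)
  cm <- wc$mesh$centers
  ctr <- c(mean(cm[, 2]), mean(cm[, 3]))
  mid <- abs(cm[, 1] - 1.5e-3) < wc$mesh$h * 0.51
  r <- sqrt((cm[mid, 2] - ctr[1])^2 + (cm[mid, 3] - ctr[2])^2)
  num <- 0; den <- 0
  for (i in seq_along(fs$times)) {
    ua <- uan(r, fs$times[i])[, 1]
    us <- fs$U[[i]][mid, 1]
    num <- num + sum((us - ua)^2)
    den <- den + sum(ua^2)
  }
  expect_lt(sqrt(num / den), 0.05)
})

test_that("cycle-to-cycle periodicity supports reporting the final cycle", {
  wc <- womersley_case()
  expect_lt(wc$fs$periodicity_error, 0.01)
})

test_that("the Womersley reference has the right limits", {
  props <- fluid_props()
  ref <- womersley_reference(props, 0.5e-3, 2 * pi / 0.12, 100)
  expect_lt(abs(ref$alpha - 1.98), 0.01)
  # no-slip at the wall for all times
  tt <- seq(0, 0.12, length.out = 7)
  expect_true(all(abs(ref$u(0.5e-3, tt)) < 1e-12))
  # quasi-steady limit: at alpha = 0.1 the profile is parabolic within 1%
  omega_small <- (0.1 / 0.5e-3)^2 * props$viscosity / props$density
  slow <- womersley_reference(props, 0.5e-3, omega_small, 100)
  r <- seq(0, 0.5e-3, length.out = 21)
  prof <- slow$u(r, 0)[, 1]
  parab <- prof[1] * (1 - (r / 0.5e-3)^2)
  expect_lt(max(abs(prof - parab)) / max(abs(prof)), 0.01)
})

test_that("halving the time step shrinks the Womersley error at order >= 1.5", {
  # fixed coarse mesh, dt sweep; errors measured against the analytic profile
  surf <- generate_phantom_surface(tube_spec(0.5, 2), resolution = 0.08)
  mesh <- mesh_volume(surf, 0.2)
  wf <- make_waveform(10 + 5 * sin(2 * pi * (0:7) / 8), period_ms = 120)
  bcs <- boundary_spec(inlet = velocity_bc(wf, "in"),
                       outlet = zero_stress_bc(), wall = no_slip_bc())
  props <- fluid_props()
  uan <- womersley_profile_from_mean(props, 0.5e-3, 0.12, 0.1, 0.05)
  cm <- mesh$centers
  ctr <- c(mean(cm[, 2]), mean(cm[, 3]))
  mid <- abs(cm[, 1] - 1e-3) < mesh$h * 0.51
  r <- sqrt((cm[mid, 2] - ctr[1])^2 + (cm[mid, 3] - ctr[2])^2)
  snaps <- lapply(c(4, 2, 1), function(dt) {
    cfg <- solver_config(dt_ms = dt, cycles = 3, store_every = 1e9)
    fs <- solve_pulsatile(mesh, bcs, props, cfg)
    fs$U[[length(fs$U)]]  # end-of-cycle snapshot, same physical time for all
  })
  # Richardson-style: solution differences against the finest dt shrink with
  # the temporal order p as (4^p - 1) / (2^p - 1); p >= 1.5 gives >= 3.8
  d41 <- sqrt(sum((snaps[[1]] - snaps[[3]])^2))
  d21 <- sqrt(sum((snaps[[2]] - snaps[[3]])^2))
  expect_gt(d41 / max(d21, 1e-300), (4^1.5 - 1) / (2^1.5 - 1))
  # sanity: the analytic profile is still matched at the coarse settings
  ua <- uan(r, 0.12)[, 1]
  expect_lt(sqrt(sum((snaps[[3]][mid, 1] - ua)^2) / sum(ua^2)), 0.12)
})
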