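test_that("eight 16 ms frames make a 128 ms period", {
  wf <- make_waveform(rep(5, 8))
  expect_equal(wf$period, 128)
  expect_equal(wf$frame_times, (0:7) * 16)
})

test_that("the 120 ms override rescales frame times proportionally", {
  wf <- make_waveform(rep(5, 8), period_ms = 120)
  expect_equal(wf$period, 120)
  expect_equal(wf$frame_times, (0:7) * 15)
})

test_that("the cycle mean uses periodic trapezoid quadrature", {
  wf <- make_waveform(c(10, 20, 30, 20, 10, 5, 5, 10))
  expect_equal(waveform_mean(wf), 13.75)
})

test_that("resampling is exact at frames, periodic, and constant-preserving", {
  wf <- make_waveform(c(10, 20, 30, 20, 10, 5, 5, 10))
  rs <- resample_waveform(wf, 0.1)
  expect_equal(length(rs$t_ms), 1280)
  expect_equal(rs$fun(wf$frame_times), wf$values, tolerance = 1e-10)
  ts <- c(3.7, 50.1, 101.9)
  expect_equal(rs$fun(ts), rs$fun(ts + wf$period), tolerance = 1e-12)
  wc <- make_waveform(rep(7, 8))
  expect_true(all(abs(resample_waveform(wc, 0.1)$v_cm_s - 7) < 1e-10))
})

test_that("a single-harmonic sinusoid is recovered to within 1%", {
  f <- function(t) 10 + 4 * sin(2 * pi * t / 128)
  wf <- make_waveform(f((0:7) * 16))
  rs <- resample_waveform(wf, 0.1)
  err <- max(abs(rs$v_cm_s - f(rs$t_ms)))
  expect_lt(err / max(abs(f(rs$t_ms))), 0.01)
})

test_that("invalid waveforms are rejected", {
  expect_error(make_waveform(c(1, NA, 3)), class = "avflow_validation_error")
  expect_error(make_waveform(5), class = "avflow_validation_error")
  wf <- make_waveform(rep(5, 8))
  expect_error(resample_waveform(wf, 200), class = "avflow_resolution_error")
})

test_that("inlet profiles reproduce the mean exactly for both shapes", {
  mesh <- tube_mesh_05()
  for (shape in c("plug", "parabolic")) {
    prof <- inlet_velocity_profile(10, mesh, "inlet", shape)
    area_mean <- sum(prof$normal_speed * mesh$faces$area[prof$faces]) /
      sum(mesh$faces$area[prof$faces])
    expect_equal(area_mean, 0.1, tolerance = 1e-12)
  }
  expect_true(all(abs(inlet_velocity_profile(10, mesh, "inlet",
                                             "plug")$normal_speed - 0.1) <
                    1e-12))
  # parabolic: near-axis face speed approaches twice the mean
  par <- inlet_velocity_profile(10, mesh, "inlet", "parabolic")
  fc <- mesh$faces$center[par$faces, ]
  ctr <- colMeans(fc)
  r <- sqrt((fc[, 2] - ctr[2])^2 + (fc[, 3] - ctr[3])^2)
  expect_gt(par$normal_speed[which.min(r)], 2 * 0.1 * 0.8)
  expect_lt(par$normal_speed[which.min(r)], 2 * 0.1 * 1.2)
})

test_that("prescribed outlets exceeding the inlet are a configuration error", {
  w_in <- make_waveform(rep(10, 8))
  w_out <- make_waveform(rep(20, 8))
  surf <- generate_phantom_surface(avf_phantom_spec(), resolution = 0.09)
  m2 <- mesh_volume(surf, 0.16)
  bad <- boundary_spec(
    inlet = velocity_bc(w_in, "in"),
    outlet_vein = velocity_bc(w_out, "out"),
    outlet_branch = velocity_bc(make_waveform(rep(1, 8)), "out"),
    outlet_artery = zero_stress_bc(),
    wall = no_slip_bc())
  expect_error(solve_pulsatile(m2, bad), class = "avflow_config_error")
  ok <- boundary_spec(
    inlet = velocity_bc(w_in, "in"),
    outlet_vein = velocity_bc(make_waveform(rep(0.5, 8)), "out"),
    outlet_branch = velocity_bc(make_waveform(rep(0.5, 8)), "out"),
    outlet_artery = zero_stress_bc(),
    wall = no_slip_bc())
  expect_silent(avflow:::build_context(m2, ok, fluid_props(),
                                       solver_config()))
})

test_that("boundary specs enforce the single zero-stress rule", {
  w <- make_waveform(rep(5, 8))
  expect_error(boundary_spec(inlet = velocity_bc(w, "in"),
                             wall = no_slip_bc()),
               class = "avflow_config_error")
  expect_error(boundary_spec(a = zero_stress_bc(), b = zero_stress_bc(),
                             wall = no_slip_bc()),
               class = "avflow_config_error")
  w2 <- make_waveform(rep(5, 8), period_ms = 100)
  expect_error(boundary_spec(inlet = velocity_bc(w, "in"),
                             out2 = velocity_bc(w2, "out"),
                             outlet = zero_stress_bc(),
                             wall = no_slip_bc()),
               class = "avflow_config_error")
})
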