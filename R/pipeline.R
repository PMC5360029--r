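# End-to-end orchestration and mesh / time-step independence protocols.

#' Run the full phantom-to-hemodynamics pipeline
#'
#' Executes segmentation (optional image route), surface reconstruction,
#' volume meshing, the pulsatile solve, wall and volumetric metrics, and the
#' cross-sectional area profile, writing all artifacts plus a run manifest.
#'
#' @param config a named list (or path to a JSON file) with sections:
#'   \describe{
#'     \item{phantom}{`list(type = "tube"|"avf", ...)` arguments passed to
#'       [tube_spec()] / [avf_phantom_spec()].}
#'     \item{route}{`"surface"` (analytic surface; default) or `"image"`
#'       (synthetic black-blood stack, segmentation, reconstruction).}
#'     \item{image}{for the image route: `spacing`, `noise_sd`, `seed`,
#'       `threshold`.}
#'     \item{mesh}{`list(edge_length = <mm>)`.}
#'     \item{waveforms}{named per-patch lists with `values` (cm/s),
#'       `frame_spacing_ms`, `period_ms`, `direction` (`"in"`/`"out"`); the
#'       patch named in `zero_stress` gets the traction-free condition.}
#'     \item{zero_stress}{patch name of the traction-free outlet.}
#'     \item{props}{arguments to [fluid_props()].}
#'     \item{solver}{arguments to [solver_config()].}
#'     \item{out_dir}{output directory.}
#'   }
#' @return A run manifest (list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  t_start <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")
  # -- validation before any compute
  for (key in c("phantom", "mesh", "waveforms", "zero_stress", "out_dir")) {
    if (is.null(config[[key]])) {
      abort(sprintf("pipeline config is missing '%s'", key),
            "avflow_validation_error")
    }
  }
  if (length(config$waveforms) == 0) {
    abort("no inlet/outlet waveforms configured", "avflow_validation_error")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(switch(config$phantom$type, tube = tube_spec,
                         avf = avf_phantom_spec,
                         torus = torus_spec),
                  config$phantom[setdiff(names(config$phantom), "type")])
  route <- config$route %||% "surface"
  t0 <- tic()
  if (route == "image") {
    img <- generate_phantom_image(
      spec, spacing = config$image$spacing %||% c(0.1, 0.1, 0.5),
      noise_sd = config$image$noise_sd %||% 0,
      seed = config$image$seed %||% 1)
    dims <- dim(img$intensities)
    mask <- segment_lumen(img, round(dims / 2),
                          config$image$threshold %||% 60)
    surface <- extract_surface(pad_mask(mask))
    # openings are not labeled on an image-derived surface; borrow the caps
    # of the analytic spec
    ref <- generate_phantom_surface(spec)
    surface$patches <- transfer_patches(ref, surface)
  } else {
    surface <- generate_phantom_surface(spec)
  }
  timings$geometry <- toc(t0)
  t0 <- tic()
  mesh <- mesh_volume(surface, config$mesh$edge_length)
  timings$meshing <- toc(t0)
  t0 <- tic()
  cl <- extract_centerline(surface)
  profile <- area_profile(cl, surface)
  timings$centerline <- toc(t0)
  # -- boundary conditions
  conds <- list()
  for (nm in names(config$waveforms)) {
    wfc <- config$waveforms[[nm]]
    wf <- make_waveform(wfc$values,
                        frame_spacing_ms = wfc$frame_spacing_ms %||% 16,
                        period_ms = wfc$period_ms,
                        location = wfc$location %||% nm)
    conds[[nm]] <- velocity_bc(wf, wfc$direction %||% "in")
  }
  conds[[config$zero_stress]] <- zero_stress_bc()
  conds$wall <- no_slip_bc()
  bcs <- do.call(boundary_spec, conds)
  props <- do.call(fluid_props, config$props %||% list())
  scfg <- do.call(solver_config, config$solver %||% list())
  t0 <- tic()
  fs <- solve_pulsatile(mesh, bcs, props, scfg)
  timings$solve <- toc(t0)
  t0 <- tic()
  shear <- wall_shear_vectors(fs)
  wss_avg <- cycle_average(wss_magnitude(shear), fs$inlet_waveform)
  wssg_avg <- cycle_average(wssg(shear), fs$inlet_waveform)
  osi_map <- osi(shear)
  vort <- cycle_average(vorticity(fs))
  heli <- cycle_average(helicity(fs))
  qcrit <- cycle_average(q_criterion(fs))
  timings$metrics <- toc(t0)
  # Poiseuille-style sanity: domain peak velocity and Reynolds number
  peak_u <- max(vapply(fs$U, function(u) max(sqrt(rowSums(u^2))), numeric(1)))
  re <- reynolds_number(props, peak_u,
                        2 * min(vapply(mesh$patch_info, function(p) p$radius,
                                       numeric(1))))
  # -- outputs
  paths <- list(
    surface = file.path(out_dir, "lumen_surface.stl"),
    patches = file.path(out_dir, "lumen_surface.patches.json"),
    mesh = file.path(out_dir, "volume_mesh.vtk"),
    area = file.path(out_dir, "area_profile.csv"),
    wall = file.path(out_dir, "wall_metrics.csv"),
    volume = file.path(out_dir, "volume_metrics.csv"),
    residuals = file.path(out_dir, "residuals.csv"))
  write_stl(surface, paths$surface)
  write_patches(surface$patches, paths$patches)
  write_area_profile(profile, paths$area)
  wall_df <- data.frame(
    x_mm = m_to_mm(wss_avg$centers[, 1]),
    y_mm = m_to_mm(wss_avg$centers[, 2]),
    z_mm = m_to_mm(wss_avg$centers[, 3]),
    wss_dyne_cm2 = wss_avg$values[, 1],
    wssg_dyne_cm3 = wssg_avg$values[, 1],
    osi = osi_map$values[, 1])
  utils::write.csv(wall_df, paths$wall, row.names = FALSE)
  vol_df <- data.frame(
    x_mm = m_to_mm(mesh$centers[, 1]),
    y_mm = m_to_mm(mesh$centers[, 2]),
    z_mm = m_to_mm(mesh$centers[, 3]),
    vorticity_1_s = vort$values[[1]]$magnitude,
    helicity_cm_s2 = heli$values[[1]]$density,
    q_1_s2 = qcrit$values[[1]]$q)
  utils::write.csv(vol_df, paths$volume, row.names = FALSE)
  utils::write.csv(fs$residual_history, paths$residuals, row.names = FALSE)
  write_vtk_mesh(mesh, paths$mesh, cell_data = list(
    vorticity = vol_df$vorticity_1_s, helicity = vol_df$helicity_cm_s2,
    q_criterion = vol_df$q_1_s2))
  manifest <- list(
    package_version = as.character(utils::packageVersion("avflow")),
    config = config,
    seeds = list(image = config$image$seed %||% NA),
    input_hashes = list(
      config = hash_object(config[setdiff(names(config), "out_dir")])),
    outputs = lapply(paths, basename),
    output_hashes = lapply(paths, function(p) unname(tools::md5sum(p))),
    summary = list(
      n_cells = mesh$quality$n_cells,
      periodicity_error = fs$periodicity_error,
      all_steps_converged = fs$converged_all,
      peak_velocity_cm_s = m_s_to_cm_s(peak_u),
      reynolds = re),
    timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# carry opening patch labels from a labeled reference surface to an
# unlabeled reconstruction of the same geometry (nearest cap assignment)
transfer_patches <- function(ref, surface) {
  cent <- triangle_centroids(surface)
  patches <- list()
  ar <- triangle_areas(ref)
  for (nm in names(ref$patches)) {
    tri <- ref$patches[[nm]]
    centroid <- colSums(triangle_centroids(ref)[tri, , drop = FALSE] *
                          ar[tri]) / sum(ar[tri])
    p1 <- ref$vertices[ref$triangles[tri, 1], , drop = FALSE]
    p2 <- ref$vertices[ref$triangles[tri, 2], , drop = FALSE]
    p3 <- ref$vertices[ref$triangles[tri, 3], , drop = FALSE]
    nrm <- normalize(colSums(vcross(p2 - p1, p3 - p1)))
    vids <- unique(as.vector(ref$triangles[tri, ]))
    rmax <- max(sqrt(rowSums(sweep(ref$vertices[vids, , drop = FALSE], 2,
                                   centroid)^2)))
    rel <- sweep(cent, 2, centroid)
    dn <- abs(rel %*% nrm)
    radial <- sqrt(pmax(rowSums(rel^2) - dn^2, 0))
    sel <- which(dn < 0.35 & radial < rmax * 1.1)
    if (length(sel)) patches[[nm]] <- sel
  }
  patches
}

#' Mesh- and time-step-independence studies
#'
#' Runs the pulsatile case at a ladder of mesh edge lengths (or time steps),
#' monitors (a) the 4-mm segment-averaged cycle-averaged WSS on the first
#' branch and (b) the domain peak velocity, and reports symmetric relative
#' differences between consecutive levels. Results are independent when the
#' difference between the two finest consecutive levels is below 5 percent.
#'
#' @param surface a labeled watertight `surface_mesh` (mm).
#' @param bcs a [boundary_spec()].
#' @param props,config solver settings ([fluid_props()], [solver_config()]);
#'   `config$dt_ms` is shared by all mesh levels (and gives the base step for
#'   the time-step study).
#' @param base_edge_length base mesh edge (mm).
#' @param refinement_factors multipliers on `base_edge_length`, coarsest
#'   first (default `c(2, 1, 0.5)`); at least 3 levels are required to
#'   compare two consecutive pairs.
#' @param window_branch,window_start,window_length where the WSS monitor is
#'   averaged (mm along the centerline).
#' @return An `independence_report`: levels, monitored quantities, pairwise
#'   relative differences (percent), and the pass flag.
#' @export
mesh_independence_study <- function(surface, bcs, props = fluid_props(),
                                    config = solver_config(),
                                    base_edge_length,
                                    refinement_factors = c(2, 1, 0.5),
                                    window_branch = NULL, window_start = 0,
                                    window_length = 4) {
  if (length(refinement_factors) < 3) {
    abort("independence needs at least 3 levels", "avflow_protocol_error")
  }
  cl <- extract_centerline(surface)
  levels <- base_edge_length * refinement_factors
  wss_mon <- numeric(0)
  umax_mon <- numeric(0)
  ncells <- integer(0)
  for (e in levels) {
    mesh <- mesh_volume(surface, e)
    fs <- solve_pulsatile(mesh, bcs, props, config)
    m <- monitor_quantities(fs, cl, window_branch, window_start,
                            window_length)
    wss_mon <- c(wss_mon, m$wss)
    umax_mon <- c(umax_mon, m$umax)
    ncells <- c(ncells, mesh$quality$n_cells)
  }
  independence_report("mesh edge length (mm)", levels, ncells,
                      wss_mon, umax_mon)
}

#' @rdname mesh_independence_study
#' @param mesh a fixed `volume_mesh` for the time-step study.
#' @param dt_factors multipliers on `config$dt_ms`, coarsest first (default
#'   `c(1, 0.5, 0.25)`).
#' @export
timestep_independence_study <- function(surface, mesh, bcs,
                                        props = fluid_props(),
                                        config = solver_config(),
                                        dt_factors = c(1, 0.5, 0.25),
                                        window_branch = NULL,
                                        window_start = 0,
                                        window_length = 4) {
  if (length(dt_factors) < 3) {
    abort("independence needs at least 3 levels", "avflow_protocol_error")
  }
  cl <- extract_centerline(surface)
  levels <- config$dt_ms * dt_factors
  wss_mon <- numeric(0); umax_mon <- numeric(0)
  for (dt in levels) {
    cfg <- config
    cfg$dt_ms <- dt
    fs <- solve_pulsatile(mesh, bcs, props, cfg)
    m <- monitor_quantities(fs, cl, window_branch, window_start,
                            window_length)
    wss_mon <- c(wss_mon, m$wss)
    umax_mon <- c(umax_mon, m$umax)
  }
  independence_report("time step (ms)", levels,
                      rep(mesh$quality$n_cells, length(levels)),
                      wss_mon, umax_mon)
}

monitor_quantities <- function(fs, cl, branch, start_s, length) {
  shear <- wall_shear_vectors(fs)
  wss_avg <- cycle_average(wss_magnitude(shear), fs$inlet_waveform)
  ra <- region_average(wss_avg, cl, branch = branch, start_s = start_s,
                       length = length)
  umax <- max(vapply(fs$U, function(u) max(sqrt(rowSums(u^2))), numeric(1)))
  list(wss = ra$mean, umax = m_s_to_cm_s(umax))
}

independence_report <- function(what, levels, ncells, wss, umax) {
  nd <- length(levels)
  pair_diff <- function(x) {
    vapply(seq_len(nd - 1), function(i) relative_difference(x[i], x[i + 1]),
           numeric(1))
  }
  dw <- pair_diff(wss); du <- pair_diff(umax)
  finest <- nd - 1
  structure(list(
    what = what, levels = levels, n_cells = ncells,
    monitored = list(segment_wss_dyne_cm2 = wss, peak_velocity_cm_s = umax),
    pairwise_diff_pct = list(segment_wss = dw, peak_velocity = du),
    finest_pair_diff_pct = max(dw[finest], du[finest]),
    pass = dw[finest] < 5 && du[finest] < 5),
    class = "independence_report")
}

#' @method print independence_report
#' @export
print.independence_report <- function(x, ...) {
  cat(sprintf("independence over %s: levels %s\n", x$what,
              paste(signif(x$levels, 3), collapse = ", ")))
  cat(sprintf("  segment WSS: %s dyne/cm^2 (diffs %s%%)\n",
              paste(signif(x$monitored$segment_wss_dyne_cm2, 4),
                    collapse = ", "),
              paste(signif(x$pairwise_diff_pct$segment_wss, 3),
                    collapse = ", ")))
  cat(sprintf("  peak velocity: %s cm/s (diffs %s%%)\n",
              paste(signif(x$monitored$peak_velocity_cm_s, 4),
                    collapse = ", "),
              paste(signif(x$pairwise_diff_pct$peak_velocity, 3),
                    collapse = ", ")))
  cat(sprintf("  finest-pair difference %.3g%% -> %s\n",
              x$finest_pair_diff_pct,
              if (x$pass) "independent (<5%)" else "NOT independent"))
  invisible(x)
}
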