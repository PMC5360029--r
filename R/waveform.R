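# Pulsatile flow waveforms.
#
# A waveform holds per-cardiac-frame cross-section-averaged velocities, as
# extracted from phase-contrast velocity mapping: by default 8 frames at
# 16 ms spacing. Frames are interpolated periodically (cubic) onto the
# solver's much finer time grid. Velocities in cm/s at this interface.

#' Construct a pulsatile velocity waveform
#'
#' @param frame_values cross-section-averaged velocities per frame (cm/s).
#' @param frame_spacing_ms time between frames (ms), default 16.
#' @param n_frames number of frames (default: length of `frame_values`).
#' @param period_ms cycle length (ms). Defaults to
#'   `n_frames * frame_spacing_ms` (128 ms for the default acquisition); a
#'   ~120 ms cycle can be imposed via this override, which rescales the frame
#'   times proportionally.
#' @param location one of `"inflow artery"`, `"outflow artery"`,
#'   `"fistula vein"`, or any informative tag.
#' @return An object of class `flow_waveform` with `frame_times` (ms),
#'   `values` (cm/s), `period` (ms), `location`.
#' @export
make_waveform <- function(frame_values, frame_spacing_ms = 16,
                          n_frames = length(frame_values),
                          period_ms = NULL, location = "inflow artery") {
  frame_values <- as.numeric(frame_values)
  if (n_frames < 2) abort("a waveform needs at least 2 frames",
                          "avflow_validation_error")
  if (length(frame_values) != n_frames) {
    abort("frame_values length must equal n_frames", "avflow_validation_error")
  }
  if (any(!is.finite(frame_values))) {
    abort("non-finite frame values", "avflow_validation_error")
  }
  stopifnot(frame_spacing_ms > 0)
  native_period <- n_frames * frame_spacing_ms
  period <- period_ms %||% native_period
  stopifnot(period > 0)
  frame_times <- (seq_len(n_frames) - 1) * frame_spacing_ms *
    period / native_period
  structure(list(frame_times = frame_times, values = frame_values,
                 period = period, location = location),
            class = "flow_waveform")
}

#' @method print flow_waveform
#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform (%s): %d frames, period %g ms, mean %.3g cm/s\n",
              x$location, length(x$values), x$period, waveform_mean(x)))
  invisible(x)
}

#' Cycle-mean velocity of a waveform
#'
#' Trapezoidal quadrature with periodic wraparound; for uniformly spaced
#' frames this equals the arithmetic frame mean.
#' @param waveform a `flow_waveform`.
#' @return Mean velocity (cm/s).
#' @export
waveform_mean <- function(waveform) {
  t <- c(waveform$frame_times, waveform$period)
  v <- c(waveform$values, waveform$values[1])
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2) / waveform$period
}

#' Resample a waveform onto a dense periodic time grid
#'
#' Periodic cubic spline through the frames; the interpolant passes through
#' every frame value exactly. The series covers one period with the endpoint
#' excluded.
#'
#' @param waveform a `flow_waveform`.
#' @param dt_ms solver time step (ms), must not exceed the period.
#' @return list with `t_ms` and `v_cm_s` (length `round(period/dt)`), plus
#'   `fun`, the periodic interpolant (ms -> cm/s).
#' @export
resample_waveform <- function(waveform, dt_ms) {
  stopifnot(dt_ms > 0)
  if (dt_ms > waveform$period) {
    abort("dt exceeds the waveform period", "avflow_resolution_error")
  }
  P <- waveform$period
  tt <- c(waveform$frame_times, P)
  vv <- c(waveform$values, waveform$values[1])
  sf <- stats::splinefun(tt, vv, method = "periodic")
  fun <- function(t) sf(t %% P)
  n <- max(1L, round(P / dt_ms))
  t_ms <- (seq_len(n) - 1) * dt_ms
  list(t_ms = t_ms, v_cm_s = fun(t_ms), fun = fun)
}

#' Distribute a mean velocity over an opening patch
#'
#' Produces per-face boundary velocities on one opening of a
#' [mesh_volume()] mesh whose area-weighted mean equals `mean_velocity`
#' exactly (a discrete renormalization absorbs the shape and rasterization
#' error). The `parabolic` shape is Poiseuille-like on the patch's inscribed
#' radius; `plug` is uniform.
#'
#' @param mean_velocity cross-section-averaged velocity (cm/s, positive =
#'   along the flow direction of the patch).
#' @param mesh a `volume_mesh`.
#' @param patch patch name.
#' @param shape `"parabolic"` (default) or `"plug"`.
#' @return list with `faces` (face indices into `mesh$faces`), `u` (per-face
#'   velocity vectors, m/s, directed along the inward patch normal for
#'   positive `mean_velocity` on an inlet-style patch -- the sign is carried
#'   by `mean_velocity`), and `normal_speed` (signed m/s along the outward
#'   face direction).
#' @export
inlet_velocity_profile <- function(mean_velocity, mesh, patch,
                                   shape = c("parabolic", "plug")) {
  shape <- match.arg(shape)
  stopifnot(inherits(mesh, "volume_mesh"))
  faces <- which(mesh$faces$patch == patch)
  if (!length(faces)) abort("unknown or empty patch", "avflow_geometry_error")
  area <- sum(mesh$faces$area[faces])
  if (area <= 0) abort("zero-area patch", "avflow_geometry_error")
  info <- mesh$patch_info[[patch]]
  fc <- mesh$faces$center[faces, , drop = FALSE]
  centroid <- colSums(fc) / length(faces)
  if (shape == "plug") {
    w <- rep(1, length(faces))
  } else {
    rel <- sweep(fc, 2, centroid)
    dn <- as.vector(rel %*% info$normal)
    r2 <- pmax(rowSums(rel^2) - dn^2, 0)
    R2 <- max(r2) + (mesh$h / 2)^2
    w <- pmax(1 - r2 / R2, 0)
  }
  # renormalize so the discrete area-weighted mean is exact
  w <- w / (sum(w * mesh$faces$area[faces]) / area)
  u_mag <- cm_s_to_m_s(mean_velocity) * w
  list(faces = faces, weights = w, normal_speed = u_mag,
       patch_area = area)
}
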