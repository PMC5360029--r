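# Synthetic vessel phantoms.
#
# Phantoms are unions of generalized tube segments: a polyline axis plus a
# radius profile r(s) along arclength. The idealized arteriovenous fistula
# (AVF) is a side(artery)-to-end(vein) junction with an optional venous side
# branch and a smooth radial bulge on the vein emulating heterogeneous
# venous dilation. All dimensions in mm.

#' Idealized AVF phantom specification
#'
#' Defaults are sized to the murine carotid-jugular configuration: artery and
#' vein radii chosen so the control cross-sectional areas are 0.29 mm^2 and
#' 1.55 mm^2 respectively, a 90 degree anastomosis, a venous bulge peaking
#' 1 mm downstream of the anastomosis, and a side branch taking off 4.5 mm
#' downstream.
#'
#' @param artery_radius,vein_radius tube radii (mm).
#' @param artery_length,vein_length total lengths (mm); the artery is centered
#'   on the anastomosis.
#' @param anastomosis_angle angle between artery axis and vein axis, degrees
#'   in (0, 180).
#' @param vein_bulge_amplitude dimensionless radial scale factor at the bulge
#'   peak (>= 1; 1 disables the bulge).
#' @param bulge_center,bulge_width Gaussian bulge center and width along the
#'   vein arclength (mm).
#' @param side_branch `NULL`, or `list(radius=, takeoff=, angle=, length=)`
#'   for a venous side branch (mm / degrees).
#' @return An object of classes `avf_phantom_spec`, `phantom_spec`.
#' @export
avf_phantom_spec <- function(artery_radius = 0.304, vein_radius = 0.702,
                             artery_length = 8, vein_length = 8,
                             anastomosis_angle = 90,
                             vein_bulge_amplitude = 1.5,
                             bulge_center = 1, bulge_width = 1,
                             side_branch = list(radius = 0.3, takeoff = 4.5,
                                                angle = 45, length = 2.5)) {
  stopifnot(artery_radius > 0, vein_radius > 0,
            artery_length > 0, vein_length > 0,
            anastomosis_angle > 0, anastomosis_angle < 180,
            vein_bulge_amplitude >= 1)
  th <- anastomosis_angle * pi / 180
  dv <- c(cos(th), sin(th), 0)
  segs <- list(
    artery = tube_segment(
      rbind(c(-artery_length / 2, 0, 0), c(artery_length / 2, 0, 0)),
      artery_radius, cap_start = "inlet", cap_end = "outlet_artery"),
    vein = tube_segment(
      rbind(c(0, 0, 0), vein_length * dv),
      bulge_radius_fun(vein_radius, vein_bulge_amplitude,
                       bulge_center, bulge_width),
      cap_start = NA, cap_end = "outlet_vein")
  )
  if (!is.null(side_branch)) {
    stopifnot(side_branch$radius > 0, side_branch$takeoff > 0,
              side_branch$takeoff < vein_length, side_branch$length > 0)
    thb <- (anastomosis_angle - side_branch$angle) * pi / 180
    db <- c(cos(thb), sin(thb), 0)
    p0 <- side_branch$takeoff * dv
    segs$branch <- tube_segment(
      rbind(p0, p0 + side_branch$length * db), side_branch$radius,
      cap_start = NA, cap_end = "outlet_branch")
  }
  structure(list(segments = segs,
                 junction = c(0, 0, 0),
                 params = list(artery_radius = artery_radius,
                               vein_radius = vein_radius,
                               anastomosis_angle = anastomosis_angle,
                               vein_bulge_amplitude = vein_bulge_amplitude,
                               bulge_center = bulge_center,
                               bulge_width = bulge_width,
                               side_branch = side_branch)),
            class = c("avf_phantom_spec", "phantom_spec"))
}

#' Straight-tube phantom specification
#'
#' A single straight tube along the x axis with optional radial bulge, for
#' solver validation and calibration tests.
#'
#' @param radius tube radius (mm).
#' @param length tube length (mm).
#' @param bulge_amplitude radial scale factor at bulge peak (>= 1).
#' @param bulge_center,bulge_width bulge position/width along arclength (mm).
#' @param axis `"x"` (default) or `"z"`; `"z"` runs the vessel through-plane,
#'   matching an axial-slice acquisition with coarse slice spacing.
#' @return An object of classes `tube_spec`, `phantom_spec`.
#' @export
tube_spec <- function(radius, length, bulge_amplitude = 1,
                      bulge_center = length / 2, bulge_width = length / 8,
                      axis = c("x", "z")) {
  stopifnot(radius > 0, length > 0, bulge_amplitude >= 1)
  axis <- match.arg(axis)
  ends <- if (axis == "x") rbind(c(0, 0, 0), c(length, 0, 0)) else
    rbind(c(0, 0, 0), c(0, 0, length))
  structure(list(
    segments = list(tube = tube_segment(
      ends,
      bulge_radius_fun(radius, bulge_amplitude, bulge_center, bulge_width),
      cap_start = "inlet", cap_end = "outlet")),
    junction = NULL,
    params = list(radius = radius, length = length,
                  bulge_amplitude = bulge_amplitude,
                  bulge_center = bulge_center, bulge_width = bulge_width,
                  axis = axis)),
    class = c("tube_spec", "phantom_spec"))
}

#' Curved-tube (torus section) phantom specification
#'
#' @param major_radius radius of the centerline circle (mm).
#' @param tube_radius tube radius (mm).
#' @param arc_degrees arc swept by the tube in (0, 360).
#' @param n_axis number of polyline vertices along the arc.
#' @return An object of classes `torus_spec`, `phantom_spec`.
#' @export
torus_spec <- function(major_radius, tube_radius, arc_degrees = 180,
                       n_axis = 121) {
  stopifnot(major_radius > tube_radius, tube_radius > 0,
            arc_degrees > 0, arc_degrees < 360)
  th <- seq(0, arc_degrees * pi / 180, length.out = n_axis)
  pts <- cbind(major_radius * cos(th), major_radius * sin(th), 0)
  structure(list(
    segments = list(tube = tube_segment(pts, tube_radius,
                                        cap_start = "inlet",
                                        cap_end = "outlet")),
    junction = NULL,
    params = list(major_radius = major_radius, tube_radius = tube_radius,
                  arc_degrees = arc_degrees)),
    class = c("torus_spec", "phantom_spec"))
}

bulge_radius_fun <- function(r0, amplitude, center, width) {
  if (amplitude == 1) return(function(s) rep(r0, length(s)))
  function(s) r0 * (1 + (amplitude - 1) * exp(-((s - center) / width)^2))
}

tube_segment <- function(points, radius, cap_start, cap_end) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  rf <- if (is.function(radius)) radius else {
    r0 <- radius
    function(s) rep(r0, length(s))
  }
  el <- sqrt(rowSums((points[-1, , drop = FALSE] -
                        points[-nrow(points), , drop = FALSE])^2))
  list(points = points, radius_fun = rf, edge_len = el,
       cum_s = c(0, cumsum(el)), length = sum(el),
       cap_start = cap_start, cap_end = cap_end)
}

# For query points X (n x 3): distance to the segment's polyline axis and the
# arclength of the closest point.
polyline_distance <- function(seg, X) {
  n <- nrow(X)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  P <- seg$points
  for (e in seq_len(nrow(P) - 1)) {
    a <- P[e, ]; b <- P[e + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((X[, 1] - a[1]) * ab[1] + (X[, 2] - a[2]) * ab[2] +
            (X[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- X[, 1] - (a[1] + t * ab[1])
    dy <- X[, 2] - (a[2] + t * ab[2])
    dz <- X[, 3] - (a[3] + t * ab[3])
    d2 <- dx * dx + dy * dy + dz * dz
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- seg$cum_s[e] + t[upd] * sqrt(len2)
  }
  # signed axial overshoot beyond the two tube ends, so the level function is
  # strictly negative past the flat end caps
  n <- nrow(P)
  d0 <- (P[2, ] - P[1, ]) / sqrt(sum((P[2, ] - P[1, ])^2))
  dL <- (P[n, ] - P[n - 1, ]) / sqrt(sum((P[n, ] - P[n - 1, ])^2))
  a0 <- (X[, 1] - P[1, 1]) * d0[1] + (X[, 2] - P[1, 2]) * d0[2] +
    (X[, 3] - P[1, 3]) * d0[3]
  aL <- (X[, 1] - P[n, 1]) * dL[1] + (X[, 2] - P[n, 2]) * dL[2] +
    (X[, 3] - P[n, 3]) * dL[3]
  s_ext <- best_s
  s_ext[a0 < 0] <- a0[a0 < 0]
  past <- aL > 0
  s_ext[past] <- seg$length + aL[past]
  list(d = sqrt(best_d2), s = best_s, s_ext = s_ext)
}

# Implicit level function of one segment: positive inside, flat end caps.
segment_field <- function(seg, X) {
  pd <- polyline_distance(seg, X)
  pmin(seg$radius_fun(pd$s) - pd$d, pd$s_ext, seg$length - pd$s_ext)
}

#' Evaluate the phantom's implicit level function
#'
#' Positive inside the lumen, negative outside; the zero level set is the
#' analytic lumen boundary (flat at tube ends).
#'
#' @param spec a `phantom_spec`.
#' @param X n x 3 matrix of physical points (mm).
#' @return Numeric vector of level values.
#' @export
phantom_field <- function(spec, X) {
  X <- matrix(as.numeric(X), ncol = 3)
  vals <- rep(-Inf, nrow(X))
  for (seg in spec$segments) vals <- pmax(vals, segment_field(seg, X))
  vals
}

phantom_bbox <- function(spec) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (seg in spec$segments) {
    rmax <- max(seg$radius_fun(seq(0, seg$length, length.out = 200)))
    lo <- pmin(lo, apply(seg$points, 2, min) - rmax)
    hi <- pmax(hi, apply(seg$points, 2, max) + rmax)
  }
  rbind(lo, hi)
}

#' Generate a synthetic black-blood image stack of a phantom
#'
#' The lumen is dark, background tissue bright, with optional additive
#' Gaussian noise. The analytic ground-truth mask is attached as attribute
#' `"ground_truth"` and is also available via [phantom_ground_truth()].
#'
#' @param spec a `phantom_spec`.
#' @param spacing per-axis voxel size (mm); default emulates a 0.1 mm
#'   in-plane / 0.5 mm slice acquisition.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units, >= 0).
#' @param seed integer seed for the noise; the caller's RNG state is
#'   restored afterwards.
#' @param margin background margin around the phantom (mm).
#' @param extent optional physical grid extent (mm, length 3). If the phantom
#'   plus margin does not fit, a sizing error is raised.
#' @param lumen_intensity,background_intensity mean intensities of the two
#'   classes (black-blood: lumen dark).
#' @return An [image_stack()] with attribute `"ground_truth"`.
#' @export
generate_phantom_image <- function(spec, spacing = c(0.1, 0.1, 0.5),
                                   noise_sd = 0, seed = 1, margin = 0.4,
                                   extent = NULL,
                                   lumen_intensity = 20,
                                   background_intensity = 100) {
  stopifnot(inherits(spec, "phantom_spec"), all(spacing > 0), noise_sd >= 0)
  bb <- phantom_bbox(spec)
  need <- (bb[2, ] - bb[1, ]) + 2 * margin
  if (!is.null(extent)) {
    if (any(extent < need)) {
      abort("phantom does not fit in requested grid extent",
            "avflow_sizing_error")
    }
    need <- extent
  }
  dims <- pmax(2L, as.integer(ceiling(need / spacing)) + 1L)
  center <- (bb[1, ] + bb[2, ]) / 2
  # fixed sub-voxel offset: scanner grids are never aligned with the vessel
  # axes, and exact alignment is a degenerate (worst-case) quantization
  origin <- center - (dims - 1) * spacing / 2 +
    spacing * c(0.271, 0.412, 0.138)
  ax <- grid_axes(dims, spacing, origin)
  X <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  inside <- phantom_field(spec, X) > 0
  gt <- array(inside, dims)
  img <- array(ifelse(inside, lumen_intensity, background_intensity), dims)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    img <- img + array(stats::rnorm(prod(dims), sd = noise_sd), dims)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  stack <- image_stack(img, spacing, origin)
  attr(stack, "ground_truth") <- lumen_mask(gt, spacing, origin)
  stack
}

#' Retrieve the analytic ground-truth mask of a phantom image
#'
#' @param stack an image stack produced by [generate_phantom_image()].
#' @return The [lumen_mask()] of lumen voxels (voxel centers strictly inside
#'   the analytic boundary).
#' @export
phantom_ground_truth <- function(stack) {
  gt <- attr(stack, "ground_truth")
  if (is.null(gt)) abort("stack carries no ground truth", "avflow_no_truth")
  gt
}

#' Generate a watertight labeled surface directly from a phantom spec
#'
#' Analytic route bypassing imaging: the implicit level function is sampled
#' on a fine grid and triangulated (marching-tetrahedra). Open tube ends are
#' closed by flat cap triangles which carry patch labels (e.g. `inlet`,
#' `outlet_vein`).
#'
#' @param spec a `phantom_spec`.
#' @param resolution sampling grid spacing (mm); default is the smallest tube
#'   radius divided by 8.
#' @return A `surface_mesh` with a `patches` component mapping patch names to
#'   triangle indices.
#' @export
generate_phantom_surface <- function(spec, resolution = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  rmin <- min(vapply(spec$segments,
                     function(s) min(s$radius_fun(seq(0, s$length,
                                                      length.out = 200))),
                     numeric(1)))
  h <- resolution %||% (rmin / 8)
  bb <- phantom_bbox(spec)
  lo <- bb[1, ] - 2 * h
  hi <- bb[2, ] + 2 * h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  ax <- grid_axes(dims, rep(h, 3), lo)
  X <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- array(phantom_field(spec, X), dims)
  surf <- marching_tetrahedra(vals, ax, level = 0)
  if (nrow(surf$vertices) == 0) {
    abort("phantom surface is empty: degenerate parameter combination",
          "avflow_geometry_error")
  }
  surf$patches <- label_phantom_caps(spec, surf, h)
  if (!is_watertight(surf)) {
    abort("phantom surface is not watertight (self-intersecting parameters?)",
          "avflow_geometry_error")
  }
  surf
}

# Assign cap triangles of an implicit phantom surface to named patches.
label_phantom_caps <- function(spec, surf, h) {
  cent <- triangle_centroids(surf)
  patches <- list()
  for (seg in spec$segments) {
    ends <- list(
      list(name = seg$cap_start, p = seg$points[1, ],
           n = normalize(seg$points[1, ] - seg$points[2, ]),
           r = seg$radius_fun(0)),
      list(name = seg$cap_end, p = seg$points[nrow(seg$points), ],
           n = normalize(seg$points[nrow(seg$points), ] -
                           seg$points[nrow(seg$points) - 1, ]),
           r = seg$radius_fun(seg$length))
    )
    for (cap in ends) {
      if (is.na(cap$name)) next
      rel <- sweep(cent, 2, cap$p)
      dn <- rel %*% cap$n
      radial <- sqrt(pmax(rowSums(rel^2) - dn^2, 0))
      sel <- which(abs(dn) < 0.55 * h & radial < cap$r + 2 * h)
      if (length(sel) == 0) {
        abort(sprintf("no cap triangles found for patch '%s'", cap$name),
              "avflow_geometry_error")
      }
      patches[[cap$name]] <- sel
    }
  }
  patches
}

normalize <- function(v) v / sqrt(sum(v^2))
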