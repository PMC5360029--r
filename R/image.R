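# Image containers and lumen segmentation.
#
# An image stack emulates a black-blood acquisition: the lumen is dark and the
# surrounding tissue bright, with anisotropic voxels (default 0.1 mm in-plane,
# 0.5 mm slice thickness). Voxel centers sit at origin + (index - 1) * spacing,
# arrays are indexed [row, col, slice] = [x, y, z] in physical mm.

#' Construct a 3D image stack
#'
#' @param intensities 3D numeric array of voxel intensities (arbitrary units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin physical mm coordinate of the center of voxel (1,1,1).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (any(dim(intensities) < 2)) {
    abort("image stack needs at least 2 voxels per axis", "avflow_dim_error")
  }
  structure(
    list(intensities = intensities, spacing = spacing,
         origin = as.numeric(origin)),
    class = "image_stack"
  )
}

#' @method print image_stack
#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %s voxels, spacing %s mm\n",
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "/")))
  invisible(x)
}

#' Construct a lumen mask aligned with an image stack
#'
#' @param labels 3D logical array; `TRUE` marks lumen voxels.
#' @param spacing,origin geometry copied from the source stack (mm).
#' @return An object of class `lumen_mask`.
#' @export
lumen_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3, is.logical(labels))
  if (!any(labels)) abort("mask has no labeled voxels", "avflow_empty_mask")
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "lumen_mask"
  )
}

# physical coordinates of voxel centers along each axis
grid_axes <- function(dims, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
}

#' Segment the lumen by seeded intensity thresholding
#'
#' Deterministic, scriptable equivalent of interactive region-grow
#' thresholding on black-blood images: the mask is the 26-connected component
#' of dark voxels (intensity below or equal to the threshold) that contains
#' the seed point.
#'
#' @param stack an [image_stack()].
#' @param seed_point integer length-3 voxel index (1-based) inside the grid.
#' @param threshold intensity cutoff; lumen voxels satisfy
#'   `intensity <= threshold`.
#' @return A [lumen_mask()] containing a single 26-connected component.
#' @export
segment_lumen <- function(stack, seed_point, threshold) {
  stopifnot(inherits(stack, "image_stack"))
  dims <- dim(stack$intensities)
  seed_point <- as.integer(round(seed_point))
  if (length(seed_point) != 3 || any(seed_point < 1) || any(seed_point > dims)) {
    abort("seed point outside the image grid", "avflow_seed_error")
  }
  rng <- range(stack$intensities)
  if (threshold < rng[1] || threshold > rng[2]) {
    # still permitted, but an all-dark/all-bright threshold is usually a bug
    if (threshold < rng[1]) {
      abort("threshold below all intensities: empty segmentation",
            "avflow_empty_segmentation")
    }
  }
  candidate <- stack$intensities <= threshold
  if (!candidate[seed_point[1], seed_point[2], seed_point[3]]) {
    abort("seed voxel above threshold: empty segmentation",
          "avflow_empty_segmentation")
  }
  comp <- connected_component_26(candidate, seed_point)
  lumen_mask(comp, stack$spacing, stack$origin)
}

# 26-connected component containing the seed, by iterative box dilation
# restricted to the candidate set. A 3x3x3 box dilation step equals one
# 26-neighbourhood growth step.
connected_component_26 <- function(candidate, seed) {
  dims <- dim(candidate)
  region <- array(FALSE, dims)
  region[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- dilate_box3(region) & candidate
    if (sum(grown) == sum(region)) break
    region <- grown
  }
  region
}

# 3x3x3 box dilation via three axis passes of shifts
dilate_box3 <- function(a) {
  for (axis in 1:3) {
    a <- a | shift_array(a, axis, 1L) | shift_array(a, axis, -1L)
  }
  a
}

# shift array contents by k along an axis, padding with FALSE/0
shift_array <- function(a, axis, k) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  ix_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_dst <- ix_src
  ix_src[[axis]] <- src
  ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    a[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

#' Exact Euclidean distance transform of a binary mask
#'
#' For every `TRUE` voxel, the Euclidean distance (mm) to the nearest `FALSE`
#' voxel center, honoring anisotropic spacing. Separable exact algorithm:
#' a run-length scan along the first axis followed by brute-force parabola
#' minimization along the remaining axes (vectorized over slices).
#'
#' @param labels 3D logical array.
#' @param spacing per-axis voxel size (mm).
#' @return 3D numeric array of distances; 0 on `FALSE` voxels.
#' @export
distance_transform <- function(labels, spacing) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  d <- dim(labels)
  big <- sum((d * spacing)^2) * 4
  # pass 1: squared distance to nearest FALSE along axis 1
  g2 <- array(big, d)
  fwd <- matrix(big, d[2], d[3])
  for (i in seq_len(d[1])) {
    sl <- labels[i, , ]
    fwd <- ifelse(sl, (sqrt(fwd) + spacing[1])^2, 0)
    fwd[fwd > big] <- big
    g2[i, , ] <- fwd
  }
  bwd <- matrix(big, d[2], d[3])
  for (i in rev(seq_len(d[1]))) {
    sl <- labels[i, , ]
    bwd <- ifelse(sl, (sqrt(bwd) + spacing[1])^2, 0)
    bwd[bwd > big] <- big
    g2[i, , ] <- pmin(g2[i, , ], bwd)
  }
  # passes 2..3: D[i] = min_j g[j] + ((i-j)*s)^2, brute force over j,
  # vectorized over all other axes
  for (axis in 2:3) {
    n <- d[axis]
    s <- spacing[axis]
    out <- array(big, d)
    for (j in seq_len(n)) {
      gj <- if (axis == 2) g2[, j, ] else g2[, , j]
      for (i in seq_len(n)) {
        cand <- gj + ((i - j) * s)^2
        if (axis == 2) {
          out[, i, ] <- pmin(out[, i, ], cand)
        } else {
          out[, , i] <- pmin(out[, , i], cand)
        }
      }
    }
    g2 <- out
  }
  sqrt(g2)
}

#' Signed distance field of a mask
#'
#' Positive inside the mask, negative outside, zero crossing midway between
#' adjacent inside/outside voxel centers.
#' @inheritParams distance_transform
#' @return 3D numeric array (mm).
#' @export
signed_distance <- function(labels, spacing) {
  distance_transform(labels, spacing) - distance_transform(!labels, spacing)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  if (inherits(a, "lumen_mask")) a <- a$labels
  if (inherits(b, "lumen_mask")) b <- b$labels
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Pad a mask with background voxels on every side
#'
#' Isosurface extraction requires the mask not to touch the grid boundary;
#' this adds `n` layers of `FALSE` voxels and shifts the origin accordingly.
#'
#' @param mask a [lumen_mask()].
#' @param n number of voxel layers to add per side.
#' @return A padded [lumen_mask()].
#' @export
pad_mask <- function(mask, n = 1L) {
  stopifnot(inherits(mask, "lumen_mask"))
  d <- dim(mask$labels)
  out <- array(FALSE, d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- mask$labels
  lumen_mask(out, mask$spacing, mask$origin - n * mask$spacing)
}

# TRUE if any labeled voxel lies on the outermost layer of the grid
mask_touches_boundary <- function(labels) {
  d <- dim(labels)
  any(labels[c(1, d[1]), , ]) || any(labels[, c(1, d[2]), ]) ||
    any(labels[, , c(1, d[3])])
}
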