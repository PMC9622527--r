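# Shared domain types, physical constants and unit conversions.
#
# World coordinates are millimetres on an axis-aligned grid:
#   world = origin + (voxel_index - 1) * spacing   (R indices are 1-based).
# All physics is done in SI internally; pressures are reported in mmHg,
# flows in ml/s, energies in mJ where stated.

#' Default blood properties
#'
#' Whole-blood density and dynamic viscosity used throughout the package
#' unless overridden. These are conventional literature values for whole
#' blood at body temperature.
#'
#' @param density blood density in kg/m^3 (default 1060)
#' @param viscosity dynamic viscosity in Pa.s (default 0.004)
#' @return an object of class `fluid_properties`
#' @export
#' @examples
#' fluid_properties()
fluid_properties <- function(density = 1060, viscosity = 0.004) {
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L)
  if (density <= 0) stop("blood density must be strictly positive")
  if (viscosity <= 0) stop("dynamic viscosity must be strictly positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Convert pressure between pascal and millimetres of mercury
#'
#' One mmHg is defined as 133.322387415 Pa; the conversions are exact
#' inverses of each other.
#'
#' @param p pressure in Pa (`pa_to_mmhg`) or mmHg (`mmhg_to_pa`)
#' @return converted pressure, same shape as the input
#' @export
#' @examples
#' pa_to_mmhg(133.322387415)  # 1 mmHg
pa_to_mmhg <- function(p) p / 133.322387415

#' @rdname pa_to_mmhg
#' @export
mmhg_to_pa <- function(p) p * 133.322387415

#' Index a measurement by body surface area
#'
#' Divides a measured quantity (diameter, wall thickness, curvature, ...)
#' by the subject's body surface area, the conventional normalisation for
#' comparing vascular dimensions across body sizes. Curvature is indexed
#' exactly like lengths (kappa / BSA, unit m^-1/m^2).
#'
#' @param value numeric quantity (vector allowed)
#' @param meta a [subject_meta()] object, or a single positive BSA in m^2
#' @return `value / bsa`, unit `<unit>/m^2`
#' @export
#' @examples
#' index_by_bsa(15.96, subject_meta("s1", bsa = 0.57, heart_period = 700))
index_by_bsa <- function(value, meta) {
  bsa <- if (inherits(meta, "subject_meta")) meta$bsa else meta
  if (!is.numeric(bsa) || length(bsa) != 1L || is.na(bsa) || bsa <= 0)
    stop("invalid subject metadata: BSA must be a single positive number (m^2)")
  value / bsa
}

#' Subject metadata
#'
#' @param subject_id subject identifier
#' @param bsa body surface area in m^2 (> 0)
#' @param heart_period cardiac cycle length in ms (> 0)
#' @param group_label cohort tag, e.g. `"HLHS"` or `"AM"`
#' @return an object of class `subject_meta`
#' @export
subject_meta <- function(subject_id, bsa, heart_period, group_label = NA_character_) {
  if (!is.numeric(bsa) || bsa <= 0) stop("bsa must be > 0")
  if (!is.numeric(heart_period) || heart_period <= 0)
    stop("heart_period must be > 0")
  structure(list(subject_id = as.character(subject_id), bsa = bsa,
                 heart_period = heart_period,
                 group_label = as.character(group_label)),
            class = "subject_meta")
}

#' Time-resolved 3D velocity field
#'
#' Container for the measured blood-velocity vectors on a regular voxel
#' grid. Values are stored as a 5-D array with dimensions
#' `(X, Y, Z, component, frame)`; components are world-axis (x, y, z)
#' velocities in m/s.
#'
#' @param values numeric array, dim `(X, Y, Z, 3, T)`, in m/s
#' @param spacing voxel edge lengths in mm (length 3, all > 0)
#' @param frame_times acquisition times in ms (length T, strictly increasing)
#' @param origin world coordinate (mm) of voxel (1,1,1); default c(0,0,0)
#' @return an object of class `velocity_field4d`
#' @export
velocity_field4d <- function(values, spacing, frame_times, origin = c(0, 0, 0)) {
  d <- dim(values)
  if (length(d) != 5L || d[4] != 3L)
    stop("values must be a 5-D array with dim (X, Y, Z, 3, T)")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths (mm)")
  if (length(frame_times) != d[5])
    stop("frame_times length must equal the number of frames")
  if (d[5] > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  structure(list(values = values, spacing = as.numeric(spacing),
                 frame_times = as.numeric(frame_times),
                 origin = as.numeric(origin)),
            class = "velocity_field4d")
}

#' @export
print.velocity_field4d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<velocity_field4d> %dx%dx%d voxels, %d frames, spacing %s mm\n",
              d[1], d[2], d[3], d[5],
              paste(format(x$spacing, digits = 3), collapse = "x")))
  invisible(x)
}

#' Binary lumen mask
#'
#' Static (peak-systolic) lumen segmentation on the same grid as the
#' velocity field.
#'
#' @param voxels logical array, dim `(X, Y, Z)`
#' @param spacing voxel edge lengths in mm
#' @param origin world coordinate (mm) of voxel (1,1,1)
#' @return an object of class `lumen_mask`
#' @export
lumen_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths (mm)")
  structure(list(voxels = array(as.logical(voxels), dim(voxels)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("<lumen_mask> %s voxels, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

# ---- internal grid helpers --------------------------------------------------

# world (mm) coordinates of 1-based voxel indices (n x 3 matrix)
voxel_to_world <- function(idx, spacing, origin) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

# continuous (1-based, fractional) voxel coordinates of world points
world_to_voxel <- function(pts, spacing, origin) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`) + 1
}

# volume of one voxel in m^3 (spacing in mm)
voxel_volume_m3 <- function(spacing) prod(spacing) * 1e-9

# Trilinear interpolation of a 3-D volume at fractional 1-based voxel
# coordinates (n x 3). Points outside the grid return `outside`.
trilinear <- function(vol, vox, outside = 0) {
  d <- dim(vol)
  n <- nrow(vox)
  i0 <- floor(vox)
  f <- vox - i0
  # clamp so that i0 and i0+1 are valid; record which points were outside
  out <- vox[, 1] < 1 | vox[, 1] > d[1] |
         vox[, 2] < 1 | vox[, 2] > d[2] |
         vox[, 3] < 1 | vox[, 3] > d[3]
  i0[, 1] <- pmin(pmax(i0[, 1], 1), d[1] - 1)
  i0[, 2] <- pmin(pmax(i0[, 2], 1), d[2] - 1)
  i0[, 3] <- pmin(pmax(i0[, 3], 1), d[3] - 1)
  f <- vox - i0
  f[f < 0] <- 0; f[f > 1] <- 1
  idx <- function(di, dj, dk)
    (i0[, 1] + di) + d[1] * ((i0[, 2] + dj) - 1) + d[1] * d[2] * ((i0[, 3] + dk) - 1)
  w000 <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3])
  w100 <- f[, 1] * (1 - f[, 2]) * (1 - f[, 3])
  w010 <- (1 - f[, 1]) * f[, 2] * (1 - f[, 3])
  w110 <- f[, 1] * f[, 2] * (1 - f[, 3])
  w001 <- (1 - f[, 1]) * (1 - f[, 2]) * f[, 3]
  w101 <- f[, 1] * (1 - f[, 2]) * f[, 3]
  w011 <- (1 - f[, 1]) * f[, 2] * f[, 3]
  w111 <- f[, 1] * f[, 2] * f[, 3]
  v <- w000 * vol[idx(0, 0, 0)] + w100 * vol[idx(1, 0, 0)] +
       w010 * vol[idx(0, 1, 0)] + w110 * vol[idx(1, 1, 0)] +
       w001 * vol[idx(0, 0, 1)] + w101 * vol[idx(1, 0, 1)] +
       w011 * vol[idx(0, 1, 1)] + w111 * vol[idx(1, 1, 1)]
  v[out] <- outside
  v
}

# shift a 3-D array by one voxel along `axis` (+1 or -1 step), zero fill
shift3 <- function(a, axis, step) {
  d <- dim(a)
  out <- array(0, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (step == 1L) {        # out[i] = a[i+1]
    src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1L)
  } else {                 # out[i] = a[i-1]
    src[[axis]] <- 1:(d[axis] - 1L); dst[[axis]] <- 2:d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# connected component of a 3-D logical array containing seed index (vector
# of 3), grown by 6-connectivity using vectorised dilation
connected_component3 <- function(mask, seed) {
  if (!mask[seed[1], seed[2], seed[3]]) stop("seed is not inside the mask")
  comp <- array(FALSE, dim(mask))
  comp[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- comp |
      shift3(comp, 1L, 1L) | shift3(comp, 1L, -1L) |
      shift3(comp, 2L, 1L) | shift3(comp, 2L, -1L) |
      shift3(comp, 3L, 1L) | shift3(comp, 3L, -1L)
    grown <- grown & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# largest 6-connected component of a 3-D logical array
largest_component3 <- function(mask) {
  remaining <- mask
  best <- NULL
  n_comp <- 0L
  while (any(remaining)) {
    seed <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- connected_component3(remaining, seed)
    n_comp <- n_comp + 1L
    if (is.null(best) || sum(comp) > sum(best)) best <- comp
    remaining <- remaining & !comp
  }
  list(component = best, n_components = n_comp)
}
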