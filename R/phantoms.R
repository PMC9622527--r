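# Synthetic 4D-flow phantoms with closed-form ground truth. Each generator
# returns the velocity field, the lumen mask and a `truth` list whose
# values come from analytic formulas evaluated independently of the voxel
# grid. Defaults mirror a paediatric 4D-flow acquisition: 1-mm voxels
# (tests use 0.5 mm where convergence headroom is needed) and ~30-ms
# frames.

new_phantom <- function(field, mask, truth, params) {
  structure(list(field = field, mask = mask, truth = truth, params = params),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s\n", x$params$kind))
  str(x$truth, give.attr = FALSE)
  invisible(x)
}

# grid for a straight tube of radius R (mm) along +z, length L, with a
# margin of empty voxels around the lumen
tube_grid <- function(R_max, L, voxel, margin = 3) {
  half <- R_max + margin * voxel
  x <- seq(-half, half, by = voxel)
  z <- seq(-voxel, L + voxel, by = voxel)
  list(x = x, y = x, z = z,
       origin = c(x[1], x[1], z[1]),
       nx = length(x), ny = length(x), nz = length(z))
}

#' Steady Poiseuille phantom
#'
#' Fully developed laminar flow in a straight rigid tube: parabolic axial
#' profile `v(r) = 2 Q / (pi R^2) (1 - r^2/R^2)`. Ground truth from the
#' Hagen-Poiseuille law: pressure drop `8 mu L Q / (pi R^4)` and viscous
#' dissipation rate `Q * dP`.
#'
#' @param R tube radius, mm (must exceed `2 * voxel`)
#' @param L tube length, mm
#' @param Q flow rate, ml/s
#' @param voxel isotropic voxel size, mm
#' @param props [fluid_properties()]
#' @param frames number of identical frames (>= 2 so temporal operations
#'   are defined)
#' @param frame_dt frame spacing, ms
#' @return a `phantom_truth` with `truth$pressure_drop` (Pa),
#'   `truth$viscous_rate` (W), `truth$flow_rate` (ml/s),
#'   `truth$diameter` (mm)
#' @export
poiseuille_phantom <- function(R = 8, L = 80, Q = 70, voxel = 1,
                               props = fluid_properties(), frames = 2,
                               frame_dt = 30) {
  if (R <= 2 * voxel)
    stop("under-resolved radius: R must exceed two voxels")
  g <- tube_grid(R, L, voxel)
  r2 <- outer(g$x^2, g$y^2, `+`)           # nx x ny, mm^2
  inside2d <- r2 <= R^2
  R_m <- R * 1e-3; Q_si <- Q * 1e-6
  vmax <- 2 * Q_si / (pi * R_m^2)          # m/s
  prof <- vmax * (1 - r2 / R^2)
  prof[!inside2d] <- 0
  mask3 <- array(inside2d, dim = c(g$nx, g$ny, g$nz))
  vals <- array(0, dim = c(g$nx, g$ny, g$nz, 3, frames))
  vz <- array(prof, dim = c(g$nx, g$ny, g$nz))
  for (t in seq_len(frames)) vals[, , , 3, t] <- vz
  field <- velocity_field4d(vals, rep(voxel, 3),
                            frame_times = seq(0, by = frame_dt,
                                              length.out = frames),
                            origin = g$origin)
  mask <- lumen_mask(mask3, rep(voxel, 3), g$origin)
  attr(mask, "max_radius_hint") <- R + 2 * voxel
  mu <- props$viscosity
  dp <- 8 * mu * (L * 1e-3) * Q_si / (pi * R_m^4)
  new_phantom(field, mask,
              truth = list(pressure_drop = dp, viscous_rate = Q_si * dp,
                           flow_rate = Q, diameter = 2 * R,
                           axis_start = c(0, 0, 0), axis_end = c(0, 0, L)),
              params = list(kind = "poiseuille", R = R, L = L, Q = Q,
                            voxel = voxel, frames = frames,
                            frame_dt = frame_dt))
}

# complex Bessel functions J0 and J1 by power series (adequate for the
# Womersley numbers of large-vessel haemodynamics, |z| up to ~25)
besselJ0_c <- function(z) {
  term <- rep(1 + 0i, length(z)); s <- term
  q <- -(z^2) / 4
  for (k in 1:80) {
    term <- term * q / (k * k)
    s <- s + term
    if (all(Mod(term) < 1e-18 * pmax(Mod(s), 1))) break
  }
  s
}
besselJ1_c <- function(z) {
  term <- rep(1 + 0i, length(z)); s <- term
  q <- -(z^2) / 4
  for (k in 1:80) {
    term <- term * q / (k * (k + 1))
    s <- s + term
    if (all(Mod(term) < 1e-18 * pmax(Mod(s), 1))) break
  }
  s * z / 2
}

#' Pulsatile Womersley phantom
#'
#' Axial flow in a straight rigid tube: steady Poiseuille component for
#' `Q_mean` plus the analytic oscillatory Womersley solution (complex
#' Bessel-function profile) for a prescribed oscillatory flow
#' `Q_osc * cos(2 pi t / period)`. With `Q_osc = 0` the generator reduces
#' bit-for-bit to [poiseuille_phantom()]. Ground truth includes the
#' Womersley number and the amplitude and phase of the analytic driving
#' pressure gradient.
#'
#' @inheritParams poiseuille_phantom
#' @param Q_mean steady flow component, ml/s
#' @param Q_osc oscillatory flow amplitude, ml/s
#' @param period cycle length, ms
#' @param frames frames per cycle (>= 8); frame times sample one full
#'   period, endpoint excluded
#' @return a `phantom_truth`; `truth$alpha` (Womersley number),
#'   `truth$pgrad_amplitude` (Pa/m), `truth$pgrad_phase` (rad),
#'   `truth$q_waveform` (ml/s per frame)
#' @export
womersley_phantom <- function(R = 8, L = 80, Q_mean = 70, Q_osc = 30,
                              period = 700, frames = 24, voxel = 1,
                              props = fluid_properties()) {
  if (R <= 2 * voxel)
    stop("under-resolved radius: R must exceed two voxels")
  if (frames < 8) stop("at least 8 frames per cycle are required")
  base <- poiseuille_phantom(R, L, Q_mean, voxel, props, frames = frames,
                             frame_dt = period / frames)
  if (Q_osc == 0) {
    base$params$kind <- "womersley"
    return(base)
  }
  g <- tube_grid(R, L, voxel)
  R_m <- R * 1e-3
  omega <- 2 * pi / (period / 1000)
  nu <- props$viscosity / props$density
  alpha <- R_m * sqrt(omega / nu)
  zeta <- alpha * complex(modulus = 1, argument = 3 * pi / 4)  # i^(3/2) alpha
  F10 <- 1 - 2 * besselJ1_c(zeta) / (zeta * besselJ0_c(zeta))
  Q_osc_si <- Q_osc * 1e-6
  r <- sqrt(outer(g$x^2, g$y^2, `+`))      # mm
  inside2d <- r <= R
  uhat <- (Q_osc_si / (pi * R_m^2)) *
    (1 - besselJ0_c(zeta * (r / R)) / besselJ0_c(zeta)) / F10
  uhat[!inside2d] <- 0
  tt <- seq(0, by = period / frames, length.out = frames)
  for (t in seq_len(frames)) {
    osc <- Re(uhat * exp(1i * omega * tt[t] / 1000))
    base$field$values[, , , 3, t] <- base$field$values[, , , 3, t] +
      array(osc, dim = c(g$nx, g$ny, g$nz))
  }
  K <- 1i * props$density * omega * Q_osc_si / (pi * R_m^2 * F10)
  base$truth$alpha <- alpha
  base$truth$pgrad_amplitude <- Mod(K)
  base$truth$pgrad_phase <- Arg(K)
  base$truth$q_waveform <- Q_mean + Q_osc * cos(omega * tt / 1000)
  base$truth$period <- period
  base$params <- list(kind = "womersley", R = R, L = L, Q_mean = Q_mean,
                      Q_osc = Q_osc, period = period, frames = frames,
                      voxel = voxel)
  base
}

#' Tapered plug-flow phantom
#'
#' Plug (uniform) axial profile through a linearly tapering tube at
#' constant flow rate, so the speed rises as the lumen narrows; a small
#' analytic radial component keeps the field divergence-free. Ground truth
#' is the Bernoulli advective pressure difference
#' `rho (v_out^2 - v_in^2) / 2`.
#'
#' @param R_in,R_out inlet and outlet radii, mm (`R_out < R_in`; use the
#'   reversed orientation for a widening vessel)
#' @inheritParams poiseuille_phantom
#' @return a `phantom_truth` with `truth$advective_dp` (Pa),
#'   `truth$v_in`, `truth$v_out` (m/s)
#' @export
tapered_plug_phantom <- function(R_in = 10, R_out = 7, L = 80, Q = 70,
                                 voxel = 1, props = fluid_properties(),
                                 frames = 2, frame_dt = 30) {
  if (R_out >= R_in)
    stop("R_out must be smaller than R_in (reverse the orientation for widening)")
  if (R_out <= 2 * voxel)
    stop("under-resolved radius: R_out must exceed two voxels")
  g <- tube_grid(R_in, L, voxel)
  Q_si <- Q * 1e-6
  Rz <- R_in + (R_out - R_in) * g$z / L    # mm per slice, linear throughout
  dRdz <- (R_out - R_in) / L                                # dimensionless
  r <- sqrt(outer(g$x^2, g$y^2, `+`))                       # mm
  mask3 <- array(FALSE, dim = c(g$nx, g$ny, g$nz))
  vals <- array(0, dim = c(g$nx, g$ny, g$nz, 3, frames))
  ux <- uy <- uz <- array(0, dim = c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) {
    inside <- r <= Rz[k]
    mask3[, , k] <- inside
    A_si <- pi * (Rz[k] * 1e-3)^2
    u <- Q_si / A_si                                        # m/s
    # radial compensation: v_r = -(r/2) du/dz, du/dz = -2 u R'/R
    dudz <- -2 * u * dRdz / (Rz[k] * 1e-3)                  # 1/s
    vr_over_r <- -dudz / 2                                  # 1/s; v_r = vr_over_r * r_m
    sl <- matrix(0, g$nx, g$ny); sl[inside] <- u
    uz[, , k] <- sl
    slx <- vr_over_r * outer(g$x, rep(1, g$ny)) * 1e-3
    sly <- vr_over_r * outer(rep(1, g$nx), g$y) * 1e-3
    slx[!inside] <- 0; sly[!inside] <- 0
    ux[, , k] <- slx
    uy[, , k] <- sly
  }
  for (t in seq_len(frames)) {
    vals[, , , 1, t] <- ux; vals[, , , 2, t] <- uy; vals[, , , 3, t] <- uz
  }
  field <- velocity_field4d(vals, rep(voxel, 3),
                            seq(0, by = frame_dt, length.out = frames),
                            origin = g$origin)
  mask <- lumen_mask(mask3, rep(voxel, 3), g$origin)
  attr(mask, "max_radius_hint") <- R_in + 2 * voxel
  v_in <- Q_si / (pi * (R_in * 1e-3)^2)
  v_out <- Q_si / (pi * (R_out * 1e-3)^2)
  new_phantom(field, mask,
              truth = list(advective_dp = props$density *
                             (v_out^2 - v_in^2) / 2,
                           v_in = v_in, v_out = v_out, flow_rate = Q),
              params = list(kind = "tapered_plug", R_in = R_in,
                            R_out = R_out, L = L, Q = Q, voxel = voxel))
}

# Default pulse waveform: baseline plateau, S-shaped (raised-cosine)
# systolic upstroke, cosine decay back to baseline; f in [0, 1], foot
# (upstroke onset) at t = t0. Aortic flow acceleration peaks mid-upstroke,
# which is also the shape the intersecting-tangents foot method assumes.
pulse_waveform <- function(t, t0 = 150, t_up = 150, t_down = 250) {
  f <- numeric(length(t))
  ris <- t >= t0 & t < t0 + t_up
  dec <- t >= t0 + t_up & t < t0 + t_up + t_down
  f[ris] <- 0.5 - 0.5 * cos(pi * (t[ris] - t0) / t_up)
  f[dec] <- 0.5 + 0.5 * cos(pi * (t[dec] - t0 - t_up) / t_down)
  f
}

pulse_waveform_deriv <- function(t, t0 = 150, t_up = 150, t_down = 250) {
  d <- numeric(length(t))
  ris <- t >= t0 & t < t0 + t_up
  dec <- t >= t0 & t >= t0 + t_up & t < t0 + t_up + t_down
  d[ris] <- (pi / (2 * t_up)) * sin(pi * (t[ris] - t0) / t_up)
  d[dec] <- -(pi / (2 * t_down)) * sin(pi * (t[dec] - t0 - t_up) / t_down)
  d   # per ms
}

#' Propagating flow-wave phantom
#'
#' Plug axial flow whose waveform travels down the tube at wave speed `c`:
#' `Q(s, t) = Q0 * f(t - s/c)`, with an analytic radial compensation
#' keeping the field divergence-free and optional additive Gaussian
#' velocity noise at a stated SNR (defined against peak speed). Supports a
#' piecewise-constant wave speed.
#'
#' @param c wave speed in m/s; either a single value or a two-column
#'   matrix `cbind(s_end_mm, c_m_s)` of regions in arc-length order
#' @param L tube length, mm
#' @param R tube radius, mm
#' @param Q0 waveform amplitude, ml/s
#' @param period covered time span, ms
#' @param frames number of frames
#' @param voxel voxel size, mm
#' @param noise_snr peak-speed / noise-SD ratio; `Inf` for noiseless
#' @param seed RNG seed for the noise (required when `noise_snr` is finite)
#' @param foot_time waveform onset time at the tube entrance, ms
#' @return a `phantom_truth` with `truth$wave_speed`, `truth$delay(s)`
#'   (function: ms of transit to arc length s), `truth$foot_time`
#' @export
propagating_wave_phantom <- function(c = 4, L = 120, R = 6, Q0 = 60,
                                     period = 700, frames = 24, voxel = 1,
                                     noise_snr = Inf, seed = NULL,
                                     foot_time = 150) {
  if (is.matrix(c)) {
    if (any(c[, 2] <= 0)) stop("wave speeds must be positive")
  } else if (c <= 0) stop("wave speed must be positive")
  if (R <= 2 * voxel) stop("under-resolved radius")
  g <- tube_grid(R, L, voxel)
  A_si <- pi * (R * 1e-3)^2
  # transit delay (ms) to arc length s (mm); c in m/s == mm/ms
  delay_fun <- if (is.matrix(c)) {
    breaks <- c(0, c[, 1]); speeds <- c[, 2]
    function(s) {
      d <- numeric(length(s))
      inside <- pmin(pmax(s, 0), max(breaks))
      for (i in seq_along(speeds)) {
        seg <- pmin(pmax(inside - breaks[i], 0), breaks[i + 1] - breaks[i])
        d <- d + seg / speeds[i]
      }
      # linear continuation beyond the defined region (grid margins)
      d + pmin(s, 0) / speeds[1] + pmax(s - max(breaks), 0) / speeds[length(speeds)]
    }
  } else function(s) s / c
  tt <- seq(0, period, length.out = frames)
  mask2 <- outer(g$x^2, g$y^2, `+`) <= R^2
  mask3 <- array(mask2, dim = c(g$nx, g$ny, g$nz))
  vals <- array(0, dim = c(g$nx, g$ny, g$nz, 3, frames))
  c_local <- if (is.matrix(c)) {
    # speed of the region each slice falls in
    vapply(g$z, function(z) {
      i <- findInterval(min(max(z, 0), max(c[, 1]) - 1e-9), c(0, c[, 1]),
                        rightmost.closed = TRUE)
      c[max(1L, min(i, nrow(c))), 2]
    }, numeric(1))
  } else rep(c, g$nz)
  dly <- delay_fun(g$z)
  r_m <- sqrt(outer(g$x^2, g$y^2, `+`)) * 1e-3
  for (t in seq_len(frames)) {
    tau <- tt[t] - dly
    fz <- pulse_waveform(tau, t0 = foot_time)
    dfz <- pulse_waveform_deriv(tau, t0 = foot_time) * 1000  # per s
    u <- Q0 * 1e-6 * fz / A_si                               # m/s per slice
    # v_r = (r / (2 c)) du/dt keeps div v = 0 for the travelling wave
    dudt <- Q0 * 1e-6 * dfz / A_si
    for (k in seq_len(g$nz)) {
      sl <- matrix(0, g$nx, g$ny); sl[mask2] <- u[k]
      vals[, , k, 3, t] <- sl
      vro <- (r_m / (2 * c_local[k])) * dudt[k]
      vrx <- vro * outer(g$x, rep(1, g$ny)) / pmax(r_m / 1e-3, 1e-9)
      vry <- vro * outer(rep(1, g$nx), g$y) / pmax(r_m / 1e-3, 1e-9)
      vrx[!mask2] <- 0; vry[!mask2] <- 0
      vals[, , k, 1, t] <- vrx
      vals[, , k, 2, t] <- vry
    }
  }
  if (is.finite(noise_snr)) {
    if (is.null(seed)) stop("a seed is required for reproducible noise")
    peak <- max(abs(vals))
    sd_n <- peak / noise_snr
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    nz <- array(stats::rnorm(length(vals), sd = sd_n), dim = dim(vals))
    m5 <- array(mask3, dim = dim(vals))   # recycle mask over comp & frame
    vals <- vals + nz * m5
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }
  field <- velocity_field4d(vals, rep(voxel, 3), tt, origin = g$origin)
  mask <- lumen_mask(mask3, rep(voxel, 3), g$origin)
  attr(mask, "max_radius_hint") <- R + 2 * voxel
  new_phantom(field, mask,
              truth = list(wave_speed = c, delay = delay_fun,
                           foot_time = foot_time, flow_amplitude = Q0,
                           axis_start = c(0, 0, 0), axis_end = c(0, 0, L)),
              params = list(kind = "propagating_wave", c = c, L = L, R = R,
                            Q0 = Q0, period = period, frames = frames,
                            voxel = voxel, noise_snr = noise_snr,
                            seed = seed, foot_time = foot_time))
}

#' Torus-segment phantom
#'
#' Lumen mask of a circular-arc tube (no flow): ground truth for the
#' three-point curvature (`1/R_t`) and effective diameter (`2 r_tube`).
#'
#' @param R_t ring (centreline) radius, mm
#' @param r_tube tube radius, mm (`r_tube < R_t`)
#' @param arc arc angle in degrees
#' @param voxel voxel size, mm
#' @return a `phantom_truth`; `truth$curvature` in 1/m, `truth$diameter`
#'   and `truth$arc_length` in mm, plus the exact centreline end points
#' @export
torus_phantom <- function(R_t = 50, r_tube = 8, arc = 180, voxel = 1) {
  if (r_tube >= R_t) stop("r_tube must be smaller than R_t")
  if (r_tube <= 2 * voxel) stop("under-resolved tube radius")
  half <- R_t + r_tube + 3 * voxel
  x <- seq(-half, half, by = voxel)
  zc <- seq(-(r_tube + 3 * voxel), r_tube + 3 * voxel, by = voxel)
  nx <- length(x); nz <- length(zc)
  arc_rad <- arc * pi / 180
  mask3 <- array(FALSE, dim = c(nx, nx, nz))
  rho <- sqrt(outer(x^2, x^2, `+`))        # nx x nx, in-plane radius
  theta <- atan2(outer(rep(1, nx), x), outer(x, rep(1, nx)))
  theta <- ifelse(theta < 0, theta + 2 * pi, theta)
  for (k in seq_len(nz)) {
    d2 <- (rho - R_t)^2 + zc[k]^2
    mask3[, , k] <- d2 <= r_tube^2 & theta <= arc_rad + 1e-12
  }
  origin <- c(x[1], x[1], zc[1])
  mask <- lumen_mask(mask3, rep(voxel, 3), origin)
  attr(mask, "max_radius_hint") <- r_tube + 2 * voxel
  vals <- array(0, dim = c(nx, nx, nz, 3, 2))
  field <- velocity_field4d(vals, rep(voxel, 3), c(0, 30), origin = origin)
  new_phantom(field, mask,
              truth = list(curvature = 1000 / R_t, diameter = 2 * r_tube,
                           arc_length = R_t * arc_rad,
                           start_point = c(R_t, 0, 0),
                           end_point = c(R_t * cos(arc_rad),
                                         R_t * sin(arc_rad), 0)),
              params = list(kind = "torus", R_t = R_t, r_tube = r_tube,
                            arc = arc, voxel = voxel))
}
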