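# Conduit-function metrics: the work-energy relative pressure (WERP)
# decomposition of the pressure difference along a vascular segment,
#
#   dP_tot = (1/Q) * (dKe/dt + Ae + Ve),
#
# its kinetic (temporal acceleration), advective (spatial acceleration)
# and viscous components, the simplified advective pressure (SAW) at a
# cross section, and timing descriptors of the systolic transients.
# Sign convention: a positive pressure difference means a larger pressure
# in the entry than in the exit plane of the segment.

# interpolate the three velocity components at world points (n x 3 m/s)
velocity_at <- function(field, pts, frame) {
  vox <- world_to_voxel(pts, field$spacing, field$origin)
  cbind(trilinear(field$values[, , , 1, frame], vox),
        trilinear(field$values[, , , 2, frame], vox),
        trilinear(field$values[, , , 3, frame], vox))
}

# Precomputed trilinear gather for a fixed set of points: 8 corner linear
# indices and weights per point, so per-frame evaluation is a single
# indexed sum. Used to evaluate plane fluxes over many frames cheaply.
interp_weights <- function(dim3, vox) {
  d <- dim3
  i0 <- floor(vox)
  i0[, 1] <- pmin(pmax(i0[, 1], 1), d[1] - 1)
  i0[, 2] <- pmin(pmax(i0[, 2], 1), d[2] - 1)
  i0[, 3] <- pmin(pmax(i0[, 3], 1), d[3] - 1)
  f <- vox - i0
  f[f < 0] <- 0; f[f > 1] <- 1
  idx <- function(di, dj, dk)
    (i0[, 1] + di) + d[1] * ((i0[, 2] + dj) - 1) + d[1] * d[2] * ((i0[, 3] + dk) - 1)
  W <- rbind((1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]),
             f[, 1] * (1 - f[, 2]) * (1 - f[, 3]),
             (1 - f[, 1]) * f[, 2] * (1 - f[, 3]),
             f[, 1] * f[, 2] * (1 - f[, 3]),
             (1 - f[, 1]) * (1 - f[, 2]) * f[, 3],
             f[, 1] * (1 - f[, 2]) * f[, 3],
             (1 - f[, 1]) * f[, 2] * f[, 3],
             f[, 1] * f[, 2] * f[, 3])
  I <- rbind(idx(0, 0, 0), idx(1, 0, 0), idx(0, 1, 0), idx(1, 1, 0),
             idx(0, 0, 1), idx(1, 0, 1), idx(0, 1, 1), idx(1, 1, 1))
  list(I = I, W = W)
}

apply_interp <- function(vol, iw) colSums(matrix(vol[iw$I], nrow = 8) * iw$W)

plane_interp_weights <- function(field, cs) {
  vox <- world_to_voxel(cs$samples, field$spacing, field$origin)
  interp_weights(dim(field$values)[1:3], vox)
}

#' Flow rate through a cross-section
#'
#' Integrates the velocity component normal to the plane over the lumen
#' portion of the cross-section, `Q = integral of v . n dA`, with the
#' velocity interpolated trilinearly onto the in-plane sampling grid.
#' Positive in the downstream (tangent) direction.
#'
#' @param field a [velocity_field4d()]
#' @param plane a `cross_section` from [cross_section_at()]
#' @param frame frame index
#' @return flow rate in ml/s
#' @export
flow_rate <- function(field, plane, frame) {
  ext <- voxel_to_world(rbind(rep(1, 3), dim(field$values)[1:3]),
                        field$spacing, field$origin)
  if (any(plane$center < ext[1, ] - field$spacing) ||
      any(plane$center > ext[2, ] + field$spacing))
    stop("cross-section plane lies outside the velocity field extent")
  v <- velocity_at(field, plane$samples, frame)
  vn <- v %*% plane$normal
  sum(vn) * plane$pixel_area   # (m/s) * mm^2 == ml/s
}

# flux integrals for one frame given precomputed weights:
#   q: integral v.n dA          (ml/s)
#   ke_flux: integral |v|^2 (v.n) dA  (SI, W per (rho/2))
plane_fluxes <- function(field, cs, iw, frame) {
  vx <- apply_interp(field$values[, , , 1, frame], iw)
  vy <- apply_interp(field$values[, , , 2, frame], iw)
  vz <- apply_interp(field$values[, , , 3, frame], iw)
  vn <- vx * cs$normal[1] + vy * cs$normal[2] + vz * cs$normal[3]
  v2 <- vx^2 + vy^2 + vz^2
  list(q = sum(vn) * cs$pixel_area,
       ke_flux = sum(v2 * vn) * cs$pixel_area * 1e-6)
}

#' Segment control volume between two cross-sections
#'
#' The lumen voxels between the inlet and outlet planes (half-spaces
#' bounded by the two planes with downstream normals), restricted to the
#' connected component containing the mid-segment centreline point so that
#' branch lumens are excluded.
#'
#' @param mask a [lumen_mask()]
#' @param inlet,outlet `cross_section` objects, ordered by arc length
#' @param cl the `centreline` (used to seed the interior component)
#' @return an object of class `segment_control_volume`
#' @export
segment_control_volume <- function(mask, inlet, outlet, cl) {
  if (outlet$station <= inlet$station)
    stop("outlet plane must lie downstream of the inlet plane")
  d <- dim(mask$voxels)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  w <- voxel_to_world(idx, mask$spacing, mask$origin)
  keep <- (sweep(w, 2, inlet$center, `-`) %*% inlet$normal) >= 0 &
    (sweep(w, 2, outlet$center, `-`) %*% outlet$normal) <= 0
  interior <- array(FALSE, d)
  interior[idx[keep, , drop = FALSE]] <- TRUE
  interior <- interior & mask$voxels
  if (!any(interior)) stop("empty control volume between the planes")
  mid <- centreline_at(cl, (inlet$station + outlet$station) / 2)
  seed <- round(world_to_voxel(mid$point, mask$spacing, mask$origin))
  seed <- pmin(pmax(as.integer(seed), 1L), d)
  if (!interior[seed[1], seed[2], seed[3]]) {
    cand <- which(interior, arr.ind = TRUE)
    dd <- rowSums(sweep(cand, 2, as.numeric(seed), `-`)^2)
    seed <- cand[which.min(dd), ]
  }
  interior <- connected_component3(interior, seed)
  structure(list(inlet = inlet, outlet = outlet, interior = interior,
                 spacing = mask$spacing, origin = mask$origin),
            class = "segment_control_volume")
}

#' Kinetic energy in a control volume
#'
#' `Ke = (rho/2) * sum over lumen voxels of |v|^2 * voxel volume`.
#'
#' @param field a [velocity_field4d()]
#' @param cv a [segment_control_volume()] (or a [lumen_mask()], in which
#'   case the whole lumen is used)
#' @param frame frame index
#' @param props [fluid_properties()]
#' @return kinetic energy in J
#' @export
kinetic_energy <- function(field, cv, frame, props = fluid_properties()) {
  interior <- if (inherits(cv, "lumen_mask")) cv$voxels else cv$interior
  if (!any(interior)) stop("empty control volume")
  v2 <- field$values[, , , 1, frame]^2 + field$values[, , , 2, frame]^2 +
    field$values[, , , 3, frame]^2
  (props$density / 2) * sum(v2[interior]) * voxel_volume_m3(field$spacing)
}

#' Temporal rate of change of kinetic energy
#'
#' Central finite differences of the kinetic-energy series over frames;
#' one-sided at the first and last frame of a non-periodic series, periodic
#' wrap when the cycle is marked periodic.
#'
#' @param ke kinetic energy per frame (J)
#' @param frame_times frame times in ms
#' @param periodic wrap the differences around the cycle
#' @param period cycle length in ms (needed for the periodic wrap; defaults
#'   to the frame spacing extrapolated one step past the last frame)
#' @return dKe/dt per frame, in W
#' @export
kinetic_energy_rate <- function(ke, frame_times, periodic = FALSE,
                                period = NULL) {
  T <- length(ke)
  if (T < 2L) stop("at least two frames are needed for a temporal derivative")
  t_s <- frame_times / 1000
  dk <- numeric(T)
  if (T == 2L) return(rep(diff(ke) / diff(t_s), 2L))
  dk[2:(T - 1)] <- (ke[3:T] - ke[1:(T - 2)]) / (t_s[3:T] - t_s[1:(T - 2)])
  if (periodic) {
    if (is.null(period)) period <- (frame_times[T] + mean(diff(frame_times))) -
        frame_times[1]
    per_s <- period / 1000
    dk[1] <- (ke[2] - ke[T]) / ((t_s[2] - t_s[T]) + per_s)
    dk[T] <- (ke[1] - ke[T - 1]) / ((t_s[1] + per_s) - t_s[T - 1])
  } else {
    dk[1] <- (ke[2] - ke[1]) / (t_s[2] - t_s[1])
    dk[T] <- (ke[T] - ke[T - 1]) / (t_s[T] - t_s[T - 1])
  }
  dk
}

#' Advective energy flux of a segment
#'
#' Net kinetic-energy flux out of the control volume through its two
#' planes, `Ae = (rho/2) * (integral_outlet |v|^2 v.n dA -
#' integral_inlet |v|^2 v.n dA)` with both normals pointing downstream.
#' Positive when the momentum leaving the outlet exceeds the momentum
#' entering the inlet.
#'
#' @inheritParams kinetic_energy
#' @return advective energy rate in W
#' @export
advective_energy <- function(field, cv, frame, props = fluid_properties()) {
  iw_in <- plane_interp_weights(field, cv$inlet)
  iw_out <- plane_interp_weights(field, cv$outlet)
  fi <- plane_fluxes(field, cv$inlet, iw_in, frame)
  fo <- plane_fluxes(field, cv$outlet, iw_out, frame)
  (props$density / 2) * (fo$ke_flux - fi$ke_flux)
}

# ---- viscous dissipation ----------------------------------------------------

# Gradient of one velocity component along one axis inside the mask:
# second-order central differences where both neighbours are lumen voxels,
# first-order one-sided differences using the interior neighbour at the
# wall (ghost values across the wall would create spurious tangential
# gradients on the voxelised boundary).
masked_gradient <- function(v, mask, axis, h_m) {
  vm <- v; vm[!mask] <- 0
  vp <- shift3(vm, axis, 1L);  mp <- shift3(mask, axis, 1L)
  vmn <- shift3(vm, axis, -1L); mn <- shift3(mask, axis, -1L)
  g <- (vp - vmn) / (2 * h_m)
  onlyp <- mp & !mn
  onlym <- mn & !mp
  g[onlyp] <- ((vp - vm) / h_m)[onlyp]
  g[onlym] <- ((vm - vmn) / h_m)[onlym]
  g[!mp & !mn] <- 0
  g[!mask] <- 0
  g
}

#' Laminar viscous energy dissipation rate
#'
#' `Ve = sum over lumen voxels of 2 mu (eps : eps) * voxel volume`, with
#' the strain-rate tensor `eps = (grad v + grad v^T) / 2` evaluated by
#' central differences inside the lumen and one-sided differences at the
#' wall. Always non-negative.
#'
#' @inheritParams kinetic_energy
#' @return viscous dissipation rate in W
#' @export
viscous_energy_rate <- function(field, cv, frame, props = fluid_properties()) {
  interior <- if (inherits(cv, "lumen_mask")) cv$voxels else cv$interior
  if (!any(interior)) stop("empty control volume")
  h <- field$spacing * 1e-3
  g <- vector("list", 9)
  k <- 0
  for (comp in 1:3) {
    v <- field$values[, , , comp, frame]
    for (axis in 1:3) {
      k <- k + 1
      g[[k]] <- masked_gradient(v, interior, axis, h[axis])
    }
  }
  # g[[3*(c-1)+a]] = d v_c / d x_a ; eps_ca = (dv_c/dx_a + dv_a/dx_c)/2
  ee <- array(0, dim(interior))
  for (ci in 1:3) for (ai in 1:3) {
    eps <- (g[[3 * (ci - 1) + ai]] + g[[3 * (ai - 1) + ci]]) / 2
    ee <- ee + eps^2
  }
  2 * props$viscosity * sum(ee[interior]) * voxel_volume_m3(field$spacing)
}

# ---- WERP traces ------------------------------------------------------------

#' WERP pressure traces over a vascular segment
#'
#' Evaluates the work-energy relative pressure decomposition for every
#' frame: `dp_kin = (1/Q) dKe/dt`, `dp_adv = (1/Q) Ae`, `dp_visc = (1/Q)
#' Ve` and their sum `dp_tot`, with `Q` the mean of the inlet and outlet
#' plane fluxes. Frames whose `|Q|` falls below `q_min_frac` of the cycle
#' peak are flagged invalid and returned as `NaN` (the quotient is
#' meaningless near zero flow).
#'
#' @param field a [velocity_field4d()]
#' @param cv a [segment_control_volume()]
#' @param props [fluid_properties()]
#' @param periodic treat the frame series as one periodic cycle
#' @param q_min_frac validity threshold as a fraction of peak `|Q|`
#' @param period cycle length in ms (periodic case)
#' @return an object of class `pressure_traces`: data frame with columns
#'   `time_ms`, `q_ml_s`, `q_in_ml_s`, `q_out_ml_s`, `dp_tot_mmhg`,
#'   `dp_kin_mmhg`, `dp_adv_mmhg`, `dp_visc_mmhg`, `ve_rate_mj_s`, `valid`
#' @export
segment_pressure_traces <- function(field, cv, props = fluid_properties(),
                                    periodic = FALSE, q_min_frac = 0.1,
                                    period = NULL) {
  T <- dim(field$values)[5]
  iw_in <- plane_interp_weights(field, cv$inlet)
  iw_out <- plane_interp_weights(field, cv$outlet)
  q_in <- q_out <- ae <- ve <- ke <- numeric(T)
  for (t in seq_len(T)) {
    fi <- plane_fluxes(field, cv$inlet, iw_in, t)
    fo <- plane_fluxes(field, cv$outlet, iw_out, t)
    q_in[t] <- fi$q; q_out[t] <- fo$q
    ae[t] <- (props$density / 2) * (fo$ke_flux - fi$ke_flux)
    ve[t] <- viscous_energy_rate(field, cv, t, props)
    ke[t] <- kinetic_energy(field, cv, t, props)
  }
  dke <- kinetic_energy_rate(ke, field$frame_times, periodic, period)
  q <- (q_in + q_out) / 2
  q_si <- q * 1e-6
  valid <- abs(q) >= q_min_frac * max(abs(q))
  dp_kin <- pa_to_mmhg(dke / q_si)
  dp_adv <- pa_to_mmhg(ae / q_si)
  dp_visc <- pa_to_mmhg(ve / q_si)
  dp_kin[!valid] <- NaN; dp_adv[!valid] <- NaN; dp_visc[!valid] <- NaN
  out <- data.frame(time_ms = field$frame_times, q_ml_s = q,
                    q_in_ml_s = q_in, q_out_ml_s = q_out,
                    dp_tot_mmhg = dp_kin + dp_adv + dp_visc,
                    dp_kin_mmhg = dp_kin, dp_adv_mmhg = dp_adv,
                    dp_visc_mmhg = dp_visc, ve_rate_mj_s = ve * 1000,
                    valid = valid)
  class(out) <- c("pressure_traces", "data.frame")
  out
}

#' WERP pressure components at one frame
#'
#' Convenience wrapper around [segment_pressure_traces()] returning the
#' decomposition at a single frame.
#'
#' @inheritParams segment_pressure_traces
#' @param frame frame index
#' @return named list `dp_tot`, `dp_kin`, `dp_adv`, `dp_visc` (mmHg)
#' @export
werp_pressure <- function(field, cv, frame, props = fluid_properties(),
                          periodic = FALSE, q_min_frac = 0.1) {
  tr <- segment_pressure_traces(field, cv, props, periodic, q_min_frac)
  list(dp_tot = tr$dp_tot_mmhg[frame], dp_kin = tr$dp_kin_mmhg[frame],
       dp_adv = tr$dp_adv_mmhg[frame], dp_visc = tr$dp_visc_mmhg[frame])
}

#' Simplified advective pressure at a cross-section (SAW)
#'
#' The pressure required to accelerate the full velocity profile observed
#' at a cross-section from rest: `dP = (rho / (2 Q)) * integral |v|^2
#' (v . n) dA`. This is a profile-aware correction of the simplified
#' Bernoulli estimate (which uses a single peak velocity) and neglects the
#' proximal inlet velocity. For uniform plug flow it reduces to
#' `rho v^2 / 2`; for a parabolic profile with mean speed `v` it equals
#' `rho v^2`.
#'
#' @param field a [velocity_field4d()]
#' @param plane a `cross_section`
#' @param frame frame index
#' @param props [fluid_properties()]
#' @param q_min absolute validity threshold on `|Q|` in ml/s; by default
#'   10 percent of the cycle-peak `|Q|` through this plane
#' @return pressure in mmHg, or `NaN` when `|Q|` is below the threshold
#' @export
saw_pressure <- function(field, plane, frame, props = fluid_properties(),
                         q_min = NULL) {
  iw <- plane_interp_weights(field, plane)
  if (is.null(q_min)) {
    qs <- vapply(seq_len(dim(field$values)[5]),
                 function(t) plane_fluxes(field, plane, iw, t)$q, numeric(1))
    q_min <- 0.1 * max(abs(qs))
  }
  fl <- plane_fluxes(field, plane, iw, frame)
  if (abs(fl$q) < q_min) return(NaN)
  pa_to_mmhg((props$density / (2 * fl$q * 1e-6)) * fl$ke_flux)
}

#' Simplified advective pressure profile along the centreline
#'
#' Evaluates [saw_pressure()] at every 1-mm centreline station at the
#' peak-systolic frame (by default the frame maximising the flow rate at
#' the first station). Per-segment deltas are the value at the segment end
#' minus the value at the segment start.
#'
#' @param field a [velocity_field4d()]
#' @param mask a [lumen_mask()]
#' @param cl a `centreline`
#' @param props [fluid_properties()]
#' @param frame peak-systolic frame; `NULL` selects it from the inlet flow
#' @param seg optional `segment_definition` for per-segment deltas
#' @return list with `profile` (data frame: station_mm, saw_mmhg, valid),
#'   `frame`, and `segment_delta` (named vector, mmHg) when `seg` is given
#' @export
saw_profile <- function(field, mask, cl, props = fluid_properties(),
                        frame = NULL, seg = NULL) {
  stations <- cl$arc_length
  cs0 <- cross_section_at(mask, cl, stations[1])
  iw0 <- plane_interp_weights(field, cs0)
  qs <- vapply(seq_len(dim(field$values)[5]),
               function(t) plane_fluxes(field, cs0, iw0, t)$q, numeric(1))
  if (is.null(frame)) frame <- which.max(qs)
  vals <- vapply(stations, function(s) {
    cs <- tryCatch(cross_section_at(mask, cl, s), error = function(e) NULL)
    if (is.null(cs)) return(NaN)
    saw_pressure(field, cs, frame, props)
  }, numeric(1))
  profile <- data.frame(station_mm = stations, saw_mmhg = vals,
                        valid = is.finite(vals))
  out <- list(profile = profile, frame = frame)
  if (!is.null(seg)) {
    b <- seg$boundaries
    delta <- vapply(seq_len(nrow(b)), function(i) {
      i0 <- which.min(abs(stations - b$s_start[i]))
      i1 <- which.min(abs(stations - b$s_end[i]))
      vals[i1] - vals[i0]
    }, numeric(1))
    names(delta) <- b$label
    out$segment_delta <- delta
  }
  out
}

#' Timing descriptors of the pressure transients
#'
#' Time to peak of `dp_tot` and `dp_kin` (three-point parabolic sub-frame
#' interpolation around the discrete maximum) and the first zero crossing
#' of `dp_kin` after its peak (linear interpolation between frames). A
#' missing crossing is reported as `NA`, not an error.
#'
#' @param traces a `pressure_traces` object
#' @return object of class `timing_metrics`: `t_peak_dp_tot`,
#'   `t_peak_dp_kin`, `t_zero_crossing_dp_kin` (ms)
#' @export
timing_metrics <- function(traces) {
  tt <- traces$time_ms
  peak_time <- function(y) {
    ok <- is.finite(y)
    if (!any(ok)) return(NA_real_)
    i <- which(ok)[which.max(y[ok])]
    if (i > 1 && i < length(y) && is.finite(y[i - 1]) && is.finite(y[i + 1])) {
      # parabola through the three points around the discrete peak
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (denom < 0) {
        delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
        dt <- (tt[i + 1] - tt[i - 1]) / 2
        return(tt[i] + delta * dt)
      }
    }
    tt[i]
  }
  t_tot <- peak_time(traces$dp_tot_mmhg)
  y <- traces$dp_kin_mmhg
  t_kin <- peak_time(y)
  ipk <- which(is.finite(y))[which.max(y[is.finite(y)])]
  t_zero <- NA_real_
  if (length(ipk) && ipk < length(y)) {
    tol <- 1e-12 * max(abs(y), na.rm = TRUE)   # exact-zero terminal samples
    for (i in ipk:(length(y) - 1L)) {
      if (is.finite(y[i]) && is.finite(y[i + 1]) && y[i] > tol &&
          y[i + 1] <= tol) {
        t_zero <- tt[i] + (tt[i + 1] - tt[i]) * y[i] / (y[i] - y[i + 1])
        break
      }
    }
  }
  structure(list(t_peak_dp_tot = t_tot, t_peak_dp_kin = t_kin,
                 t_zero_crossing_dp_kin = t_zero),
            class = "timing_metrics")
}

#' @export
print.timing_metrics <- function(x, ...) {
  cat(sprintf(paste0("<timing_metrics> peak dP_tot %.1f ms, peak dP_kin ",
                     "%.1f ms, zero-crossing dP_kin %.1f ms\n"),
              x$t_peak_dp_tot, x$t_peak_dp_kin, x$t_zero_crossing_dp_kin))
  invisible(x)
}
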