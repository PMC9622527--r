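# Reservoir-function metrics: flow waveforms along the centreline,
# foot-to-foot transit times, pulse wave velocity (PWV) and the
# Moens-Korteweg elastic modulus E = rho * PWV^2 * D / h.

#' Flow waveforms at every centreline station
#'
#' Evaluates the flow rate through the perpendicular cross-section at
#' every 1-mm centreline station and every frame, then upsamples each
#' waveform in time by cubic-spline interpolation for sub-frame foot
#' detection (per-millimetre transit times are a fraction of a
#' millisecond, far below the native frame spacing).
#'
#' @param field a [velocity_field4d()]
#' @param mask a [lumen_mask()]
#' @param cl a `centreline` resampled at 1-mm stations
#' @param upsample temporal upsampling factor (default 20)
#' @param sections optional list of precomputed `cross_section`s (one per
#'   station), e.g. to reuse geometry across noise realisations
#' @return an object of class `waveform_series`: `stations` (mm), `q`
#'   (station x frame matrix, ml/s), `frame_times` (ms), `q_fine` and
#'   `fine_times` (upsampled), `sections`
#' @export
waveform_series <- function(field, mask, cl, upsample = 20,
                            sections = NULL) {
  stations <- cl$arc_length
  if (is.null(sections))
    sections <- lapply(stations, function(s) cross_section_at(mask, cl, s))
  T <- dim(field$values)[5]
  q <- matrix(NA_real_, nrow = length(stations), ncol = T)
  iws <- lapply(sections, function(cs) plane_interp_weights(field, cs))
  for (t in seq_len(T)) {        # frame-outer: one slice extraction per frame
    vx <- field$values[, , , 1, t]
    vy <- field$values[, , , 2, t]
    vz <- field$values[, , , 3, t]
    for (i in seq_along(sections)) {
      cs <- sections[[i]]; iw <- iws[[i]]
      vn <- apply_interp(vx, iw) * cs$normal[1] +
        apply_interp(vy, iw) * cs$normal[2] +
        apply_interp(vz, iw) * cs$normal[3]
      q[i, t] <- sum(vn) * cs$pixel_area
    }
  }
  tt <- field$frame_times
  fine_times <- seq(tt[1], tt[T], length.out = (T - 1) * upsample + 1)
  q_fine <- t(apply(q, 1, function(y)
    stats::spline(tt, y, xout = fine_times, method = "fmm")$y))
  structure(list(stations = stations, q = q, frame_times = tt,
                 q_fine = q_fine, fine_times = fine_times,
                 upsample = upsample, sections = sections),
            class = "waveform_series")
}

#' @export
print.waveform_series <- function(x, ...) {
  cat(sprintf("<waveform_series> %d stations x %d frames (x%d upsampled)\n",
              length(x$stations), ncol(x$q), x$upsample))
  invisible(x)
}

#' Foot of a flow waveform (intersecting tangents)
#'
#' Locates the onset of the systolic upstroke: the baseline is the mean of
#' the pre-upstroke minimum plateau (samples within 2 percent of the waveform
#' range above the pre-upstroke minimum), the upstroke tangent is taken at
#' the point of maximum dQ/dt, and the foot is the time where the tangent
#' intersects the baseline.
#'
#' @param q single flow waveform (preferably upsampled)
#' @param times sample times, ms
#' @param smooth_ms half-width (ms) of the running-mean applied to the
#'   waveform derivative before locating the steepest upstroke; defaults
#'   to half the median native frame interval implied by 20x upsampling,
#'   i.e. noise at sub-frame scale is averaged out while the upstroke
#'   (an order of magnitude longer) is untouched
#' @return foot time in ms
#' @export
waveform_foot <- function(q, times, smooth_ms = NULL) {
  n <- length(q)
  if (n < 5L) stop("waveform too short for foot detection")
  rng <- diff(range(q))
  if (rng <= 0 || rng < 1e-12 * max(abs(q), 1))
    stop("flat waveform: no systolic upstroke to locate")
  dt <- stats::median(diff(times))
  if (is.null(smooth_ms)) smooth_ms <- 10 * dt
  half <- max(0L, round(smooth_ms / dt))
  dq <- diff(q) / diff(times)
  if (half > 0L && length(dq) > 2L * half + 1L) {
    k <- rep(1 / (2 * half + 1), 2 * half + 1)
    dq_s <- stats::filter(dq, k, sides = 2)
    pad <- is.na(dq_s)
    dq_s[pad] <- dq[pad]
    dq <- as.numeric(dq_s)
  }
  i_up <- which.max(dq)            # steepest upstroke interval
  slope <- dq[i_up]
  if (slope <= 0) stop("waveform has no rising upstroke")
  t_up <- (times[i_up] + times[i_up + 1]) / 2
  lo <- max(1L, i_up - half); hi <- min(n, i_up + 1L + half)
  q_up <- mean(q[lo:hi])
  pre <- seq_len(i_up)
  q_min <- min(q[pre])
  plateau <- pre[q[pre] <= q_min + 0.02 * rng]
  baseline <- mean(q[plateau])
  t_up - (q_up - baseline) / slope
}

#' Pulse wave velocity profile from foot-to-foot transit times
#'
#' Detects the waveform foot at every station, then estimates PWV in a
#' moving window along the vessel: within each window the foot times are
#' regressed on arc length and PWV is the inverse slope (equivalently, the
#' window span divided by the moving-averaged foot-time difference).
#' Windows with a non-positive averaged delay (retrograde or
#' noise-dominated) are flagged invalid rather than raising an error.
#'
#' @param ws a [waveform_series()]
#' @param window moving-average window span in mm (default 20)
#' @return an object of class `stiffness_profile` (PWV part): data frame
#'   `stations`, `foot_ms`, `pwv` (m/s, `NA` where invalid), `valid`
#' @export
pwv_estimate <- function(ws, window = 20) {
  s <- ws$stations
  foot <- vapply(seq_along(s), function(i)
    tryCatch(waveform_foot(ws$q_fine[i, ], ws$fine_times),
             error = function(e) NA_real_), numeric(1))
  half <- window / 2
  pwv <- rep(NA_real_, length(s))
  for (i in seq_along(s)) {
    in_w <- which(s >= s[i] - half - 1e-9 & s <= s[i] + half + 1e-9 &
                    is.finite(foot))
    if (length(in_w) < 2L) next
    sx <- s[in_w]; ty <- foot[in_w]
    slope <- stats::cov(sx, ty) / stats::var(sx)    # ms per mm
    if (is.finite(slope) && slope > 0) pwv[i] <- 1 / slope   # mm/ms == m/s
  }
  structure(list(stations = s, foot_ms = foot, pwv = pwv,
                 valid = is.finite(pwv), window = window),
            class = "stiffness_profile")
}

#' Moens-Korteweg elastic modulus
#'
#' `E = rho * PWV^2 * D / h` with lumen diameter `D` and wall thickness
#' `h`. The `D/h` ratio is invariant to BSA indexing, so indexed values
#' may be supplied for both.
#'
#' @param pwv pulse wave velocity, m/s
#' @param diameter lumen diameter (mm, or mm/m^2 if indexed)
#' @param thickness wall thickness (same indexing as `diameter`)
#' @param props [fluid_properties()]
#' @return elastic modulus in kPa
#' @export
#' @examples
#' moens_korteweg(4.3, 28.0, 3.7)  # about 148 kPa
moens_korteweg <- function(pwv, diameter, thickness,
                           props = fluid_properties()) {
  if (any(diameter <= 0, na.rm = TRUE)) stop("diameter must be positive")
  if (any(thickness <= 0, na.rm = TRUE)) stop("wall thickness must be positive")
  props$density * pwv^2 * (diameter / thickness) / 1000
}

#' Stiffness profile and per-segment reservoir summary
#'
#' Combines the PWV profile with local diameter and wall thickness to give
#' the Moens-Korteweg elastic modulus per station, and reports per-segment
#' means of PWV and E. Invalid windows are excluded from segment means and
#' counted in the QC fields; a segment with no valid window reports `NA`.
#'
#' @param ws a [waveform_series()]
#' @param diameter per-station lumen diameter, mm (length of `ws$stations`,
#'   or a single value)
#' @param thickness per-station wall thickness, mm (or a single value)
#' @param seg a `segment_definition`
#' @param props [fluid_properties()]
#' @param window PWV moving-average window, mm
#' @return list with `profile` (data frame: station_mm, foot_ms, pwv_m_s,
#'   e_kpa, valid) and `segments` (data frame: segment, pwv, e_kpa,
#'   n_valid, n_invalid)
#' @export
stiffness_profile <- function(ws, diameter, thickness, seg,
                              props = fluid_properties(), window = 20) {
  sp <- pwv_estimate(ws, window)
  n <- length(sp$stations)
  diameter <- rep_len(diameter, n)
  thickness <- rep_len(thickness, n)
  e <- ifelse(sp$valid,
              moens_korteweg(sp$pwv, diameter, thickness, props), NA_real_)
  profile <- data.frame(station_mm = sp$stations, foot_ms = sp$foot_ms,
                        pwv_m_s = sp$pwv, e_kpa = e, valid = sp$valid)
  segments <- NULL
  if (!is.null(seg)) {
    lab <- segment_membership(sp$stations, seg)
    segments <- do.call(rbind, lapply(seg$boundaries$label, function(L) {
      in_seg <- !is.na(lab) & lab == L
      ok <- in_seg & sp$valid
      data.frame(segment = L,
                 pwv = if (any(ok)) mean(sp$pwv[ok]) else NA_real_,
                 e_kpa = if (any(ok)) mean(e[ok]) else NA_real_,
                 n_valid = sum(ok), n_invalid = sum(in_seg & !sp$valid),
                 stringsAsFactors = FALSE)
    }))
  }
  list(profile = profile, segments = segments)
}
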