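# Shared oracles and fixtures, independent of the code paths they check.

# circumradius of three points by brute-force circumcentre fit: solve for
# the centre equidistant from the three points within their plane
circumradius_fit <- function(p1, p2, p3) {
  # centre = p1 + x*u + y*v constrained by |c-p1| = |c-p2| = |c-p3|
  u <- p2 - p1; v <- p3 - p1
  M <- rbind(c(sum(u * u), sum(u * v)), c(sum(u * v), sum(v * v)))
  rhs <- c(sum(u * u) / 2, sum(v * v) / 2)
  if (abs(det(M)) < 1e-14) return(Inf)
  xy <- solve(M, rhs)
  centre <- p1 + xy[1] * u + xy[2] * v
  sqrt(sum((centre - p1)^2))
}

# numeric integration oracle for cross-sectional SAW integrals of an
# axisymmetric profile v(r): returns list(q_si, ke_flux_si)
profile_flux_oracle <- function(v_of_r, R_m, n = 4000) {
  r <- seq(0, R_m, length.out = n + 1)
  vr <- v_of_r(r)
  q <- sum(2 * pi * r * vr) * (R_m / n)
  kf <- sum(2 * pi * r * vr^3) * (R_m / n)
  list(q_si = q, ke_flux_si = kf)
}

# exhaustive-permutation two-sided Mann-Whitney p-value (no ties)
mann_whitney_perm <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  rk <- rank(x)
  w_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(length(x), n_a)
  w_all <- apply(combs, 2, function(ix) sum(rk[ix]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# straight-tube landmark set spanning [0, L] along +z
tube_landmarks <- function(L) {
  list(aortic_valve = c(0, 0, 0),
       brachiocephalic = c(0, 0, 0.25 * L),
       left_subclavian = c(0, 0, 0.45 * L),
       da_at_valve_level = c(0, 0, 0.75 * L),
       diaphragm = c(0, 0, L))
}

# cache expensive fixtures within one test file
local_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = cache)) assign(key, force(expr), envir = cache)
    get(key, envir = cache)
  }
})

# periodic Womersley phantom pressure traces, shared across files
womersley_traces <- function() {
  wp <- local_fixture("wom", womersley_phantom(R = 8, L = 80, Q_mean = 70,
                                               Q_osc = 30, period = 700,
                                               frames = 24, voxel = 1))
  cl <- local_fixture("wom_cl",
    extract_centreline(wp$mask, c(0, 0, 0), c(0, 0, 80)))
  cv <- local_fixture("wom_cv", {
    s_max <- max(cl$arc_length)
    segment_control_volume(wp$mask, cross_section_at(wp$mask, cl, 2),
                           cross_section_at(wp$mask, cl, s_max - 2), cl)
  })
  local_fixture("wom_tr",
    segment_pressure_traces(wp$field, cv, periodic = TRUE, period = 700))
}

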