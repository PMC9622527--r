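# WERP decomposition, SAW and viscous dissipation against analytic
# phantom truth.

pois <- local_fixture("cyl", poiseuille_phantom(R = 8, L = 80, Q = 70,
                                                voxel = 1))
pois_cl <- local_fixture("cyl_cl",
  extract_centreline(pois$mask, pois$truth$axis_start, pois$truth$axis_end))
pois_cv <- local_fixture("cyl_cv", {
  s_max <- max(pois_cl$arc_length)
  segment_control_volume(pois$mask,
                         cross_section_at(pois$mask, pois_cl, 2),
                         cross_section_at(pois$mask, pois_cl, s_max - 2),
                         pois_cl)
})

test_that("flow rate integrates v.n over the lumen plane", {
  # plug flow 1 m/s through a 2 cm^2 square duct -> 200 ml/s
  vox <- array(FALSE, c(20, 20, 9))
  vox[2:15, 2:15, ] <- TRUE                # 14.14 x 14.14 mm^2 ~ 2 cm^2
  side <- sqrt(200)
  vox <- array(FALSE, c(20, 20, 9))
  ix <- which(abs(seq_len(20) - 10.5) <= side / 2)
  vox[ix, ix, ] <- TRUE
  m <- lumen_mask(vox, c(1, 1, 1))
  vals <- array(0, c(20, 20, 9, 3, 2))
  vals[, , , 3, ] <- 1
  f <- velocity_field4d(vals, c(1, 1, 1), c(0, 30))
  cl <- structure(list(points = cbind(9.5, 9.5, seq(0, 8)),
                       arc_length = seq(0, 8),
                       tangent = matrix(rep(c(0, 0, 1), 9), ncol = 3,
                                        byrow = TRUE)),
                  class = "centreline")
  cs <- cross_section_at(m, cl, 4)
  q <- flow_rate(f, cs, 1)
  a_sq <- sum(vox[, , 5])                  # actual voxelised area, mm^2
  expect_equal(q, a_sq, tolerance = 0.02)
  # velocity parallel to the plane contributes nothing
  vals2 <- vals; vals2[, , , 3, ] <- 0; vals2[, , , 1, ] <- 1
  f2 <- velocity_field4d(vals2, c(1, 1, 1), c(0, 30))
  expect_lt(abs(flow_rate(f2, cs, 1)), 1e-9 * a_sq)
  # plane far outside the field extent is rejected
  cs_far <- cs; cs_far$center <- c(500, 500, 500)
  expect_error(flow_rate(f, cs_far, 1), "extent")
})

test_that("Poiseuille flow rate is recovered within 2%", {
  cs <- cross_section_at(pois$mask, pois_cl, 40)
  expect_equal(flow_rate(pois$field, cs, 1), 70, tolerance = 0.02)
})

test_that("kinetic energy matches (rho/2) <v^2> V", {
  # uniform |v| = 1 over the lumen: Ke = 530 * V
  vox <- array(FALSE, c(10, 10, 10)); vox[3:8, 3:8, 3:8] <- TRUE
  m <- lumen_mask(vox, c(1, 1, 1))
  vals <- array(0, c(10, 10, 10, 3, 2)); vals[, , , 3, ] <- 1
  f <- velocity_field4d(vals, c(1, 1, 1), c(0, 30))
  V <- sum(vox) * 1e-9
  expect_equal(kinetic_energy(f, m, 1), 530 * V, tolerance = 1e-12)
  # zero field -> 0
  f0 <- velocity_field4d(array(0, c(10, 10, 10, 3, 2)), c(1, 1, 1), c(0, 30))
  expect_equal(kinetic_energy(f0, m, 1), 0)
  # parabolic profile: <v^2> = (4/3) vbar^2
  vbar <- 70e-6 / (pi * 0.008^2)
  V_cyl <- pi * 0.008^2 * 0.080
  ke_true <- (1060 / 2) * (4 / 3) * vbar^2 * V_cyl
  expect_equal(kinetic_energy(pois$field, pois$mask, 1), ke_true,
               tolerance = 0.02)
})

test_that("kinetic energy rate differentiates the Ke series", {
  tt <- seq(0, 300, by = 30)
  expect_equal(kinetic_energy_rate(rep(2, 11), tt), rep(0, 11))
  ke_lin <- 5e-3 * tt / 1000                       # c = 5e-3 W ramp
  expect_equal(kinetic_energy_rate(ke_lin, tt), rep(5e-3, 11),
               tolerance = 1e-12)
  expect_error(kinetic_energy_rate(numeric(1), 0), "two frames")
  # periodic wrap: cycle sum of central differences telescopes to zero
  ke_per <- 1 + 0.3 * sin(2 * pi * (0:23) / 24)
  dk <- kinetic_energy_rate(ke_per, seq(0, by = 30, length.out = 24),
                            periodic = TRUE, period = 720)
  expect_lt(abs(sum(dk)), 1e-12 * max(abs(dk)))
})

test_that("advective energy follows the plug-flow closed form", {
  tp <- tapered_plug_phantom(R_in = 10, R_out = 10 / sqrt(2), L = 80,
                             Q = 70, voxel = 1)
  cl <- extract_centreline(tp$mask, c(0, 0, 0), c(0, 0, 80))
  s_max <- max(cl$arc_length)
  cs_in <- cross_section_at(tp$mask, cl, 3)
  cs_out <- cross_section_at(tp$mask, cl, s_max - 3)
  cv <- segment_control_volume(tp$mask, cs_in, cs_out, cl)
  ae <- advective_energy(tp$field, cv, 1)
  rz <- function(s) 10 + (10 / sqrt(2) - 10) * s / 80
  v_at <- function(s) 70e-6 / (pi * (rz(s) * 1e-3)^2)
  ae_true <- 0.5 * 1060 * 70e-6 *
    (v_at(cs_out$station)^2 - v_at(cs_in$station)^2)
  expect_equal(ae, ae_true, tolerance = 0.05)
  expect_gt(ae, 0)
  # straight cylinder, identical profiles -> ~0
  ae0 <- advective_energy(pois$field, pois_cv, 1)
  expect_lt(abs(ae0), 0.01 * abs(ae_true))
  # swapping the planes flips the sign
  cv_rev <- cv
  cv_rev$inlet <- cv$outlet; cv_rev$outlet <- cv$inlet
  expect_equal(advective_energy(tp$field, cv_rev, 1), -ae,
               tolerance = 1e-12)
})

test_that("viscous dissipation matches the Hagen-Poiseuille rate", {
  # uniform field: zero gradients away from the wall dominate
  vox <- array(FALSE, c(10, 10, 10)); vox[3:8, 3:8, 3:8] <- TRUE
  m <- lumen_mask(vox, c(1, 1, 1))
  f0 <- velocity_field4d(array(0, c(10, 10, 10, 3, 2)), c(1, 1, 1), c(0, 30))
  expect_equal(viscous_energy_rate(f0, m, 1), 0)
  # Poiseuille: Ve = Q dP within 10% at 1-mm voxels, and non-negative
  ve <- viscous_energy_rate(pois$field, pois$mask, 1)
  expect_lt(abs(ve - pois$truth$viscous_rate) / pois$truth$viscous_rate,
            0.10)
  expect_gte(ve, 0)
  # random field stays non-negative (quadratic form)
  set.seed(11)
  vr <- array(rnorm(10 * 10 * 10 * 3 * 2), c(10, 10, 10, 3, 2))
  fr <- velocity_field4d(vr, c(1, 1, 1), c(0, 30))
  expect_gte(viscous_energy_rate(fr, m, 1), 0)
})

test_that("WERP recovers the Poiseuille pressure drop", {
  tr <- segment_pressure_traces(pois$field, pois_cv)
  L_cv <- pois_cv$outlet$station - pois_cv$inlet$station
  dp_true <- pa_to_mmhg(pois$truth$pressure_drop * L_cv / 80)
  expect_lt(abs(tr$dp_tot_mmhg[1] - dp_true) / dp_true, 0.10)
  expect_equal(tr$dp_kin_mmhg[1], 0)
  expect_lt(abs(tr$dp_adv_mmhg[1]), 0.02 * dp_true)
  w <- werp_pressure(pois$field, pois_cv, 1)
  expect_equal(w$dp_tot, tr$dp_tot_mmhg[1])
})

test_that("decomposition closure holds at every valid frame", {
  tr <- womersley_traces()
  ok <- tr$valid
  expect_true(any(ok))
  lhs <- tr$dp_tot_mmhg[ok]
  rhs <- tr$dp_kin_mmhg[ok] + tr$dp_adv_mmhg[ok] + tr$dp_visc_mmhg[ok]
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  # viscous pressure term carries the sign of Q
  expect_true(all(sign(tr$dp_visc_mmhg[ok]) == sign(tr$q_ml_s[ok])))
})

test_that("cycle mean of the kinetic pressure vanishes on the periodic phantom", {
  tr <- womersley_traces()
  m <- mean(tr$dp_kin_mmhg[tr$valid])
  expect_lt(abs(m) / max(abs(tr$dp_kin_mmhg[tr$valid])), 0.02)
})

test_that("near-zero flow frames are flagged invalid, not errors", {
  wp <- womersley_phantom(R = 8, L = 40, Q_mean = 10, Q_osc = 30,
                          period = 700, frames = 16, voxel = 1)
  cl <- extract_centreline(wp$mask, c(0, 0, 0), c(0, 0, 40))
  s_max <- max(cl$arc_length)
  cv <- segment_control_volume(wp$mask, cross_section_at(wp$mask, cl, 2),
                               cross_section_at(wp$mask, cl, s_max - 2), cl)
  tr <- segment_pressure_traces(wp$field, cv, periodic = TRUE, period = 700)
  expect_true(any(!tr$valid))              # backflow/near-zero frames exist
  expect_true(all(is.nan(tr$dp_tot_mmhg[!tr$valid])))
  expect_true(all(is.finite(tr$ve_rate_mj_s)))   # Ve itself is always defined
})

test_that("SAW reduces to Bernoulli for plug flow and rho*vbar^2 for parabolic", {
  # plug 1 m/s: rho v^2 / 2 = 530 Pa = 3.97 mmHg
  vox <- array(FALSE, c(24, 24, 9))
  r2 <- outer((1:24 - 12.5)^2, (1:24 - 12.5)^2, `+`)
  vox[, , ] <- array(r2 <= 81, c(24, 24, 9))
  m <- lumen_mask(vox, c(1, 1, 1))
  vals <- array(0, c(24, 24, 9, 3, 2)); vals[, , , 3, ] <- 1
  f <- velocity_field4d(vals, c(1, 1, 1), c(0, 30))
  cl <- structure(list(points = cbind(11.5, 11.5, 0:8),
                       arc_length = seq(0, 8),
                       tangent = matrix(rep(c(0, 0, 1), 9), ncol = 3,
                                        byrow = TRUE)),
                  class = "centreline")
  cs <- cross_section_at(m, cl, 4)
  saw <- saw_pressure(f, cs, 1)
  expect_equal(saw, pa_to_mmhg(530), tolerance = 0.01)
  # parabolic, vbar = 1 m/s: rho vbar^2, checked against integral oracle
  vbar <- 70e-6 / (pi * 0.008^2)
  csp <- cross_section_at(pois$mask, pois_cl, 40)
  sawp <- saw_pressure(pois$field, csp, 1)
  expect_equal(sawp, pa_to_mmhg(1060 * vbar^2), tolerance = 0.03)
  orc <- profile_flux_oracle(function(r)
    2 * vbar * (1 - r^2 / 0.008^2), 0.008)
  expect_equal(sawp,
               pa_to_mmhg(1060 / (2 * orc$q_si) * orc$ke_flux_si),
               tolerance = 0.03)
  # near-zero flow -> NaN flag
  f0 <- velocity_field4d(array(1e-9, c(24, 24, 9, 3, 2)), c(1, 1, 1),
                         c(0, 30))
  expect_true(is.nan(saw_pressure(f0, cs, 1, q_min = 1)))
})

test_that("SAW profile is flat on a cylinder and rises along a taper", {
  prof <- saw_profile(pois$field, pois$mask, pois_cl)
  v <- prof$profile$saw_mmhg[prof$profile$valid]
  expect_lt(diff(range(v)) / mean(v), 0.05)
  expect_equal(nrow(prof$profile), length(pois_cl$arc_length))
  tp <- local_fixture("tap", tapered_plug_phantom(R_in = 10, R_out = 6,
                                                  L = 80, Q = 70, voxel = 1))
  cl <- extract_centreline(tp$mask, c(0, 0, 0), c(0, 0, 80))
  pr <- saw_profile(tp$field, tp$mask, cl, seg = assign_segments(
    cl, tube_landmarks(max(cl$arc_length))))
  vv <- pr$profile$saw_mmhg
  inner <- 5:(length(vv) - 5)
  expect_true(all(diff(vv[inner]) > -0.02 * max(vv, na.rm = TRUE)))
  expect_gt(sum(pr$segment_delta), 0)
})

test_that("timing metrics find peaks and zero crossings", {
  T0 <- 600
  tt <- seq(0, T0 / 2, by = 25)
  tr <- data.frame(time_ms = tt,
                   dp_tot_mmhg = sin(2 * pi * tt / T0),
                   dp_kin_mmhg = sin(2 * pi * tt / T0))
  tm <- timing_metrics(tr)
  expect_equal(tm$t_peak_dp_kin, T0 / 4, tolerance = 0.02)
  expect_equal(tm$t_zero_crossing_dp_kin, T0 / 2, tolerance = 0.02)
  expect_gte(tm$t_zero_crossing_dp_kin, tm$t_peak_dp_kin)
  # monotone decreasing positive series: peak at first frame, no crossing
  tr2 <- data.frame(time_ms = tt, dp_tot_mmhg = rev(seq_along(tt)),
                    dp_kin_mmhg = rev(seq_along(tt)))
  tm2 <- timing_metrics(tr2)
  expect_equal(tm2$t_peak_dp_kin, 0)
  expect_true(is.na(tm2$t_zero_crossing_dp_kin))
})

test_that("halving the voxel size moves the Poiseuille estimate toward truth", {
  ve1 <- viscous_energy_rate(pois$field, pois$mask, 1)
  p5 <- poiseuille_phantom(R = 8, L = 40, Q = 70, voxel = 0.5)
  p1 <- poiseuille_phantom(R = 8, L = 40, Q = 70, voxel = 1)
  e1 <- abs(viscous_energy_rate(p1$field, p1$mask, 1) / p1$truth$viscous_rate - 1)
  e5 <- abs(viscous_energy_rate(p5$field, p5$mask, 1) / p5$truth$viscous_rate - 1)
  expect_lt(e5, e1)
})
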