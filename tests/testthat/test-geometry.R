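# Centreline, curvature, cross-sections and segment subdivision against
# phantom ground truth and closed-form geometry.

cyl <- local_fixture("cyl", poiseuille_phantom(R = 8, L = 80, Q = 70,
                                               voxel = 1))
cyl_cl <- local_fixture("cyl_cl",
  extract_centreline(cyl$mask, cyl$truth$axis_start, cyl$truth$axis_end))
tor <- local_fixture("tor", torus_phantom(R_t = 50, r_tube = 8, arc = 180,
                                          voxel = 1))
tor_cl <- local_fixture("tor_cl",
  extract_centreline(tor$mask, tor$truth$start_point, tor$truth$end_point))

test_that("peak-systolic frame maximises in-mask kinetic energy", {
  vals <- array(0, dim = c(5, 5, 5, 3, 4))
  mask <- lumen_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  ps <- peak_systolic_speed(velocity_field4d(vals, c(1, 1, 1),
                                             c(0, 30, 60, 90)), mask)
  expect_equal(ps$peak_frame, 1L)          # all-zero: first frame on ties
  expect_true(all(ps$speed == 0))
  vals[, , , 1, 3] <- 1                    # single hot frame
  ps <- peak_systolic_speed(velocity_field4d(vals, c(1, 1, 1),
                                             c(0, 30, 60, 90)), mask)
  expect_equal(ps$peak_frame, 3L)
  expect_equal(unique(as.numeric(ps$speed)), 1)
  expect_error(peak_systolic_speed(
    velocity_field4d(vals, c(1, 1, 1), c(0, 30, 60, 90)),
    lumen_mask(array(FALSE, c(5, 5, 5)), c(1, 1, 1))), "empty")
})

test_that("peak frame on the Womersley phantom matches the analytic flow peak", {
  wp <- local_fixture("wom", womersley_phantom(R = 8, L = 80, Q_mean = 70,
                                               Q_osc = 30, period = 700,
                                               frames = 24, voxel = 1))
  ps <- peak_systolic_speed(wp$field, wp$mask)
  expect_equal(ps$peak_frame, which.max(wp$truth$q_waveform))
})

test_that("cylinder centreline recovers the tube axis", {
  expect_lt(max(sqrt(rowSums(cyl_cl$points[, 1:2]^2))), 0.5)  # 0.5 voxel
  expect_lt(abs(max(cyl_cl$arc_length) - 80) / 80, 0.02)
  expect_equal(diff(cyl_cl$arc_length),
               rep(1, nrow(cyl_cl$points) - 1), tolerance = 1e-6)
})

test_that("torus centreline stays on the ring and preserves arc length", {
  ring_r <- sqrt(tor_cl$points[, 1]^2 + tor_cl$points[, 2]^2)
  expect_lt(max(abs(ring_r - 50)), 0.5)
  expect_lt(max(abs(tor_cl$points[, 3])), 0.5)
  expect_lt(abs(max(tor_cl$arc_length) - tor$truth$arc_length) /
              tor$truth$arc_length, 0.02)
})

test_that("disconnected seeds raise an error", {
  vox <- array(FALSE, c(12, 5, 5))
  vox[1:4, 2:4, 2:4] <- TRUE
  vox[9:12, 2:4, 2:4] <- TRUE
  m <- lumen_mask(vox, c(1, 1, 1))
  expect_error(extract_centreline(m, c(1, 2, 2), c(10, 2, 2)),
               "disconnected")
  expect_error(extract_centreline(m, c(6, 2, 2), c(10, 2, 2)), "seed")
})

test_that("centreline resampling preserves arc length", {
  # smooth helix-like polyline: resampled chord length vs dense length
  t <- seq(0, 2, length.out = 41)
  pts <- cbind(30 * cos(t), 30 * sin(t), 8 * t)
  out <- aortaflow:::smooth_resample_polyline(pts, sigma = 0, by = 1)
  len_in <- sum(sqrt(rowSums(diff(pts)^2)))
  len_out <- max(c(0, cumsum(sqrt(rowSums(diff(out)^2)))))
  expect_lt(abs(len_out - len_in) / len_in, 0.005)
})

test_that("three-point curvature matches closed forms and the circumcentre fit", {
  # exact circle, radius 50 mm -> 20 1/m everywhere
  th <- seq(0, pi, length.out = 120)
  circ <- structure(list(points = cbind(50 * cos(th), 50 * sin(th), 0)),
                    class = "centreline")
  k <- curvature_profile(circ)
  expect_equal(k, rep(20, length(th)), tolerance = 1e-9)
  # collinear points -> zero
  line <- structure(list(points = cbind(seq(0, 10), 0, 0)),
                    class = "centreline")
  expect_equal(curvature_profile(line), rep(0, 11))
  # right triangle (0,0,0),(1,0,0),(0,1,0): R = sqrt(2)/2 mm
  tri <- structure(list(points = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
                   class = "centreline")
  k3 <- curvature_profile(tri)
  expect_equal(k3[2], 1000 / (sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(k3[2], 1414.2, tolerance = 1e-4)
  expect_equal(1000 / circumradius_fit(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               k3[2], tolerance = 1e-9)
  # random triples agree with the brute-force circumcentre fit
  set.seed(7)
  for (i in 1:20) {
    p <- matrix(rnorm(9, sd = 10), 3, 3)
    kf <- 1000 / circumradius_fit(p[1, ], p[2, ], p[3, ])
    kp <- curvature_profile(structure(list(points = p),
                                      class = "centreline"))[2]
    expect_equal(kp, kf, tolerance = 1e-9)
  }
  # duplicate consecutive points rejected
  dup <- structure(list(points = rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
                   class = "centreline")
  expect_error(curvature_profile(dup), "duplicate")
})

test_that("discretised torus curvature is within 5% of 1/R_t", {
  k <- curvature_profile(tor_cl)
  interior <- 10:(length(k) - 10)
  expect_lt(abs(mean(k[interior]) - tor$truth$curvature) /
              tor$truth$curvature, 0.05)
})

test_that("cross sections recover diameter and the area-diameter bijection", {
  cs <- cross_section_at(cyl$mask, cyl_cl, 40)
  expect_lt(abs(cs$diameter - 16) / 16, 0.02)
  expect_lt(abs(cs$lumen_area - pi * 64) / (pi * 64), 0.04)
  expect_equal(cs$diameter, 2 * sqrt(cs$lumen_area / pi))
  cst <- cross_section_at(tor$mask, tor_cl, tor$truth$arc_length / 2)
  expect_lt(abs(cst$diameter - 16) / 16, 0.02)
  expect_error(cross_section_at(cyl$mask, cyl_cl, 1e4), "outside")
})

test_that("tapered phantom diameters decrease monotonically", {
  tp <- local_fixture("tap", tapered_plug_phantom(R_in = 10, R_out = 6,
                                                  L = 80, Q = 70, voxel = 1))
  cl <- extract_centreline(tp$mask, c(0, 0, 0), c(0, 0, 80))
  ss <- seq(5, max(cl$arc_length) - 5, by = 10)
  d <- vapply(ss, function(s) cross_section_at(tp$mask, cl, s)$diameter,
              numeric(1))
  expect_true(all(diff(d) < 0.2))          # monotone within half a voxel
  expect_lt(abs(d[1] - 2 * (10 - 5 / 80 * 4)) / d[1], 0.06)
})

test_that("wall thickness follows the half-difference convention", {
  expect_equal(wall_thickness(16.0, 20.2), 2.1)
  expect_error(wall_thickness(16, 16), "exceed")
  expect_error(wall_thickness(-1, 2), "positive")
  # observers as columns are averaged
  endo <- cbind(c(16, 16), c(16.2, 15.8), c(15.8, 16.2))
  epi <- endo + 2 * cbind(c(2.0, 2.0), c(2.1, 2.1), c(2.2, 2.2))
  expect_equal(wall_thickness(endo, epi), c(2.1, 2.1))
})

test_that("segments partition the landmark span in order", {
  seg <- assign_segments(cyl_cl, tube_landmarks(79))
  b <- seg$boundaries
  expect_equal(b$label, c("AA", "TA", "DA1", "DA2"))
  expect_equal(b$s_start[-1], b$s_end[-4])            # contiguous
  expect_equal(b$s_start[1], 0)
  expect_equal(b$s_end[4], max(cyl_cl$arc_length))
  # permuted landmarks -> ordering error naming the landmark
  lm_bad <- tube_landmarks(79)
  tmp <- lm_bad$brachiocephalic
  lm_bad$brachiocephalic <- lm_bad$left_subclavian
  lm_bad$left_subclavian <- tmp
  expect_error(assign_segments(cyl_cl, lm_bad), "left_subclavian")
  expect_error(assign_segments(cyl_cl, tube_landmarks(79)[-2]),
               "brachiocephalic")
})

test_that("torus landmark intervals match analytic arc lengths", {
  arc <- tor$truth$arc_length
  ang <- function(f) c(50 * cos(f * pi), 50 * sin(f * pi), 0)
  lm <- list(aortic_valve = ang(0.001), brachiocephalic = ang(0.25),
             left_subclavian = ang(0.45), da_at_valve_level = ang(0.75),
             diaphragm = ang(0.999))
  seg <- assign_segments(tor_cl, lm)
  b <- seg$boundaries
  lens <- b$s_end - b$s_start
  true_lens <- c(0.249, 0.20, 0.30, 0.249) * pi * 50
  expect_equal(lens, true_lens, tolerance = 0.02 * max(true_lens))
})

test_that("segment summaries average stations and index by BSA", {
  seg <- assign_segments(cyl_cl, tube_landmarks(79))
  stations <- cyl_cl$arc_length
  const <- rep(12, length(stations))
  meta <- subject_meta("s", bsa = 0.5, heart_period = 700)
  sm <- segment_summary(const, stations, seg, meta)
  expect_equal(sm$mean, rep(12, 4))
  expect_equal(sm$mean_indexed, rep(24, 4))
  # linear profile: segment mean = value at interval midpoint
  lin <- 2 * stations
  sm2 <- segment_summary(lin, stations, seg, 1)
  b <- seg$boundaries
  mids <- (b$s_start + b$s_end) / 2
  expect_lt(max(abs(sm2$mean - 2 * mids)), 1.1)      # within half-spacing
  # cylinder diameter, BSA = 1 -> ~16 everywhere
  d <- vapply(stations, function(s)
    cross_section_at(cyl$mask, cyl_cl, s)$diameter, numeric(1))
  sm3 <- segment_summary(d, stations, seg, 1)
  expect_equal(sm3$mean_indexed, rep(16, 4), tolerance = 0.02)
})
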