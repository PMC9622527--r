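# Centreline extraction and the anatomical metric panel: curvature,
# diameter, wall thickness and the four-segment subdivision of the aorta.

#' Virtual angiography: peak-systolic speed volume
#'
#' Selects the peak-systolic frame as the frame with the largest total
#' in-mask kinetic energy and returns the speed magnitude image at that
#' frame, masked to the lumen. Ties resolve to the earliest frame.
#'
#' @param field a [velocity_field4d()]
#' @param mask a [lumen_mask()] on the same grid
#' @return list with `speed` (3-D array, m/s, zero outside the lumen) and
#'   `peak_frame` (frame index)
#' @export
peak_systolic_speed <- function(field, mask) {
  stopifnot(inherits(field, "velocity_field4d"), inherits(mask, "lumen_mask"))
  if (!any(mask$voxels)) stop("empty lumen mask")
  d <- dim(field$values)
  if (!all(d[1:3] == dim(mask$voxels)))
    stop("velocity field and mask grids differ")
  ke <- vapply(seq_len(d[5]), function(t) {
    v2 <- field$values[, , , 1, t]^2 + field$values[, , , 2, t]^2 +
      field$values[, , , 3, t]^2
    sum(v2[mask$voxels])
  }, numeric(1))
  pk <- which.max(ke)
  sp <- sqrt(field$values[, , , 1, pk]^2 + field$values[, , , 2, pk]^2 +
               field$values[, , , 3, pk]^2)
  sp[!mask$voxels] <- 0
  list(speed = sp, peak_frame = pk)
}

# ---- centreline -------------------------------------------------------------

# distance-to-wall in voxel layers by iterative 6-connected erosion
erosion_distance <- function(mask) {
  d <- array(0, dim(mask))
  cur <- mask
  while (any(cur)) {
    d[cur] <- d[cur] + 1
    cur <- cur &
      shift3(cur, 1L, 1L) & shift3(cur, 1L, -1L) &
      shift3(cur, 2L, 1L) & shift3(cur, 2L, -1L) &
      shift3(cur, 3L, 1L) & shift3(cur, 3L, -1L)
  }
  d
}

# 26-neighbourhood offsets (13 unique directions)
neighbour_offsets26 <- function() {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  # keep one of each +/- pair
  keep <- off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
    (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0)
  off[keep, , drop = FALSE]
}

# shortest ridge path between two in-mask voxels, favouring the interior
# distance-transform ridge; returns k x 3 voxel indices
ridge_path <- function(mask, dt, seed_a, seed_b) {
  d <- dim(mask)
  lin <- array(0L, d)
  lin[mask] <- seq_len(sum(mask))
  vox <- which(mask, arr.ind = TRUE)
  dt_max <- max(dt)
  node_cost <- 1 / (1 + dt[mask])^2  # strongly prefer the lumen centre
  offs <- neighbour_offsets26()
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- sweep(vox, 2, o, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_id <- integer(nrow(vox))
    nb_id[ok] <- lin[nb[ok, , drop = FALSE]]
    ok <- ok & nb_id > 0L
    len <- sqrt(sum(o^2))
    efrom <- c(efrom, lin[mask][ok])
    eto <- c(eto, nb_id[ok])
    ew <- c(ew, len * (node_cost[lin[mask][ok]] + node_cost[nb_id[ok]]) / 2)
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  igraph::E(g)$weight <- ew
  ia <- lin[seed_a[1], seed_a[2], seed_a[3]]
  ib <- lin[seed_b[1], seed_b[2], seed_b[3]]
  if (ia == 0L || ib == 0L) stop("seed point is not inside the mask")
  sp <- suppressWarnings(igraph::shortest_paths(g, from = ia, to = ib,
                                                output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2L)
    stop("mask is disconnected between the two seed points")
  vox[vp, , drop = FALSE]
}

# Gaussian kernel smoothing of an ordered polyline along arc length,
# evaluated on a dense parameter grid, followed by uniform arc-length
# resampling. The polyline is reflection-padded at both ends so the
# kernel stays symmetric there (otherwise the end points drift inward
# along the curve); the dense evaluation keeps the resampled stations on
# the smooth curve itself, which the three-point curvature needs (chord
# kinks at coarser spacing would dominate it).
smooth_resample_polyline <- function(pts, sigma, by = 1) {
  n <- nrow(pts)
  if (sigma > 0 && n > 2L) {
    npad <- min(n - 1L, max(2L, ceiling(3 * sigma)))
    head_ref <- sweep(-pts[(npad + 1):2, , drop = FALSE], 2,
                      2 * pts[1, ], `+`)
    tail_ref <- sweep(-pts[(n - 1):(n - npad), , drop = FALSE], 2,
                      2 * pts[n, ], `+`)
    ext <- rbind(head_ref, pts, tail_ref)
    s <- c(0, cumsum(sqrt(rowSums(diff(ext)^2))))
    s_lo <- s[npad + 1]; s_hi <- s[npad + n]
    s_dense <- seq(s_lo, s_hi, by = by / 8)
    dense <- matrix(0, length(s_dense), 3)
    for (i in seq_along(s_dense)) {
      w <- exp(-(s - s_dense[i])^2 / (2 * sigma^2))
      w <- w / sum(w)
      dense[i, ] <- colSums(ext * w)
    }
  } else {
    dense <- pts
  }
  sd_ <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  s_out <- seq(0, sd_[length(sd_)], by = by)
  cbind(stats::approx(sd_, dense[, 1], xout = s_out)$y,
        stats::approx(sd_, dense[, 2], xout = s_out)$y,
        stats::approx(sd_, dense[, 3], xout = s_out)$y)
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  tg / sqrt(rowSums(tg^2))
}

new_centreline <- function(points) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  structure(list(points = points, arc_length = arc,
                 tangent = polyline_tangents(points)),
            class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("<centreline> %d stations, length %.1f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

# linear interpolation of centreline point and tangent at arc length s
centreline_at <- function(cl, s) {
  if (s < min(cl$arc_length) - 1e-9 || s > max(cl$arc_length) + 1e-9)
    stop(sprintf("arc length %.2f mm outside centreline range [0, %.2f]",
                 s, max(cl$arc_length)))
  p <- vapply(1:3, function(j)
    stats::approx(cl$arc_length, cl$points[, j], xout = s, rule = 2)$y,
    numeric(1))
  tg <- vapply(1:3, function(j)
    stats::approx(cl$arc_length, cl$tangent[, j], xout = s, rule = 2)$y,
    numeric(1))
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

#' Extract a vessel centreline from a lumen mask
#'
#' Tracks the interior distance-transform ridge between two seed points
#' (shortest path weighted towards the lumen centre), recentres each point
#' on the centroid of its perpendicular lumen cross-section, smooths the
#' polyline with a Gaussian kernel along arc length, and resamples it at
#' regular 1-mm stations.
#'
#' @param mask a [lumen_mask()]
#' @param seed_root,seed_end world coordinates (mm) of the two ends, e.g.
#'   aortic valve plane and diaphragm level; both must lie inside the mask
#' @param sigma Gaussian smoothing bandwidth along arc length (mm). The
#'   default of 4 mm is a few voxels at typical resolutions: enough to
#'   suppress voxelisation stair-casing, which otherwise dominates the
#'   three-point curvature, while remaining well below aortic bend radii.
#' @param station_spacing output station spacing in mm (default 1)
#' @param recentre_iter number of cross-section centroid recentring passes
#' @return a `centreline` object: `points` (N x 3 mm), `arc_length`
#'   (cumulative mm, starts at 0), `tangent` (unit vectors)
#' @export
extract_centreline <- function(mask, seed_root, seed_end, sigma = 4,
                               station_spacing = 1, recentre_iter = 2) {
  stopifnot(inherits(mask, "lumen_mask"))
  va <- round(world_to_voxel(seed_root, mask$spacing, mask$origin))
  vb <- round(world_to_voxel(seed_end, mask$spacing, mask$origin))
  d <- dim(mask$voxels)
  for (v in list(va, vb))
    if (any(v < 1) || any(v > d) || !mask$voxels[v[1], v[2], v[3]])
      stop("seed point is not inside the mask")
  comp <- connected_component3(mask$voxels, as.integer(va))
  if (!comp[vb[1], vb[2], vb[3]])
    stop("mask is disconnected between the two seed points")
  dt <- erosion_distance(mask$voxels)
  path_vox <- ridge_path(mask$voxels, dt, as.integer(va), as.integer(vb))
  pts <- voxel_to_world(path_vox, mask$spacing, mask$origin)
  # thin to ~2 mm steps before recentring to keep cost bounded
  step <- max(1L, floor(2 / mean(mask$spacing)))
  keep <- unique(c(seq(1, nrow(pts), by = step), nrow(pts)))
  pts <- pts[keep, , drop = FALSE]
  pitch <- min(mask$spacing) / 2
  for (iter in seq_len(recentre_iter)) {
    tg <- polyline_tangents(pts)
    for (i in seq_len(nrow(pts))) {
      pl <- try(plane_lumen(mask, pts[i, ], tg[i, ], pitch), silent = TRUE)
      if (!inherits(pl, "try-error")) pts[i, ] <- pl$centroid
    }
  }
  pts <- smooth_resample_polyline(pts, sigma, by = station_spacing)
  inside <- trilinear(array(as.numeric(mask$voxels), d),
                      world_to_voxel(pts, mask$spacing, mask$origin))
  if (any(inside < 0.25))
    warning(sprintf("%d centreline stations fall at the lumen boundary",
                    sum(inside < 0.25)))
  new_centreline(pts)
}

# ---- cross sections ---------------------------------------------------------

# orthonormal in-plane basis perpendicular to a unit normal
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  e <- diag(3)[, which.min(abs(n))]
  u <- c(e[2] * n[3] - e[3] * n[2], e[3] * n[1] - e[1] * n[3],
         e[1] * n[2] - e[2] * n[1])
  u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, w = w)
}

shift2 <- function(m, axis, step) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  if (axis == 1L) {
    if (step == 1L) out[1:(d[1] - 1), ] <- m[2:d[1], ]
    else out[2:d[1], ] <- m[1:(d[1] - 1), ]
  } else {
    if (step == 1L) out[, 1:(d[2] - 1)] <- m[, 2:d[2]]
    else out[, 2:d[2]] <- m[, 1:(d[2] - 1)]
  }
  out
}

flood_fill2 <- function(m, seed_i, seed_j) {
  comp <- matrix(FALSE, nrow(m), ncol(m))
  if (!m[seed_i, seed_j]) return(comp)
  comp[seed_i, seed_j] <- TRUE
  repeat {
    grown <- (comp | shift2(comp, 1L, 1L) | shift2(comp, 1L, -1L) |
                shift2(comp, 2L, 1L) | shift2(comp, 2L, -1L)) & m
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# In-plane lumen sampling: regular grid of pitch `pitch` on the plane
# through `center` with unit normal `normal`; the lumen is the 4-connected
# in-plane component containing `center` (branch lumens cut by the same
# plane are excluded). The grid is grown until the component no longer
# touches its border.
plane_lumen <- function(mask, center, normal, pitch = min(mask$spacing) / 2,
                        extent = NULL) {
  b <- plane_basis(normal)
  vol <- array(as.numeric(mask$voxels), dim(mask$voxels))
  if (is.null(extent)) {
    dtm <- attr(mask, "max_radius_hint")
    extent <- if (!is.null(dtm)) dtm else 6 * max(mask$spacing)
  }
  max_extent <- sqrt(sum((dim(mask$voxels) * mask$spacing)^2))
  repeat {
    ax <- seq(-extent, extent, by = pitch)
    g <- expand.grid(a = ax, b = ax)
    pts <- outer(g$a, b$u) + outer(g$b, b$w)
    pts <- sweep(pts, 2, center, `+`)
    inm_val <- trilinear(vol, world_to_voxel(pts, mask$spacing, mask$origin))
    m <- matrix(inm_val >= 0.5, nrow = length(ax))
    ci <- which.min(abs(ax))
    comp <- flood_fill2(m, ci, ci)
    if (!any(comp)) {
      # centre pixel may sit just off-lumen; try nearest in-plane lumen pixel
      if (any(m)) {
        ij <- which(m, arr.ind = TRUE)
        dd <- (ax[ij[, 1]])^2 + (ax[ij[, 2]])^2
        near <- ij[which.min(dd), ]
        if (min(dd) <= (2 * max(mask$spacing))^2)
          comp <- flood_fill2(m, near[1], near[2])
      }
      if (!any(comp)) stop("cross-section plane does not intersect the lumen")
    }
    touches <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)])
    if (!touches || extent >= max_extent) break
    extent <- extent * 1.6
  }
  idx <- which(comp, arr.ind = TRUE)
  samples <- sweep(outer(ax[idx[, 1]], b$u) + outer(ax[idx[, 2]], b$w),
                   2, center, `+`)
  # Fractional area: sum of the interpolated indicator over the component
  # and its sub-voxel fringe. The binary 0.5-level count is biased by up
  # to half a pixel ring; the fractional sum places the boundary at the
  # mid-crossing of the indicator ramp.
  iv <- matrix(pmin(pmax(inm_val, 0), 1), nrow = length(ax))
  fringe <- comp
  n_dil <- ceiling(max(mask$spacing) / pitch) + 1L
  for (i in seq_len(n_dil))
    fringe <- fringe | shift2(fringe, 1L, 1L) | shift2(fringe, 1L, -1L) |
      shift2(fringe, 2L, 1L) | shift2(fringe, 2L, -1L)
  area <- sum(iv[fringe]) * pitch^2
  list(samples = samples, pixel_area = pitch^2,
       area = area, centroid = colMeans(samples),
       normal = b$n)
}

#' Lumen cross-section perpendicular to the centreline
#'
#' Intersects the plane through the centreline point at arc length `s`,
#' normal to the local tangent, with the lumen mask. The lumen area is that
#' of the connected in-plane component containing the centreline point,
#' sampled on an in-plane grid of pitch at most half the smallest voxel
#' edge; branch lumens cut by the same plane are excluded. The effective
#' diameter is `2 * sqrt(area / pi)`.
#'
#' @param mask a [lumen_mask()]
#' @param cl a `centreline`
#' @param s arc length station (mm) within the centreline range
#' @return an object of class `cross_section`: `center`, `normal`,
#'   `lumen_area` (mm^2), `diameter` (mm), `station` (mm) and the in-plane
#'   sample points used for flux integrals
#' @export
cross_section_at <- function(mask, cl, s) {
  loc <- centreline_at(cl, s)
  pl <- plane_lumen(mask, loc$point, loc$tangent)
  structure(list(center = loc$point, normal = pl$normal,
                 lumen_area = pl$area, diameter = 2 * sqrt(pl$area / pi),
                 station = s, samples = pl$samples,
                 pixel_area = pl$pixel_area),
            class = "cross_section")
}

#' Three-point curvature along a centreline
#'
#' Curvature at each interior station is the inverse of the radius of the
#' circumscribed circle through three consecutive centreline points
#' (`kappa = 4 * Area / (a b c)` for triangle side lengths a, b, c).
#' Collinear triples give zero curvature; the endpoints copy the nearest
#' interior value.
#'
#' @param cl a `centreline` (at least 3 stations)
#' @return numeric vector of curvature in 1/m, one value per station
#' @export
curvature_profile <- function(cl) {
  pts <- cl$points
  n <- nrow(pts)
  if (n < 3L) stop("curvature needs at least three centreline points")
  if (any(rowSums(diff(pts)^2) == 0))
    stop("duplicate consecutive centreline points")
  p1 <- pts[1:(n - 2), , drop = FALSE]
  p2 <- pts[2:(n - 1), , drop = FALSE]
  p3 <- pts[3:n, , drop = FALSE]
  a <- sqrt(rowSums((p2 - p1)^2))
  b <- sqrt(rowSums((p3 - p2)^2))
  cc <- sqrt(rowSums((p3 - p1)^2))
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  kappa_mm <- 4 * area / (a * b * cc)   # 1/mm
  kappa <- c(kappa_mm[1], kappa_mm, kappa_mm[length(kappa_mm)]) * 1000
  kappa
}

#' Wall thickness from endo- and epi-vascular diameters
#'
#' Per-side wall thickness `(epi - endo) / 2` at systole. Inputs may be
#' vectors (stations) or matrices (stations x observers); observer columns
#' are averaged, mirroring measurement by several independent observers.
#'
#' @param endo_diam endovascular (lumen) diameter, mm
#' @param epi_diam epivascular (outer) diameter, mm; must exceed `endo_diam`
#' @return wall thickness in mm, one value per station
#' @export
wall_thickness <- function(endo_diam, epi_diam) {
  endo <- as.matrix(endo_diam); epi <- as.matrix(epi_diam)
  if (!all(dim(endo) == dim(epi)))
    stop("endo and epi diameter inputs must have matching shape")
  if (any(endo <= 0)) stop("diameters must be positive")
  if (any(epi <= endo))
    stop("epivascular diameter must exceed endovascular diameter")
  th <- (epi - endo) / 2
  rowMeans(th)
}

#' Subdivide the aorta into four anatomical segments
#'
#' Projects the five anatomical landmarks onto the centreline (nearest
#' station; ties resolve to the smallest arc length) and builds the four
#' half-open arc-length intervals: ascending aorta AA = \[valve,
#' brachiocephalic), transverse arch TA = \[brachiocephalic, left
#' subclavian), DA1 = \[left subclavian, DA-at-valve-level) and DA2 =
#' \[DA-at-valve-level, diaphragm\].
#'
#' @param cl a `centreline`
#' @param landmarks named list of world points (mm): `aortic_valve`,
#'   `brachiocephalic`, `left_subclavian`, `da_at_valve_level`, `diaphragm`
#' @return an object of class `segment_definition` with a `boundaries`
#'   data frame (label, s_start, s_end) and the projected landmark stations
#' @export
assign_segments <- function(cl, landmarks) {
  required <- c("aortic_valve", "brachiocephalic", "left_subclavian",
                "da_at_valve_level", "diaphragm")
  miss <- setdiff(required, names(landmarks))
  if (length(miss))
    stop("missing landmark(s): ", paste(miss, collapse = ", "))
  proj <- vapply(required, function(nm) {
    p <- as.numeric(landmarks[[nm]])
    d2 <- rowSums(sweep(cl$points, 2, p, `-`)^2)
    cl$arc_length[which.min(d2)]   # which.min takes the first: smallest s
  }, numeric(1))
  if (any(diff(proj) <= 0)) {
    bad <- required[which(diff(proj) <= 0)[1] + 1L]
    stop(sprintf("landmark '%s' projects out of order along the centreline",
                 bad))
  }
  boundaries <- data.frame(
    label = c("AA", "TA", "DA1", "DA2"),
    s_start = proj[1:4], s_end = proj[2:5],
    stringsAsFactors = FALSE)
  structure(list(boundaries = boundaries, landmark_stations = proj),
            class = "segment_definition")
}

#' @export
print.segment_definition <- function(x, ...) {
  cat("<segment_definition>\n")
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

# station membership: half-open [start, end) except the final segment
segment_membership <- function(stations, seg) {
  b <- seg$boundaries
  lab <- rep(NA_character_, length(stations))
  for (i in seq_len(nrow(b))) {
    inb <- if (i < nrow(b))
      stations >= b$s_start[i] - 1e-9 & stations < b$s_end[i] - 1e-9
    else stations >= b$s_start[i] - 1e-9 & stations <= b$s_end[i] + 1e-9
    lab[inb] <- b$label[i]
  }
  lab
}

#' Per-segment mean of a station profile, BSA-indexed
#'
#' Averages a per-station profile (diameter, curvature, ...) within each
#' anatomical segment and divides by the subject's body surface area.
#'
#' @param profile numeric vector of per-station values
#' @param stations arc lengths (mm) the profile is sampled on
#' @param seg a `segment_definition`
#' @param meta a [subject_meta()] (or single BSA in m^2); use `bsa = 1`
#'   for unindexed means
#' @return data frame with columns `segment`, `mean`, `mean_indexed`
#' @export
segment_summary <- function(profile, stations, seg, meta) {
  if (length(profile) != length(stations))
    stop("profile and stations lengths differ")
  lab <- segment_membership(stations, seg)
  out <- lapply(seg$boundaries$label, function(L) {
    v <- profile[!is.na(lab) & lab == L]
    v <- v[is.finite(v)]
    if (!length(v)) stop(sprintf("segment %s contains no stations", L))
    data.frame(segment = L, mean = mean(v),
               mean_indexed = index_by_bsa(mean(v), meta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
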