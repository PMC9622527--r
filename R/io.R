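# Readers/writers for NIfTI fields and masks, JSON sidecars, YAML study
# configuration, and the end-to-end pipeline.
#
# Grids are axis-aligned: voxel spacing comes from the NIfTI pixdim and
# the world origin / frame times from a JSON sidecar written next to the
# image (<file>.json). Velocities are stored in m/s.

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path),
                                      ".json")

#' Write / read a 4D velocity series as NIfTI + JSON sidecar
#'
#' The field is stored as a 5-D NIfTI with dimensions (X, Y, Z, T, 3) in
#' float32; the world origin (mm) and frame times (ms) go to a JSON
#' sidecar next to the image. `read_velocity_series()` also accepts a
#' character vector of three per-component 4-D NIfTIs (X, Y, Z, T), which
#' must share grid, spacing and sidecar metadata.
#'
#' @param field a [velocity_field4d()]
#' @param path output `.nii.gz` path
#' @return `write_velocity_series()` the path, invisibly;
#'   `read_velocity_series()` a [velocity_field4d()]
#' @export
write_velocity_series <- function(field, path) {
  d <- dim(field$values)
  arr <- aperm(field$values, c(1, 2, 3, 5, 4))   # store as X,Y,Z,T,3
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(field$spacing, 1, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  jsonlite::write_json(list(origin_mm = field$origin,
                            frame_times_ms = field$frame_times,
                            units = "m/s"),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing JSON sidecar for '%s'", path))
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' @rdname write_velocity_series
#' @param frame_times frame times in ms, overriding the sidecar
#' @export
read_velocity_series <- function(path, frame_times = NULL) {
  if (length(path) == 3L) {
    comps <- lapply(path, RNifti::readNifti)
    dims <- lapply(comps, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      stop(sprintf("component grids differ: '%s'", path[2]))
    sp <- RNifti::pixdim(comps[[1]])[1:3]
    for (i in 2:3)
      if (!isTRUE(all.equal(sp, RNifti::pixdim(comps[[i]])[1:3])))
        stop(sprintf("voxel spacing differs in component file '%s'", path[i]))
    d <- dims[[1]]
    arr <- array(0, dim = c(d[1:3], 3, d[4]))
    for (i in 1:3) arr[, , , i, ] <- aperm(array(as.numeric(comps[[i]]), d),
                                           c(1, 2, 3, 4))
    sc <- read_sidecar(path[1])
    return(velocity_field4d(arr, sp,
                            frame_times = frame_times %||% sc$frame_times_ms,
                            origin = sc$origin_mm))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 5L || d[5] != 3L)
    stop(sprintf("'%s' is not a 5-D (X,Y,Z,T,3) velocity series", path))
  sc <- read_sidecar(path)
  vals <- aperm(array(as.numeric(img), d), c(1, 2, 3, 5, 4))
  velocity_field4d(vals, RNifti::pixdim(img)[1:3],
                   frame_times = frame_times %||% sc$frame_times_ms,
                   origin = sc$origin_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a lumen mask as NIfTI + JSON sidecar
#'
#' On reading, voxels above 0.5 are foreground; if the foreground has
#' several connected components the largest is kept with a warning. An
#' all-zero mask is an error.
#'
#' @param mask a [lumen_mask()]
#' @param path `.nii.gz` path
#' @return `write_mask()` the path invisibly; `read_mask()` a
#'   [lumen_mask()]
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  jsonlite::write_json(list(origin_mm = mask$origin), sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img) > 0.5, dim(img)[1:3])
  if (!any(vox)) stop(sprintf("mask '%s' is empty", path))
  sc <- read_sidecar(path)
  lc <- largest_component3(vox)
  if (lc$n_components > 1L) {
    warning(sprintf("mask '%s' has %d connected components; keeping the largest",
                    path, lc$n_components))
    vox <- lc$component
  }
  lumen_mask(vox, RNifti::pixdim(img)[1:3], origin = sc$origin_mm)
}

#' Read anatomical landmarks from JSON
#'
#' Expects an object mapping landmark names (`aortic_valve`,
#' `brachiocephalic`, `left_subclavian`, `da_at_valve_level`, `diaphragm`)
#' to world coordinates `[x, y, z]` in mm.
#'
#' @param path JSON file
#' @return named list of numeric length-3 vectors
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file '%s' not found", path))
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lm, as.numeric)
}

#' Read subject metadata from JSON
#'
#' Expects `{subject_id, bsa_m2, heart_period_ms, group}`.
#'
#' @param path JSON file
#' @return a [subject_meta()]
#' @export
read_subject_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata file '%s' not found", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_meta(m$subject_id, m$bsa_m2, m$heart_period_ms,
               m$group %||% NA_character_)
}

# polynomial rolling hash of the JSON-serialised configuration, for the
# provenance line embedded in every output file
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = 10)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Study configuration
#'
#' Loads (from YAML) or builds the configuration driving [run_pipeline()]:
#' input paths, fluid properties, analysis thresholds and flags. All
#' thresholds are validated against their documented bounds, defaults are
#' filled in, and a hash of the resolved configuration is recorded in
#' every output file.
#'
#' @param x path to a YAML file, or a named list
#' @return a validated `study_config` list
#' @export
study_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    fluid = list(density = 1060, viscosity = 0.004),
    thresholds = list(q_min_frac = 0.1, pwv_window_mm = 20, upsample = 20,
                      alpha = 0.05),
    flags = list(periodic = FALSE, peak_frame = NULL),
    seed = 1L)
  for (sec in names(defaults)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- defaults[[sec]]
    else for (k in names(defaults[[sec]]))
      if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- defaults[[sec]][[k]]
  }
  th <- cfg$thresholds
  if (th$q_min_frac <= 0 || th$q_min_frac > 0.5)
    stop("q_min_frac must be in (0, 0.5]")
  if (th$pwv_window_mm < 4) stop("pwv_window_mm must be at least 4 mm")
  if (th$upsample < 1) stop("upsample factor must be >= 1")
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$fluid$density <= 0 || cfg$fluid$viscosity <= 0)
    stop("fluid properties must be positive")
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "study_config")
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# aortaflow %s config %s",
                     as.character(utils::packageVersion("aortaflow")), hash),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full conduit / reservoir analysis pipeline
#'
#' Executes the analysis chain for one subject: load the velocity field,
#' lumen mask, landmarks and metadata; virtual angiography (peak-systolic
#' frame); centreline extraction between the aortic-valve and diaphragm
#' landmarks; four-segment subdivision; diameter and curvature profiles
#' with BSA-indexed segment means; per-segment WERP pressure traces and
#' timing metrics; peak-systolic advective (SAW) pressure profile;
#' flow-waveform PWV and Moens-Korteweg stiffness profile; and a QC
#' report (flow-conservation residuals, invalid frame and window counts).
#' All outputs are CSV/JSON files carrying the configuration hash, and the
#' run is deterministic given the configuration and seed.
#'
#' @param config a [study_config()] (or path / list coercible to one) with
#'   `paths$velocity`, `paths$mask`, `paths$landmarks`, `paths$metadata`
#'   and `paths$out_dir`; optional `wall_thickness_mm` (per-segment or
#'   scalar endo/epi-derived wall thickness used for the elastic modulus)
#' @return list of results (geometry, conduit, reservoir, qc), invisibly
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  set.seed(cfg$seed)
  stage <- function(name) message(sprintf("[aortaflow] %-22s %s", name,
                                          format(Sys.time(), "%H:%M:%OS1")))
  props <- fluid_properties(cfg$fluid$density, cfg$fluid$viscosity)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage("load")
  field <- read_velocity_series(cfg$paths$velocity)
  mask <- read_mask(cfg$paths$mask)
  if (!all(dim(mask$voxels) == dim(field$values)[1:3]))
    stop("mask grid does not match the velocity field grid")
  landmarks <- read_landmarks(cfg$paths$landmarks)
  meta <- read_subject_meta(cfg$paths$metadata)

  stage("virtual angiography")
  angio <- peak_systolic_speed(field, mask)

  stage("centreline")
  cl <- extract_centreline(mask, landmarks$aortic_valve, landmarks$diaphragm)
  seg <- assign_segments(cl, landmarks)

  stage("geometry profiles")
  stations <- cl$arc_length
  sections <- lapply(stations, function(s)
    tryCatch(cross_section_at(mask, cl, s), error = function(e) NULL))
  diam <- vapply(sections, function(cs)
    if (is.null(cs)) NA_real_ else cs$diameter, numeric(1))
  kappa <- curvature_profile(cl)
  geom_profile <- data.frame(station_mm = stations,
                             curvature_per_m = kappa, diameter_mm = diam)
  geom_segments <- merge(
    stats::setNames(segment_summary(diam, stations, seg, meta),
                    c("segment", "diameter_mm", "diameter_mm_per_m2")),
    stats::setNames(segment_summary(kappa, stations, seg, meta),
                    c("segment", "curvature_per_m", "curvature_per_m_per_m2")),
    by = "segment", sort = FALSE)

  stage("conduit traces")
  ok_cs <- !vapply(sections, is.null, logical(1))
  seg_cs <- function(s) {
    i <- which(ok_cs)[which.min(abs(stations[ok_cs] - s))]
    sections[[i]]
  }
  b <- seg$boundaries
  conduit <- list(); qc_flow <- list()
  for (i in seq_len(nrow(b))) {
    cv <- segment_control_volume(mask, seg_cs(b$s_start[i]),
                                 seg_cs(b$s_end[i]), cl)
    tr <- segment_pressure_traces(field, cv, props,
                                  periodic = isTRUE(cfg$flags$periodic),
                                  q_min_frac = cfg$thresholds$q_min_frac,
                                  period = meta$heart_period)
    tm <- timing_metrics(tr)
    conduit[[b$label[i]]] <- list(traces = tr, timing = tm)
    qc_flow[[b$label[i]]] <- list(
      flow_conservation_residual =
        max(abs(tr$q_in_ml_s - tr$q_out_ml_s)) / max(abs(tr$q_ml_s)),
      n_invalid_frames = sum(!tr$valid))
    write_report_csv(tr, file.path(out_dir,
                                   sprintf("conduit_traces_%s.csv",
                                           b$label[i])), cfg$hash)
  }
  conduit_summary <- do.call(rbind, lapply(b$label, function(L) {
    tr <- conduit[[L]]$traces; tm <- conduit[[L]]$timing
    data.frame(segment = L,
               peak_dp_tot_mmhg = max(tr$dp_tot_mmhg, na.rm = TRUE),
               peak_dp_kin_mmhg = max(tr$dp_kin_mmhg, na.rm = TRUE),
               peak_dp_adv_mmhg = max(tr$dp_adv_mmhg, na.rm = TRUE),
               peak_ve_rate_mj_s = max(tr$ve_rate_mj_s, na.rm = TRUE),
               t_peak_dp_tot_ms = tm$t_peak_dp_tot,
               t_peak_dp_kin_ms = tm$t_peak_dp_kin,
               t_zero_crossing_dp_kin_ms = tm$t_zero_crossing_dp_kin)
  }))

  stage("advective profile")
  pk <- cfg$flags$peak_frame %||% angio$peak_frame
  saw <- saw_profile(field, mask, cl, props, frame = pk, seg = seg)

  stage("reservoir")
  ws <- waveform_series(field, mask, cl, upsample = cfg$thresholds$upsample,
                        sections = if (all(ok_cs)) sections else NULL)
  th_mm <- cfg$wall_thickness_mm %||% rep(1, length(stations))
  stiff <- stiffness_profile(ws, diam, th_mm, seg, props,
                             window = cfg$thresholds$pwv_window_mm)

  stage("report")
  write_report_csv(geom_profile, file.path(out_dir, "geometry_profile.csv"),
                   cfg$hash)
  write_report_csv(geom_segments, file.path(out_dir, "geometry_segments.csv"),
                   cfg$hash)
  write_report_csv(conduit_summary, file.path(out_dir, "conduit_summary.csv"),
                   cfg$hash)
  write_report_csv(saw$profile, file.path(out_dir, "saw_profile.csv"),
                   cfg$hash)
  write_report_csv(data.frame(segment = names(saw$segment_delta),
                              saw_delta_mmhg = as.numeric(saw$segment_delta)),
                   file.path(out_dir, "saw_segments.csv"), cfg$hash)
  write_report_csv(stiff$profile, file.path(out_dir, "reservoir_profile.csv"),
                   cfg$hash)
  write_report_csv(stiff$segments, file.path(out_dir,
                                             "reservoir_segments.csv"),
                   cfg$hash)
  qc <- list(software_version =
               as.character(utils::packageVersion("aortaflow")),
             config_hash = cfg$hash, subject_id = meta$subject_id,
             peak_frame = pk, centreline_length_mm = max(stations),
             flow_conservation = qc_flow,
             n_invalid_pwv_windows = sum(!stiff$profile$valid),
             n_missing_cross_sections = sum(!ok_cs))
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(centreline = cl, segments = seg,
                 geometry = list(profile = geom_profile,
                                 segments = geom_segments),
                 conduit = list(per_segment = conduit,
                                summary = conduit_summary),
                 saw = saw, reservoir = stiff, qc = qc))
}
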