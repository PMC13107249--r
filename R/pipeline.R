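# End-to-end pipeline: phantom pair -> preprocess -> segment -> reconstruct
# -> compare states -> flow -> obstruction localization, driven by a single
# resolved configuration and a single seed.

#' Default pipeline configuration
#'
#' Returns the fully resolved configuration the pipeline runs with when no
#' overrides are given. The phantom block reproduces the study conditions
#' (150 mm span, 6 mm pharyngeal radius, asleep-state area losses of 8%,
#' 56% and 32% in the nasopharynx, base of tongue and epiglottis); the
#' acquisition block keeps the protocol timing (25 frames/s, 12.5 mm/s,
#' 12.8 mm range) but samples 360 A-lines x 512 depth pixels per frame —
#' the package's desk-scale sampling density, ample for sub-pixel wall
#' localization at these radii.
#'
#' @return a nested named list; see the fields themselves for units.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 0L,
    phantom = list(span = 150, baseRadius = 6.0, taperWidth = 4,
      offsetAmplitude = 0.5, curved = TRUE),
    geometry = list(framesPerS = 25, alinesPerFrame = 360L,
      pullbackSpeed = 12.5, depthRange = 12.8, depthPixels = 512L,
      axialPsfFwhm = 0.010),
    imaging = list(maskBand = c(0.7, 1.1), align = TRUE),
    segmentation = list(enabled = TRUE, exclusionMm = 1.3, k = 4, m = 5L,
      smoothWindow = 9L, maxMissingFrac = 0.5, fillSearchLimit = 10L),
    reconstruction = list(trim = c(5, 5), contourDecimate = 4L),
    tracker = list(noiseSd = 0.1),
    flow = list(enabled = TRUE, dx = 0.75, inflowLpm = 9.45, Re = 200,
      collision = "mrt", mode = "steady", uLat = 0.03, maxSteps = 16000L,
      avgSteps = 1000L, stations = 7L),
    out = NULL
  )
}

# contours with every k-th vertex (loft/voxelization economy)
.decimate_contour <- function(ct, k) {
  if (k <= 1L) return(ct)
  i <- seq(1L, nrow(ct@vertices), by = k)
  new("LumenContour", frameIndex = ct@frameIndex, z = ct@z,
    vertices = ct@vertices[i, , drop = FALSE],
    sectorValid = ct@sectorValid[i], extrapolated = ct@extrapolated[i],
    usable = ct@usable)
}

# one state through render -> preprocess -> segment -> areas
.measure_state <- function(state, cfg, geometry, seed) {
  phantom <- makePhantom(state, seed = seed,
    span = cfg$phantom$span, baseRadius = cfg$phantom$baseRadius,
    taperWidth = cfg$phantom$taperWidth,
    offsetAmplitude = cfg$phantom$offsetAmplitude,
    curved = cfg$phantom$curved)
  pull <- simulatePullback(phantom, geometry,
    trackerNoiseSd = cfg$tracker$noiseSd, seed = seed)
  if (isTRUE(cfg$segmentation$enabled)) {
    stack <- lapply(pull$stack, maskSheathArtifact, band = cfg$imaging$maskBand)
    if (isTRUE(cfg$imaging$align)) stack <- alignFrames(stack)$stack
    sg <- cfg$segmentation
    contours <- lapply(stack, contourFromFrame, exclusionMm = sg$exclusionMm,
      k = sg$k, m = sg$m, smoothWindow = sg$smoothWindow,
      maxMissingFrac = sg$maxMissingFrac)
    contours <- fillMissingSectors(contours, searchLimit = sg$fillSearchLimit)
  } else {
    # segmentation bypass: inject analytic truth contours
    phi <- 2 * pi * (seq_len(geometry@alinesPerFrame) - 1L) /
      geometry@alinesPerFrame
    contours <- lapply(seq_along(pull$z), function(i) {
      m <- -phantomOffset(phantom, pull$z[i])[1, ]
      r <- phantomRadius(phantom, pull$z[i])
      new("LumenContour", frameIndex = i - 1L, z = pull$z[i],
        vertices = cbind(m[1] + r * cos(phi), m[2] + r * sin(phi)),
        sectorValid = rep(TRUE, length(phi)),
        extrapolated = rep(FALSE, length(phi)), usable = TRUE)
    })
  }
  areas <- data.frame(
    z_mm = pull$z,
    area_mm2 = vapply(contours, function(ct) as.numeric(crossSectionalArea(ct)),
      0),
    pct_extrapolated = vapply(contours,
      function(ct) 100 * mean(ct@extrapolated), 0))
  list(phantom = phantom, pull = pull, contours = contours, areas = areas)
}

#' Run the full obstruction-localization pipeline
#'
#' Executes phantom (awake + asleep) -> preprocessing -> segmentation ->
#' area measurement -> awake/asleep comparison, and (when enabled) flow
#' simulation on the asleep geometry followed by obstruction ranking. All
#' randomness derives from `config$seed`; identical configurations give
#' identical reports. When `config$out` is a directory, the resolved
#' configuration and all artifacts (areas, contours, centerline, mesh,
#' flow field, obstruction table) are written beside the report.
#'
#' @param config configuration list; missing entries are filled from
#'   [defaultPipelineConfig()].
#' @return a report list: `reductions` (data.frame per region),
#'   `dominant_site`, `profile` ([ObstructionProfile-class] or `NULL`),
#'   `flow_summary`, `areas_awake`, `areas_asleep`, `config`.
#' @export
runPipeline <- function(config = list()) {
  cfg <- .merge_config(defaultPipelineConfig(), config)
  g <- cfg$geometry
  geometry <- acquisitionGeometry(g$framesPerS, g$alinesPerFrame,
    g$pullbackSpeed, g$depthRange, g$depthPixels, g$axialPsfFwhm)
  seed <- as.integer(cfg$seed)

  awake <- .measure_state("awake", cfg, geometry, seed)
  asleep <- .measure_state("asleep", cfg, geometry, seed + 1L)

  reductions <- compareStates(awake$areas, asleep$areas,
    awake$phantom@regionWindows)

  profile <- NULL
  flowSummary <- NULL
  field <- NULL
  surf <- NULL
  if (isTRUE(cfg$flow$enabled)) {
    dec <- lapply(asleep$contours, .decimate_contour,
      k = cfg$reconstruction$contourDecimate)
    z <- asleep$pull$z
    cl <- new("Centerline", samples = cbind(0, 0, z), arcLength = z,
      tangent = matrix(0, 0, 3), normal1 = matrix(0, 0, 3),
      normal2 = matrix(0, 0, 3), residualRms = 0)
    surf <- loftSurface(dec, framesAlongCenterline(cl),
      trim = cfg$reconstruction$trim)
    lat <- voxelize(surf, cfg$flow$dx)
    field <- runSimulation(lat, inflowLpm = cfg$flow$inflowLpm,
      mode = cfg$flow$mode, collision = cfg$flow$collision,
      Re = cfg$flow$Re, uLat = cfg$flow$uLat,
      maxSteps = cfg$flow$maxSteps, avgSteps = cfg$flow$avgSteps)
    stationDf <- stationPressures(field, cfg$flow$stations)
    profile <- rankObstructions(obstructionProfile(stationDf))
    u <- velocityField(field)
    speed <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    p <- pressureField(field)
    flowSummary <- list(
      Re = field@conversions$Re,
      collision = field@conversions$collision,
      status = field@status,
      steps = field@stepsRun,
      max_speed_m_s = max(speed, na.rm = TRUE),
      pressure_drop_pa = max(p, na.rm = TRUE) - min(p, na.rm = TRUE))
  }

  report <- list(
    reductions = reductions,
    dominant_site = if (!is.null(profile)) profile@dominantSite else NA_character_,
    profile = profile,
    flow_summary = flowSummary,
    areas_awake = awake$areas,
    areas_asleep = asleep$areas,
    config = cfg)

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    writePipelineConfig(cfg, file.path(cfg$out, "config_resolved.yaml"))
    utils::write.csv(awake$areas, file.path(cfg$out, "areas_awake.csv"),
      row.names = FALSE)
    utils::write.csv(asleep$areas, file.path(cfg$out, "areas_asleep.csv"),
      row.names = FALSE)
    utils::write.csv(reductions, file.path(cfg$out, "region_reductions.csv"),
      row.names = FALSE)
    writeContours(asleep$contours, file.path(cfg$out, "contours_asleep.json"))
    if (!is.null(surf)) {
      writeSTL(surf, file.path(cfg$out, "airway_asleep.stl"))
      writeVTKPolyData(surf, file.path(cfg$out, "airway_asleep.vtk"))
    }
    if (!is.null(field))
      writeVTKImageData(field, file.path(cfg$out, "flow_field.vtk"))
    if (!is.null(profile)) {
      utils::write.csv(
        data.frame(station = profile@stations, z_mm = profile@z,
          area_mm2 = profile@area, p_bar_pa = profile@pBar,
          dp_dz = profile@dpDz, d2p_dz2 = profile@d2pDz2),
        file.path(cfg$out, "obstruction_profile.csv"), row.names = FALSE)
    }
  }
  report
}
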