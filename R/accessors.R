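#' Construct an acquisition geometry
#'
#' Defaults are the clinical pullback protocol: 25 frames/s with 2000
#' A-lines per rotation, 12.5 mm/s pullback, 12.8 mm imaging range sampled
#' at 1024 depth pixels, and a 10 um axial PSF. The derived frame spacing is
#' `12.5 / 25 = 0.5` mm.
#'
#' @param framesPerS rotational frame rate (frames/s).
#' @param alinesPerFrame A-lines per B-scan.
#' @param pullbackSpeed pullback speed (mm/s).
#' @param depthRange depth range per A-line (mm).
#' @param depthPixels depth samples per A-line.
#' @param axialPsfFwhm axial PSF FWHM (mm).
#' @return an [AcquisitionGeometry-class] object.
#' @examples
#' g <- acquisitionGeometry()
#' frameSpacing(g)  # 0.5 mm
#' @export
acquisitionGeometry <- function(framesPerS = 25, alinesPerFrame = 2000L,
                                pullbackSpeed = 12.5, depthRange = 12.8,
                                depthPixels = 1024L, axialPsfFwhm = 0.010) {
  new("AcquisitionGeometry",
    framesPerS = framesPerS,
    alinesPerFrame = as.integer(alinesPerFrame),
    pullbackSpeed = pullbackSpeed,
    depthRange = depthRange,
    depthPixels = as.integer(depthPixels),
    axialPsfFwhm = axialPsfFwhm
  )
}

#' @describeIn acquisitionGeometry B-scan spacing along the pullback,
#'   `pullbackSpeed / framesPerS` (mm).
#' @param geometry an [AcquisitionGeometry-class].
#' @export
frameSpacing <- function(geometry) geometry@pullbackSpeed / geometry@framesPerS

#' @describeIn acquisitionGeometry depth pixel pitch,
#'   `depthRange / depthPixels` (mm/pixel).
#' @export
pixelPitch <- function(geometry) geometry@depthRange / geometry@depthPixels

#' @rdname intensity
#' @title Basic slot accessors
#' @description Read-only accessors for the core classes.
#' @param x the object.
#' @return the slot contents.
#' @export
intensity <- function(x) x@intensity

#' @rdname intensity
#' @export
sectorValid <- function(x) x@sectorValid

#' @rdname intensity
#' @export
vertices <- function(x) x@vertices

#' @rdname intensity
#' @export
frameIndex <- function(x) x@frameIndex

#' @rdname intensity
#' @export
arcLength <- function(x) x@arcLength

#' @rdname intensity
#' @export
occupancy <- function(x) x@occupancy

#' @rdname intensity
#' @export
conversions <- function(x) x@conversions

#' @rdname intensity
#' @export
dominantSite <- function(x) x@dominantSite

#' @rdname intensity
#' @export
siteRanking <- function(x) x@ranking

#' Physical velocity field of a flow solution
#'
#' @param field a [FlowField-class].
#' @return a 4D array `(nx, ny, nz, 3)` of velocity in m/s (`NA` on solid).
#' @export
velocityField <- function(field) {
  cu <- field@conversions$u_phys_per_lat
  out <- array(NA_real_, c(dim(field@ux), 3L))
  out[, , , 1] <- field@ux * cu
  out[, , , 2] <- field@uy * cu
  out[, , , 3] <- field@uz * cu
  out
}

#' Physical pressure field of a flow solution
#'
#' Pressure is `c_s^2 (rho - rho0)` in lattice units, converted to Pa with
#' the recorded velocity scale and air density.
#'
#' @param field a [FlowField-class].
#' @return a 3D array of pressure in Pa relative to the outlet reference.
#' @export
pressureField <- function(field) {
  (field@rho - 1) / 3 * field@conversions$p_phys_per_lat
}

#' Interpolate phantom truth profiles
#'
#' @param phantom an [AirwayPhantom-class].
#' @param z arc-length positions (mm).
#' @return `phantomRadius`: lumen radius (mm); `phantomArea`: cross-sectional
#'   area `pi r^2` (mm^2); `phantomCenter`: n x 3 centerline points;
#'   `phantomOffset`: n x 2 catheter eccentricity (mm).
#' @export
phantomRadius <- function(phantom, z) {
  stats::approx(phantom@zGrid, phantom@radius, z, rule = 2)$y
}

#' @rdname phantomRadius
#' @export
phantomArea <- function(phantom, z) pi * phantomRadius(phantom, z)^2

#' @rdname phantomRadius
#' @export
phantomCenter <- function(phantom, z) {
  cbind(
    stats::approx(phantom@zGrid, phantom@centerlinePts[, 1], z, rule = 2)$y,
    stats::approx(phantom@zGrid, phantom@centerlinePts[, 2], z, rule = 2)$y,
    stats::approx(phantom@zGrid, phantom@centerlinePts[, 3], z, rule = 2)$y
  )
}

#' @rdname phantomRadius
#' @export
phantomOffset <- function(phantom, z) {
  cbind(
    stats::approx(phantom@zGrid, phantom@catheterOffset[, 1], z, rule = 2)$y,
    stats::approx(phantom@zGrid, phantom@catheterOffset[, 2], z, rule = 2)$y
  )
}

#' @rdname intensity
#' @export
regionWindows <- function(x) x@regionWindows

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry:",
    sprintf("%g frames/s, %d A-lines/frame, %g mm/s pullback",
      object@framesPerS, object@alinesPerFrame, object@pullbackSpeed), "\n")
  cat(sprintf("  depth range %g mm in %d pixels (pitch %.4g mm), PSF %g um\n",
    object@depthRange, object@depthPixels, pixelPitch(object),
    1000 * object@axialPsfFwhm))
  cat(sprintf("  frame spacing %g mm\n", frameSpacing(object)))
})

setMethod("show", "AirwayPhantom", function(object) {
  cat(sprintf("AirwayPhantom (%s), span %.1f mm, seed %d\n",
    object@state, object@span, object@seed))
  cat(sprintf("  radius %.2f-%.2f mm; %d regions: %s\n",
    min(object@radius), max(object@radius), length(object@regionWindows),
    paste(names(object@regionWindows), collapse = ", ")))
  con <- object@stateConstriction[object@stateConstriction < 1]
  if (length(con))
    cat("  constricted:", paste(sprintf("%s=%.2f", names(con), con),
      collapse = ", "), "\n")
})

setMethod("show", "PolarBScan", function(object) {
  cat(sprintf("PolarBScan frame %d (z=%.1f mm): %d A-lines x %d depth px, pitch %.4g mm; %d/%d sectors valid\n",
    object@frameIndex, object@zNominal, nrow(object@intensity),
    ncol(object@intensity), object@pixelPitch,
    sum(object@sectorValid), length(object@sectorValid)))
})

setMethod("show", "LumenContour", function(object) {
  cat(sprintf("LumenContour frame %d (z=%.1f mm): %d vertices, %.1f%% measured, %.1f%% extrapolated%s\n",
    object@frameIndex, object@z, nrow(object@vertices),
    100 * mean(object@sectorValid), 100 * mean(object@extrapolated),
    if (object@usable) "" else " [UNUSABLE]"))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d stations over %.1f mm (residual RMS %.3g mm)%s\n",
    nrow(object@samples), diff(range(object@arcLength)), object@residualRms,
    if (nrow(object@tangent)) ", frames attached" else ""))
})

setMethod("show", "AirwaySurface", function(object) {
  cat(sprintf("AirwaySurface: %d vertices, %d triangles, volume %.1f mm^3\n",
    nrow(object@vertices), nrow(object@triangles), meshVolume(object)))
})

setMethod("show", "VoxelLattice", function(object) {
  d <- dim(object@occupancy)
  tab <- tabulate(object@occupancy + 1L, 4L)
  cat(sprintf("VoxelLattice %d x %d x %d @ dx=%g mm: %d fluid, %d inlet, %d outlet\n",
    d[1], d[2], d[3], object@dx, tab[2], tab[3], tab[4]))
})

setMethod("show", "FlowField", function(object) {
  cv <- object@conversions
  cat(sprintf("FlowField (%s, %s): %s after %d steps\n",
    cv$collision, cv$mode, object@status, object@stepsRun))
  cat(sprintf("  dx=%g mm, dt=%.3g s, tau=%.4f, nu_lat=%.4g, Re=%g\n",
    cv$dx_mm, cv$dt_s, cv$tau, cv$nu_lat, cv$Re))
})

setMethod("show", "ObstructionProfile", function(object) {
  cat(sprintf("ObstructionProfile: %d stations (%s)\n",
    length(object@stations), paste(object@stations, collapse = "")))
  if (object@noFocalObstruction) {
    cat("  no focal obstruction (pressure profile essentially linear)\n")
  } else {
    cat(sprintf("  dominant site: %s (z=%.1f mm)\n", object@dominantSite,
      object@z[match(object@dominantSite, object@stations)]))
  }
})
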