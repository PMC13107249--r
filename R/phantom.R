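# Synthetic airway phantom: paired awake/asleep geometries, rendered polar
# B-scan stacks, tracker coordinates, and analytic ground truth.

.default_region_windows <- function() {
  list(
    nasopharynx = c(10, 38),
    velopharynx = c(44, 68),
    base_of_tongue = c(74, 100),
    epiglottis = c(110, 126),
    hypopharynx = c(132, 146)
  )
}

# Asleep-state area scale factors: the three constricted regions lose 8%,
# 56% and 32% of their cross-sectional area (nasopharynx, base of tongue,
# epiglottic region).
.asleep_constriction <- function() {
  c(nasopharynx = 0.92, base_of_tongue = 0.44, epiglottis = 0.68)
}

# Cosine-tapered area scale profile. The full factor holds across the
# window; half-cosine ramps of width `taper` sit immediately OUTSIDE the
# window edges, so within-window means equal the nominal factor exactly.
.constriction_profile <- function(z, windows, factors, taper) {
  s <- rep(1, length(z))
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (f >= 1) next
    w <- windows[[nm]]
    sf <- rep(1, length(z))
    inside <- z >= w[1] & z <= w[2]
    sf[inside] <- f
    up <- z > w[1] - taper & z < w[1]
    sf[up] <- 1 + (f - 1) * 0.5 * (1 - cos(pi * (z[up] - (w[1] - taper)) / taper))
    dn <- z > w[2] & z < w[2] + taper
    sf[dn] <- f + (1 - f) * 0.5 * (1 - cos(pi * (z[dn] - w[2]) / taper))
    s <- s * sf
  }
  s
}

# Gently curved 3D catheter path, reparameterized to arc length so that
# station z IS arc length along the curve. `curved = FALSE` gives the z-axis.
.phantom_centerline <- function(zGrid, span, curved) {
  if (!curved) {
    return(cbind(0, 0, zGrid))
  }
  shape <- function(t, Lz) cbind(8 * sin(pi * t), 3 * sin(2 * pi * t), Lz * t)
  Lz <- span
  tFine <- seq(0, 1, length.out = 4001)
  for (i in 1:4) {
    p <- shape(tFine, Lz)
    seg <- sqrt(rowSums(diff(p)^2))
    Lz <- Lz * span / sum(seg)
  }
  p <- shape(tFine, Lz)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  s <- s / s[length(s)] * span
  cbind(
    stats::approx(s, p[, 1], zGrid)$y,
    stats::approx(s, p[, 2], zGrid)$y,
    stats::approx(s, p[, 3], zGrid)$y
  )
}

#' Build a synthetic airway phantom
#'
#' Constructs the analytic awake or asleep airway model used as ground truth
#' throughout the pipeline. Lumen cross-sections are circles of radius
#' `baseRadius * sqrt(s(z))`, where `s(z)` is the per-region area scale
#' profile: 1 everywhere in the awake state; 0.92, 0.44 and 0.68 in the
#' nasopharynx, base-of-tongue and epiglottis windows in the asleep state
#' (8%, 56% and 32% area loss), with half-cosine ramps of width `taperWidth`
#' just outside the window edges. The asleep phantom is identical to the
#' awake one in every other respect.
#'
#' @param state `"awake"` or `"asleep"`.
#' @param seed integer seed recorded with the phantom and used as the default
#'   by the renderers.
#' @param span total arc length (mm).
#' @param baseRadius unconstricted lumen radius (mm).
#' @param regionWindows named list of `c(lo, hi)` arc-length windows (mm),
#'   ordered and disjoint.
#' @param constriction named area scale factors for the asleep state.
#' @param taperWidth half-cosine ramp width at window edges (mm).
#' @param offsetAmplitude catheter eccentricity amplitude (mm); the catheter
#'   meanders sinusoidally inside the lumen.
#' @param curved use the curved default centerline (`FALSE` gives a straight
#'   z-axis path, convenient for flow validation).
#' @return an [AirwayPhantom-class].
#' @examples
#' ph <- makePhantom("asleep", seed = 0)
#' phantomRadius(ph, 87)          # constricted base-of-tongue radius
#' phantomArea(ph, 87) / phantomArea(makePhantom("awake"), 87)  # 0.44
#' @export
makePhantom <- function(state = c("awake", "asleep"), seed = 0L,
                        span = 150, baseRadius = 6.0,
                        regionWindows = .default_region_windows(),
                        constriction = .asleep_constriction(),
                        taperWidth = 4, offsetAmplitude = 0.5,
                        curved = TRUE) {
  if (!is.character(state) || !state[1] %in% c("awake", "asleep"))
    stop("unknown state '", state[1], "': valid labels are 'awake', 'asleep'")
  state <- state[1]
  zGrid <- seq(0, span, by = 0.1)
  factors <- if (state == "asleep") constriction else
    stats::setNames(rep(1, length(constriction)), names(constriction))
  scale <- .constriction_profile(zGrid, regionWindows, as.list(factors), taperWidth)
  radius <- baseRadius * sqrt(scale)
  offset <- cbind(
    offsetAmplitude * sin(2 * pi * zGrid / 37),
    offsetAmplitude * cos(2 * pi * zGrid / 53)
  )
  new("AirwayPhantom",
    state = state,
    zGrid = zGrid,
    centerlinePts = .phantom_centerline(zGrid, span, curved),
    radius = radius,
    baseRadius = rep(baseRadius, length(zGrid)),
    catheterOffset = offset,
    regionWindows = regionWindows,
    stateConstriction = factors,
    taperWidth = taperWidth,
    span = span,
    seed = as.integer(seed)
  )
}

# Distance from the catheter (origin) to the lumen wall along unit
# directions `u` (n x 2), for a circular section of radius r centered at `m`
# relative to the catheter. Returns NA where the ray misses (never happens
# while the catheter is inside the lumen).
.wall_distance <- function(u, m, r) {
  b <- u[, 1] * m[1] + u[, 2] * m[2]
  disc <- r^2 - sum(m^2) + b^2
  d <- b + sqrt(pmax(disc, 0))
  d[disc < 0] <- NA_real_
  d
}

# Core renderer; consumes the current RNG stream.
.render_bscan_impl <- function(phantom, geometry, stationZ,
                               sheath = TRUE, sheathRadius = 0.9,
                               speckle = TRUE,
                               peakAmp = 1.0, tissueAmp = 1.0,
                               noiseSd = 0.02, tissueDecay = 1.2,
                               sheathAmp = 1.5) {
  nA <- geometry@alinesPerFrame
  nD <- geometry@depthPixels
  pitch <- pixelPitch(geometry)
  theta <- 2 * pi * (seq_len(nA) - 1L) / nA
  u <- cbind(cos(theta), sin(theta))
  m <- -phantomOffset(phantom, stationZ)[1, ]
  r <- phantomRadius(phantom, stationZ)
  d <- .wall_distance(u, m, r)
  valid <- !is.na(d) & d <= geometry@depthRange
  depth <- (seq_len(nD) - 1L) * pitch
  sigma <- geometry@axialPsfFwhm / (2 * sqrt(2 * log(2)))

  dd <- outer(ifelse(valid, d, Inf), depth, function(a, b) b - a)  # depth - wall
  img <- peakAmp * exp(-dd^2 / (2 * sigma^2)) +
    tissueAmp * stats::pnorm(dd / sigma) * exp(-pmax(dd, 0) / tissueDecay)
  img[!valid, ] <- 0

  if (speckle) {
    sigR <- 1 / sqrt(pi / 2)  # Rayleigh with unit mean
    spk <- matrix(sigR * sqrt(-2 * log(stats::runif(nA * nD))), nA, nD)
    # axial speckle correlation over ~3 pixels (finite coherence length)
    spk <- (spk + cbind(spk[, 1], spk[, -nD]) + cbind(spk[, -1], spk[, nD])) / 3
    img <- img * spk
  }
  img <- img + abs(matrix(stats::rnorm(nA * nD, 0, noiseSd), nA, nD))
  if (sheath) {
    ring <- sheathAmp * exp(-(depth - sheathRadius)^2 / (2 * max(2 * pitch, sigma)^2))
    img <- img + matrix(ring, nA, nD, byrow = TRUE)
  }
  fs <- frameSpacing(geometry)
  new("PolarBScan",
    intensity = img,
    pixelPitch = pitch,
    frameIndex = as.integer(round(stationZ / fs)),
    zNominal = stationZ,
    sectorValid = valid
  )
}

#' Render one rotational polar B-scan of the phantom
#'
#' For each A-line, the synthetic backscatter profile is: a wall echo at the
#' catheter-to-wall distance for that angle (Gaussian of the axial PSF
#' width), a tissue tail decaying exponentially beyond the wall, both
#' multiplied by axially correlated Rayleigh speckle of unit mean; an
#' additive rectified-Gaussian noise floor; and a bright specular ring at the
#' stationary sheath radius. A-lines whose wall distance exceeds the imaging
#' range carry no echo and are flagged truth-missing in `sectorValid`.
#'
#' @param phantom an [AirwayPhantom-class].
#' @param geometry an [AcquisitionGeometry-class].
#' @param stationZ arc-length station (mm); must lie within the span.
#' @param sheath render the sheath-reflection ring artifact.
#' @param sheathRadius sheath radius (mm).
#' @param speckle apply multiplicative speckle.
#' @param seed integer seed; `NULL` consumes the current RNG stream (used by
#'   [simulatePullback()] so one seed drives the whole stack).
#' @return a [PolarBScan-class].
#' @export
renderBScan <- function(phantom, geometry, stationZ, sheath = TRUE,
                        sheathRadius = 0.9, speckle = TRUE, seed = phantom@seed) {
  if (stationZ < 0 || stationZ > phantom@span)
    stop("station ", stationZ, " mm is outside the phantom span [0, ",
      phantom@span, "] mm")
  if (is.null(seed)) {
    .render_bscan_impl(phantom, geometry, stationZ, sheath, sheathRadius, speckle)
  } else {
    withr::with_seed(as.integer(seed),
      .render_bscan_impl(phantom, geometry, stationZ, sheath, sheathRadius, speckle))
  }
}

#' Simulate a full catheter pullback
#'
#' Renders B-scans at exactly `pullbackSpeed / framesPerS` spacing from
#' station 0 to the phantom span (`floor(span/spacing) + 1` frames) and
#' samples the electromagnetic tracker as centerline points with isotropic
#' Gaussian noise. A single seeded RNG stream drives all speckle, noise and
#' tracker jitter, so identical seeds give bit-identical output.
#'
#' @inheritParams renderBScan
#' @param trackerNoiseSd isotropic tracker noise SD (mm), `>= 0`.
#' @param seed integer seed for the whole pullback.
#' @return a list with `stack` (list of [PolarBScan-class]), `tracker`
#'   (data.frame `frame_index`, `x_mm`, `y_mm`, `z_mm`), and `z` (station
#'   arc lengths in mm).
#' @export
simulatePullback <- function(phantom, geometry, trackerNoiseSd = 0.1,
                             seed = phantom@seed, sheath = TRUE, speckle = TRUE) {
  stopifnot(trackerNoiseSd >= 0)
  fs <- frameSpacing(geometry)
  z <- seq(0L, floor(phantom@span / fs)) * fs
  withr::with_seed(as.integer(seed), {
    stack <- lapply(z, function(zi)
      .render_bscan_impl(phantom, geometry, zi, sheath = sheath, speckle = speckle))
    ctr <- phantomCenter(phantom, z)
    noise <- matrix(stats::rnorm(3 * length(z), 0, trackerNoiseSd), ncol = 3)
    tracker <- data.frame(
      frame_index = seq_along(z) - 1L,
      x_mm = ctr[, 1] + noise[, 1],
      y_mm = ctr[, 2] + noise[, 2],
      z_mm = ctr[, 3] + noise[, 3]
    )
    list(stack = stack, tracker = tracker, z = z)
  })
}

#' Analytic ground truth for a phantom
#'
#' Returns the per-station true areas (`pi r(z)^2`) and a watertight surface
#' lofted from the true circular contours along the true centerline. Used by
#' tests and validation runs; the measurement pipeline never sees it.
#'
#' @inheritParams renderBScan
#' @param nVertices vertices per truth contour.
#' @param straighten loft along a straight axis instead of the true curved
#'   centerline (arc length preserved); used to prepare flow domains with
#'   axis-aligned inlet/outlet planes.
#' @param trim arc length to drop from each end (mm), `c(proximal, distal)`.
#' @return list with `areas` (data.frame `z_mm`, `area_mm2`), `surface`
#'   (an [AirwaySurface-class]) and `centerline` (a [Centerline-class]).
#' @export
groundTruth <- function(phantom, geometry, nVertices = 128L,
                        straighten = FALSE, trim = c(0, 0)) {
  fs <- frameSpacing(geometry)
  z <- seq(0L, floor(phantom@span / fs)) * fs
  areas <- data.frame(z_mm = z, area_mm2 = phantomArea(phantom, z))

  phi <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  contours <- lapply(seq_along(z), function(i) {
    m <- -phantomOffset(phantom, z[i])[1, ]
    r <- phantomRadius(phantom, z[i])
    v <- cbind(m[1] + r * cos(phi), m[2] + r * sin(phi))
    new("LumenContour",
      frameIndex = i - 1L, z = z[i], vertices = v,
      sectorValid = rep(TRUE, nVertices),
      extrapolated = rep(FALSE, nVertices), usable = TRUE)
  })
  pts <- if (straighten) cbind(0, 0, z) else phantomCenter(phantom, z)
  cl <- new("Centerline",
    samples = pts, arcLength = z,
    tangent = matrix(0, 0, 3), normal1 = matrix(0, 0, 3),
    normal2 = matrix(0, 0, 3), residualRms = 0)
  cl <- framesAlongCenterline(cl)
  surface <- loftSurface(contours, cl, trim = trim)
  list(areas = areas, surface = surface, centerline = cl)
}
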