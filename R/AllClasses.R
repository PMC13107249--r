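#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib airwayflow, .registration = TRUE
NULL

#' Acquisition geometry of a rotational OCT pullback
#'
#' Describes the scanning apparatus: rotational frame rate, number of axial
#' scans (A-lines) per B-scan, pullback speed, imaging depth range and its
#' sampling, and the axial point-spread-function width. The B-scan spacing
#' along the pullback is always `pullbackSpeed / framesPerS` and the depth
#' pixel pitch is always `depthRange / depthPixels`; both are derived, never
#' stored.
#'
#' @slot framesPerS rotational B-scan rate (frames/s).
#' @slot alinesPerFrame number of A-lines per 360 degree rotation.
#' @slot pullbackSpeed catheter translation speed (mm/s).
#' @slot depthRange imaging range of one A-line (mm).
#' @slot depthPixels number of depth samples per A-line.
#' @slot axialPsfFwhm full width at half maximum of the axial PSF (mm).
#'
#' @seealso [acquisitionGeometry()], [frameSpacing()], [pixelPitch()]
#' @export
setClass("AcquisitionGeometry",
  representation(
    framesPerS = "numeric",
    alinesPerFrame = "integer",
    pullbackSpeed = "numeric",
    depthRange = "numeric",
    depthPixels = "integer",
    axialPsfFwhm = "numeric"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  if (object@framesPerS <= 0) msg <- c(msg, "framesPerS must be positive")
  if (object@alinesPerFrame < 8L) msg <- c(msg, "alinesPerFrame must be >= 8")
  if (object@pullbackSpeed <= 0) msg <- c(msg, "pullbackSpeed must be positive")
  if (object@depthRange <= 0) msg <- c(msg, "depthRange must be positive")
  if (object@depthPixels < 8L) msg <- c(msg, "depthPixels must be >= 8")
  if (object@axialPsfFwhm <= 0) msg <- c(msg, "axialPsfFwhm must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic airway phantom
#'
#' An analytic model of the upper-airway lumen used as ground truth: a 3D
#' centerline sampled densely in arc length, a circular cross-section radius
#' profile, named anatomical region windows along arc length, per-region
#' cross-sectional-area scale factors (the awake/asleep constrictions), and a
#' catheter eccentricity path inside the lumen. All profiles are stored on a
#' fine arc-length grid `zGrid` and interpolated by the accessors.
#'
#' @slot state `"awake"` or `"asleep"`.
#' @slot zGrid fine arc-length grid (mm) on which profiles are sampled.
#' @slot centerlinePts dense centerline samples, `length(zGrid)` x 3 (mm).
#' @slot radius lumen radius at `zGrid` (mm), constriction applied.
#' @slot baseRadius radius before constriction (mm).
#' @slot catheterOffset catheter eccentricity at `zGrid`, n x 2 (mm).
#' @slot regionWindows named list of `c(lo, hi)` arc-length windows (mm).
#' @slot stateConstriction named per-region area scale factors in (0, 1].
#' @slot taperWidth cosine taper width at window edges (mm).
#' @slot span total arc length (mm).
#' @slot seed integer seed the phantom was built from.
#' @export
setClass("AirwayPhantom",
  representation(
    state = "character",
    zGrid = "numeric",
    centerlinePts = "matrix",
    radius = "numeric",
    baseRadius = "numeric",
    catheterOffset = "matrix",
    regionWindows = "list",
    stateConstriction = "numeric",
    taperWidth = "numeric",
    span = "numeric",
    seed = "integer"
  )
)

setValidity("AirwayPhantom", function(object) {
  msg <- character()
  if (!object@state %in% c("awake", "asleep"))
    msg <- c(msg, "state must be 'awake' or 'asleep'")
  if (any(object@radius <= 0)) msg <- c(msg, "all radii must be strictly positive")
  sc <- object@stateConstriction
  if (length(sc) && (any(sc <= 0) || any(sc > 1)))
    msg <- c(msg, "area scale factors must lie in (0, 1]")
  rw <- object@regionWindows
  if (length(rw) > 1) {
    m <- do.call(rbind, rw)
    if (any(m[, 2] <= m[, 1])) msg <- c(msg, "each region window needs hi > lo")
    if (any(m[-1, 1] < m[-nrow(m), 2]))
      msg <- c(msg, "region windows must be disjoint and ordered along arc length")
  }
  if (object@span > 200)
    msg <- c(msg, "arc length exceeds the acquisition span (<= 200 mm)")
  if (nrow(object@centerlinePts) != length(object@zGrid) ||
      nrow(object@catheterOffset) != length(object@zGrid) ||
      length(object@radius) != length(object@zGrid))
    msg <- c(msg, "profile grids are inconsistent")
  if (length(msg)) msg else TRUE
})

#' One rotational polar B-scan
#'
#' Backscatter intensity of one full catheter rotation, indexed by
#' (A-line angle, depth). A-line `k` (1-based) points along
#' `theta = 2*pi*(k-1)/nAlines`, measured counter-clockwise from +x.
#'
#' @slot intensity `nAlines x depthPixels` non-negative matrix (a.u.).
#' @slot pixelPitch depth sampling (mm/pixel).
#' @slot frameIndex 0-based frame number within the pullback.
#' @slot zNominal nominal pullback position, `frameIndex * frameSpacing` (mm).
#' @slot sectorValid per-A-line flag; `FALSE` where the wall lies beyond the
#'   imaging range (truth-missing sector).
#' @export
setClass("PolarBScan",
  representation(
    intensity = "matrix",
    pixelPitch = "numeric",
    frameIndex = "integer",
    zNominal = "numeric",
    sectorValid = "logical"
  )
)

setValidity("PolarBScan", function(object) {
  msg <- character()
  if (any(object@intensity < 0)) msg <- c(msg, "intensity must be non-negative")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (length(object@sectorValid) != nrow(object@intensity))
    msg <- c(msg, "sectorValid must have one entry per A-line")
  if (length(msg)) msg else TRUE
})

#' A closed lumen contour at one pullback station
#'
#' Ordered polygon of the airway wall in catheter-centered coordinates.
#' Vertices are ordered by strictly increasing A-line angle; `sectorValid`
#' marks vertices actually measured, `extrapolated` marks vertices filled in
#' from neighboring frames or angles.
#'
#' @slot frameIndex 0-based source frame.
#' @slot z arc-length station (mm).
#' @slot vertices n x 2 matrix of (x, y) in mm, catheter at the origin.
#' @slot sectorValid per-vertex measured flag.
#' @slot extrapolated per-vertex fill flag.
#' @slot usable `FALSE` when more than the allowed fraction of sectors was
#'   missing at detection time (quality triage).
#' @export
setClass("LumenContour",
  representation(
    frameIndex = "integer",
    z = "numeric",
    vertices = "matrix",
    sectorValid = "logical",
    extrapolated = "logical",
    usable = "logical"
  )
)

setValidity("LumenContour", function(object) {
  msg <- character()
  n <- nrow(object@vertices)
  if (n < 64) msg <- c(msg, "a lumen contour needs >= 64 vertices")
  if (length(object@sectorValid) != n || length(object@extrapolated) != n)
    msg <- c(msg, "per-vertex flags must match the vertex count")
  th <- atan2(object@vertices[, 2], object@vertices[, 1])
  th <- (th - th[1]) %% (2 * pi)
  if (any(diff(th) <= 0))
    msg <- c(msg, "vertices must be ordered by strictly increasing angle")
  if (length(msg)) msg else TRUE
})

#' Smoothed, arc-length-parameterized catheter path
#'
#' Centerline samples at uniform arc-length stations, optionally carrying a
#' rotation-minimizing orthonormal frame (tangent, normal1, normal2) per
#' station. Frames are attached by [framesAlongCenterline()].
#'
#' @slot samples n x 3 station coordinates (mm).
#' @slot arcLength cumulative arc length at each station (mm).
#' @slot tangent,normal1,normal2 n x 3 frame vectors (may be 0-row before
#'   frames are attached).
#' @slot residualRms smoothing-spline residual RMS (mm).
#' @export
setClass("Centerline",
  representation(
    samples = "matrix",
    arcLength = "numeric",
    tangent = "matrix",
    normal1 = "matrix",
    normal2 = "matrix",
    residualRms = "numeric"
  )
)

setValidity("Centerline", function(object) {
  msg <- character()
  n <- nrow(object@samples)
  if (length(object@arcLength) != n)
    msg <- c(msg, "arcLength must have one entry per sample")
  if (n >= 2 && any(diff(object@arcLength) <= 0))
    msg <- c(msg, "arcLength must be strictly increasing")
  if (nrow(object@tangent) > 0) {
    if (nrow(object@tangent) != n || nrow(object@normal1) != n ||
        nrow(object@normal2) != n)
      msg <- c(msg, "frames must have one triad per station")
  }
  if (length(msg)) msg else TRUE
})

#' Triangulated airway lumen surface
#'
#' Watertight triangle mesh of the lumen wall in anatomical coordinates, with
#' a per-vertex mapping back to the source contour station (0 for cap-center
#' vertices).
#'
#' @slot vertices V x 3 (mm).
#' @slot triangles T x 3 1-based vertex indices, consistently oriented
#'   (outward normals).
#' @slot stationOfVertex integer V, source contour index (0 = cap apex).
#' @export
setClass("AirwaySurface",
  representation(
    vertices = "matrix",
    triangles = "matrix",
    stationOfVertex = "integer"
  )
)

setValidity("AirwaySurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3) msg <- c(msg, "vertices must be V x 3")
  if (ncol(object@triangles) != 3) msg <- c(msg, "triangles must be T x 3")
  if (nrow(object@triangles) > 0) {
    idx <- range(object@triangles)
    if (idx[1] < 1 || idx[2] > nrow(object@vertices))
      msg <- c(msg, "triangle indices out of range")
  }
  if (length(object@stationOfVertex) != nrow(object@vertices))
    msg <- c(msg, "stationOfVertex must have one entry per vertex")
  if (length(msg)) msg else TRUE
})

#' D3Q19 lattice definition
#'
#' The 19-velocity set, its weights, opposite-direction map, lattice speed of
#' sound, and the orthogonal moment matrix used by the multi-relaxation-time
#' (MRT) collision operator.
#'
#' @slot c 19 x 3 integer velocity set.
#' @slot w 19 weights (1/3 rest, 1/18 axis, 1/36 diagonal).
#' @slot opp opposite-direction index (1-based).
#' @slot csSq lattice speed of sound squared (1/3).
#' @slot M,Minv 19 x 19 moment transform and its inverse.
#' @export
setClass("LatticeD3Q19",
  representation(
    c = "matrix",
    w = "numeric",
    opp = "integer",
    csSq = "numeric",
    M = "matrix",
    Minv = "matrix"
  )
)

#' Voxelized flow domain
#'
#' Occupancy grid linking the lattice to physical coordinates. Codes:
#' 0 solid, 1 fluid, 2 inlet, 3 outlet.
#'
#' @slot occupancy integer 3D array.
#' @slot origin physical coordinate of voxel (1,1,1) center (mm).
#' @slot dx lattice spacing (mm).
#' @export
setClass("VoxelLattice",
  representation(
    occupancy = "array",
    origin = "numeric",
    dx = "numeric"
  )
)

setValidity("VoxelLattice", function(object) {
  msg <- character()
  if (length(dim(object@occupancy)) != 3) msg <- c(msg, "occupancy must be 3D")
  if (!all(object@occupancy %in% 0:3)) msg <- c(msg, "occupancy codes must be 0..3")
  if (object@dx <= 0) msg <- c(msg, "dx must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulated flow field
#'
#' Macroscopic density, velocity and pressure on the voxel grid, with the
#' full lattice-to-physical unit conversion recorded. Velocity is stored in
#' lattice units in `ux`/`uy`/`uz`; [velocityField()] returns m/s and
#' [pressureField()] returns Pa via the recorded conversions.
#'
#' @slot rho,ux,uy,uz 3D arrays (lattice units), time-averaged when
#'   `timeAveraged` is `TRUE`; `NA` outside fluid nodes.
#' @slot occupancy the occupancy grid the run used.
#' @slot timeAveraged logical.
#' @slot conversions named list: `dx_mm`, `dt_s`, `u_phys_per_lat` (m/s per
#'   lattice unit), `p_phys_per_lat` (Pa per lattice pressure unit), `tau`,
#'   `nu_lat`, `Re`, `rho_air_kg_m3`, `u_inlet_lat`, `collision`, `mode`.
#' @slot convergence matrix (step, relative velocity change).
#' @slot stepsRun number of time steps executed.
#' @slot status `"converged"`, `"max_steps"` or `"oscillatory"`.
#' @export
setClass("FlowField",
  representation(
    rho = "array",
    ux = "array",
    uy = "array",
    uz = "array",
    occupancy = "array",
    timeAveraged = "logical",
    conversions = "list",
    convergence = "matrix",
    stepsRun = "integer",
    status = "character"
  )
)

#' Per-station obstruction profile
#'
#' Cross-section-averaged pressure at ordered arc-length stations, its first
#' and second axial derivatives, the per-station lumen area, and the site
#' ranking by `|d2p/dz2|`.
#'
#' @slot stations station labels (default `"A"`..`"G"`).
#' @slot z arc-length positions (mm), strictly increasing.
#' @slot pBar section-averaged pressure relative to the first station (Pa).
#' @slot dpDz first axial derivative (Pa/mm).
#' @slot d2pDz2 second axial derivative (Pa/mm^2); `NA` at the ends.
#' @slot area lumen area at each station (mm^2).
#' @slot ranking data.frame of interior stations ordered by descending
#'   `|d2p/dz2|` (columns: station, z, score, pBar, area).
#' @slot dominantSite label of the top-ranked station.
#' @slot noFocalObstruction `TRUE` when the pressure profile is essentially
#'   linear and no site stands out.
#' @export
setClass("ObstructionProfile",
  representation(
    stations = "character",
    z = "numeric",
    pBar = "numeric",
    dpDz = "numeric",
    d2pDz2 = "numeric",
    area = "numeric",
    ranking = "data.frame",
    dominantSite = "character",
    noFocalObstruction = "logical"
  )
)

setValidity("ObstructionProfile", function(object) {
  msg <- character()
  if (any(diff(object@z) <= 0)) msg <- c(msg, "stations must be strictly increasing in z")
  n <- length(object@z)
  if (length(object@stations) != n || length(object@pBar) != n)
    msg <- c(msg, "stations, z and pBar must have equal length")
  if (length(msg)) msg else TRUE
})
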