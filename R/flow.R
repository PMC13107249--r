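# Voxelization of the lumen surface and drivers for the D3Q19 solver:
# `lbmRun()` works in raw lattice units (validation cases), and
# `runSimulation()` adds the physical unit bookkeeping for airway runs.

.edge_key <- function(tri, a, b) {
  lo <- pmin(tri[, a], tri[, b])
  hi <- pmax(tri[, a], tri[, b])
  lo * (2^26) + hi
}

# every undirected edge must be shared by exactly two triangles
.is_watertight <- function(surface) {
  tri <- surface@triangles
  k <- sort(c(.edge_key(tri, 1, 2), .edge_key(tri, 2, 3), .edge_key(tri, 3, 1)))
  r <- rle(k)
  all(r$lengths == 2L)
}

#' Construct a voxel lattice directly
#'
#' Convenience constructor for validation domains built in code.
#'
#' @param occupancy integer 3D array of codes 0 solid, 1 fluid, 2 inlet,
#'   3 outlet.
#' @param origin coordinates of voxel `[1,1,1]` center (mm).
#' @param dx lattice spacing (mm).
#' @return a [VoxelLattice-class].
#' @export
voxelLattice <- function(occupancy, origin = c(0, 0, 0), dx = 1) {
  storage.mode(occupancy) <- "integer"
  new("VoxelLattice", occupancy = occupancy, origin = origin, dx = dx)
}

#' Voxelize a watertight airway surface
#'
#' Marks voxel centers inside the surface as fluid (parity ray casting) and
#' everything else solid, then labels the proximal (minimum-z) fluid slice
#' as inlet and the distal (maximum-z) fluid slice as outlet — the trimmed
#' end planes of the loft. Warns when the narrowest lumen cross-section
#' spans fewer than 10 voxels across.
#'
#' @param surface a watertight [AirwaySurface-class], oriented with the flow
#'   axis along +z (see [loftSurface()] / [groundTruth()] with
#'   `straighten = TRUE`).
#' @param dx lattice spacing (mm).
#' @return a [VoxelLattice-class].
#' @export
voxelize <- function(surface, dx) {
  if (!.is_watertight(surface))
    stop("surface is not watertight (an edge is not shared by exactly 2 triangles)")
  v <- surface@vertices
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  # voxel centers sit half a spacing off the bounding planes, so flat
  # trimmed caps never coincide with a sampling plane
  origin <- lo - dx / 2
  dims <- as.integer(floor((hi - origin) / dx) + 2L)
  inside <- .cpp_voxelize(v, surface@triangles, origin, dx, dims)
  occ <- array(as.integer(inside), dim = dims)
  counts <- apply(occ, 3, sum)
  # full cross-sections only: slices clipped by the end caps (well below
  # their neighbor's count) must not define the inlet/outlet area
  zFluid <- which(counts > 0 & counts >= 0.5 * stats::median(counts[counts > 0]))
  if (length(zFluid)) {
    # drop stray voxels beyond the end planes (parity slivers at the caps)
    drop <- setdiff(seq_along(counts),
      seq.int(zFluid[1], zFluid[length(zFluid)]))
    if (length(drop)) occ[, , drop] <- 0L
    occ[, , zFluid[1]][occ[, , zFluid[1]] == 1L] <- 2L
    occ[, , zFluid[length(zFluid)]][occ[, , zFluid[length(zFluid)]] == 1L] <- 3L
    minDiam <- 2 * sqrt(min(counts[zFluid]) / pi)
    if (minDiam < 10)
      warning(sprintf(
        "narrowest lumen spans only %.1f voxels across; consider dx < %.3g mm",
        minDiam, dx * minDiam / 10))
  }
  new("VoxelLattice", occupancy = occ, origin = origin, dx = dx)
}

.default_conversions <- function(lat, tau, collision, mode) {
  list(dx_mm = lat@dx, dt_s = NA_real_, u_phys_per_lat = 1,
    p_phys_per_lat = 1, tau = tau, nu_lat = (tau - 0.5) / 3,
    Re = NA_real_, rho_air_kg_m3 = NA_real_, u_inlet_lat = NA_real_,
    collision = collision, mode = mode)
}

#' Run the D3Q19 solver in lattice units
#'
#' Low-level driver used by validation cases and by [runSimulation()]:
#' collide (SRT or MRT) + stream with halfway bounce-back at solid links,
#' non-equilibrium bounce-back velocity inlet (plug profile along +z,
#' ramped), fixed-density outlet, optional uniform body force (Guo
#' forcing), and optional periodic axes. Steady mode iterates until the
#' relative velocity-field change over `convInterval` steps drops below
#' `convTol`, then time-averages `avgSteps` steps.
#'
#' @param lat a [VoxelLattice-class].
#' @param collision `"srt"` or `"mrt"`.
#' @param tau relaxation time (> 0.5); for MRT the shear rates are `1/tau`.
#' @param uInlet inlet plug velocity (lattice units).
#' @param rho0 reference (outlet) density.
#' @param bodyForce force density per node (lattice units), length 3.
#' @param periodic logical length 3: periodic x/y/z.
#' @param maxSteps,rampSteps,convTol,convInterval,avgSteps run control.
#' @param oscillatory sinusoidal inflow modulation instead of steady inflow.
#' @param periodSteps,nCycles oscillatory cycle length (steps) and count;
#'   fields are averaged over the final inspiratory half cycle.
#' @param mrtOthers MRT rate for non-hydrodynamic moments.
#' @param fInit optional initial populations (array `c(dims, 19)`).
#' @param returnF also return the final populations (attribute `f`).
#' @param conversions unit-conversion record to attach (default: identity,
#'   lattice units).
#' @return a [FlowField-class].
#' @export
lbmRun <- function(lat, collision = c("srt", "mrt"), tau = 0.8,
                   uInlet = 0, rho0 = 1, bodyForce = c(0, 0, 0),
                   periodic = c(FALSE, FALSE, FALSE),
                   maxSteps = 5000L, rampSteps = 500L,
                   convTol = 1e-6, convInterval = 100L, avgSteps = 500L,
                   oscillatory = FALSE, periodSteps = 2000L, nCycles = 3L,
                   mrtOthers = 1.2, fInit = NULL, returnF = FALSE,
                   conversions = NULL) {
  collision <- match.arg(collision)
  if (tau <= 0.5) stop("tau must exceed 0.5 for stability")
  dims <- dim(lat@occupancy)
  useMatrix <- collision == "mrt"
  A <- matrix(0, 1, 1)
  if (useMatrix) {
    lt <- latticeD3Q19()
    A <- lt@Minv %*% (mrtRates(tau, mrtOthers) * lt@M)
  }
  res <- .cpp_lbm_run(
    as.integer(dims), as.vector(lat@occupancy),
    useMatrix, tau, A, uInlet, rho0, as.numeric(bodyForce),
    as.logical(periodic), as.integer(maxSteps), as.integer(rampSteps),
    convTol, as.integer(convInterval), as.integer(avgSteps),
    oscillatory, as.integer(periodSteps), as.integer(nCycles),
    if (is.null(fInit)) numeric(0) else as.numeric(fInit), returnF)
  if (res$status == "unstable")
    stop("LBM run went unstable (|u| > 0.4 lattice units or NaN) at step ",
      res$steps, "; increase tau (larger dx or lower Re) or reduce the ",
      "inlet velocity / time step")
  if (is.null(conversions))
    conversions <- .default_conversions(lat, tau, collision,
      if (oscillatory) "oscillatory" else "steady")
  conversions$mass_start <- res$mass_start
  conversions$mass_end <- res$mass_end
  conversions$origin_mm <- lat@origin
  field <- new("FlowField",
    rho = array(res$rho, dims), ux = array(res$ux, dims),
    uy = array(res$uy, dims), uz = array(res$uz, dims),
    occupancy = lat@occupancy,
    timeAveraged = res$averaged,
    conversions = conversions,
    convergence = res$convergence,
    stepsRun = as.integer(res$steps),
    status = res$status)
  if (returnF) attr(field, "f") <- array(res$f, c(19, dims))
  field
}

#' Simulate airflow through a voxelized airway
#'
#' Sets the inlet plug velocity so the volumetric flux through the inlet
#' plane equals the requested flow rate, matches the lattice viscosity to
#' the target Reynolds number (desk-scale runs inflate the physical air
#' viscosity; geometric similarity is preserved), and runs the solver. All
#' unit conversions (dx, dt, tau, Reynolds number, velocity and pressure
#' scales) are recorded in the returned field.
#'
#' The Reynolds number uses the inlet hydraulic diameter
#' `D_h = 2 sqrt(A/pi)` and the inlet mean speed. In oscillatory mode the
#' inflow is modulated sinusoidally; the respiratory period (default 5 s)
#' is mapped to `periodSteps` lattice steps and the reported `dt_s` makes
#' the mapping explicit.
#'
#' @param lat a [VoxelLattice-class] with inlet and outlet labeled.
#' @param inflowLpm inlet volumetric flow (L/min), `> 0`.
#' @param mode `"steady"` or `"oscillatory"`.
#' @param collision `"srt"` or `"mrt"`.
#' @param Re target Reynolds number (desk scale: 100-500).
#' @param uLat inlet speed in lattice units (sets the time step).
#' @param periodS respiratory period (s) for oscillatory mode.
#' @param periodSteps lattice steps per respiratory cycle.
#' @param rhoAir air density (kg/m^3) for the pressure scale.
#' @inheritParams lbmRun
#' @param ... passed to [lbmRun()].
#' @return a [FlowField-class] with physical conversions attached.
#' @export
runSimulation <- function(lat, inflowLpm = 9.45,
                          mode = c("steady", "oscillatory"),
                          collision = c("mrt", "srt"),
                          Re = 200, uLat = 0.03, rho0 = 1,
                          maxSteps = 20000L, rampSteps = 1000L,
                          convTol = 1e-6,
                          avgSteps = 500L, periodS = 5,
                          periodSteps = 4000L, nCycles = 3L,
                          rhoAir = 1.204, ...) {
  mode <- match.arg(mode)
  collision <- match.arg(collision)
  if (inflowLpm <= 0) stop("inflow must be positive")
  nInlet <- sum(lat@occupancy == 2L)
  if (nInlet == 0) stop("lattice has no inlet cells")
  areaMm2 <- nInlet * lat@dx^2
  Q <- inflowLpm / 60000                       # m^3/s
  uPhys <- Q / (areaMm2 * 1e-6)                # m/s mean inlet speed
  dh <- 2 * sqrt(areaMm2 / pi)                 # mm
  nuLat <- uLat * (dh / lat@dx) / Re
  tau <- 0.5 + 3 * nuLat
  dt <- uLat * (lat@dx * 1e-3) / uPhys         # s per step
  conv <- list(
    dx_mm = lat@dx, dt_s = dt,
    u_phys_per_lat = uPhys / uLat,
    p_phys_per_lat = rhoAir * (uPhys / uLat)^2,
    tau = tau, nu_lat = nuLat, Re = Re,
    rho_air_kg_m3 = rhoAir, u_inlet_lat = uLat,
    inlet_area_mm2 = areaMm2, flow_lpm = inflowLpm,
    hydraulic_diameter_mm = dh,
    period_s = if (mode == "oscillatory") periodS else NA_real_,
    period_steps = if (mode == "oscillatory") periodSteps else NA_real_,
    collision = collision, mode = mode)
  lbmRun(lat, collision = collision, tau = tau, uInlet = uLat, rho0 = rho0,
    maxSteps = maxSteps, rampSteps = rampSteps,
    convTol = convTol, avgSteps = avgSteps,
    oscillatory = mode == "oscillatory", periodSteps = periodSteps,
    nCycles = nCycles, conversions = conv, ...)
}
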