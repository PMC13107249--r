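# Voxelization and hydrodynamic behavior of the solver.

test_that("voxelized cylinder has the analytic per-slice fluid count", {
  z <- seq(0, 20, by = 1)
  surf <- tubeSurface(function(z) 5, z, n = 96L)
  lat <- suppressWarnings(voxelize(surf, 1))
  counts <- apply(occupancy(lat) != 0L, 3, sum)
  interior <- counts[counts > 0]
  expect_true(all(abs(interior - pi * 25) <= 3))
  expect_gt(sum(occupancy(lat) == 2L), 0)
  expect_gt(sum(occupancy(lat) == 3L), 0)
})

test_that("voxelized sphere volume is within 5% at r = 10 voxels", {
  R <- 10
  z <- seq(-R, R, by = 0.25)
  rOfZ <- function(z) sqrt(pmax(R^2 - z^2, 1e-4))
  surf <- tubeSurface(rOfZ, z, n = 96L)
  lat <- suppressWarnings(voxelize(surf, 1))
  expect_equal(sum(occupancy(lat) != 0L), 4 / 3 * pi * R^3, tolerance = 0.05)
})

test_that("half-voxel translation changes counts by at most the shell", {
  z <- seq(0, 10, by = 0.5)
  surf <- tubeSurface(function(z) 5.2, z, n = 96L)
  lat1 <- suppressWarnings(voxelize(surf, 1))
  surf2 <- surf
  surf2@vertices <- surf@vertices +
    matrix(c(0.5, 0.5, 0.5), nrow(surf@vertices), 3, byrow = TRUE)
  lat2 <- suppressWarnings(voxelize(surf2, 1))
  n1 <- sum(occupancy(lat1) != 0L)
  n2 <- sum(occupancy(lat2) != 0L)
  occ <- occupancy(lat1)
  d <- dim(occ)
  fluid <- occ != 0L
  shell <- 0L
  for (k in which(fluid)) {
    idx <- arrayInd(k, d)
    nb <- rbind(idx + c(1, 0, 0), idx - c(1, 0, 0), idx + c(0, 1, 0),
      idx - c(0, 1, 0), idx + c(0, 0, 1), idx - c(0, 0, 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
    if (any(!fluid[nb])) shell <- shell + 1L
  }
  expect_lte(abs(n1 - n2), shell)
})

test_that("non-watertight meshes are rejected", {
  z <- seq(0, 5, by = 1)
  surf <- tubeSurface(function(z) 3, z, n = 64L)
  broken <- surf
  broken@triangles <- broken@triangles[-10, ]
  expect_error(voxelize(broken, 1), "watertight")
})

test_that("a perturbed population advects one link per step", {
  lt <- latticeD3Q19()
  d <- c(5L, 5L, 5L)
  occ <- array(1L, d)
  feq0 <- equilibriumD3Q19(1, c(0, 0, 0), lt)
  fArr <- array(rep(as.vector(feq0), each = prod(d)), c(d, 19))
  i <- 12L  # velocity (-1, 0, -1)
  fArr[3, 3, 3, i] <- fArr[3, 3, 3, i] + 1e-3
  fInit <- aperm(fArr, c(4, 1, 2, 3))
  out <- lbmRun(voxelLattice(occ), "srt", tau = 1e9,
    periodic = c(TRUE, TRUE, TRUE), maxSteps = 1L, rampSteps = 0L,
    convInterval = 0L, avgSteps = 0L, fInit = fInit, returnF = TRUE)
  f1 <- aperm(attr(out, "f"), c(2, 3, 4, 1))
  dest <- c(3, 3, 3) + lt@c[i, ]
  expect_gt(f1[dest[1], dest[2], dest[3], i] - feq0[i], 5e-4)
  expect_lt(abs(f1[3, 3, 3, i] - feq0[i]), 1e-10)
})

test_that("closed box conserves mass to near machine precision", {
  d <- c(8L, 8L, 8L)
  occ <- array(1L, d)
  occ[1, , ] <- 0L; occ[d[1], , ] <- 0L
  occ[, 1, ] <- 0L; occ[, d[2], ] <- 0L
  occ[, , 1] <- 0L; occ[, , d[3]] <- 0L
  set.seed(8)
  lt <- latticeD3Q19()
  rho <- runif(prod(d), 0.95, 1.05)
  u <- matrix(runif(prod(d) * 3, -0.02, 0.02), ncol = 3)
  fInit <- aperm(array(as.vector(equilibriumD3Q19(rho, u, lt)),
    c(d, 19)), c(4, 1, 2, 3))
  fl <- lbmRun(voxelLattice(occ), "srt", tau = 0.8, maxSteps = 1000L,
    rampSteps = 0L, convInterval = 0L, avgSteps = 0L, fInit = fInit)
  cv <- conversions(fl)
  expect_lt(abs(cv$mass_end - cv$mass_start) / cv$mass_start, 1e-12)
})

test_that("uniform velocity in a fully periodic box is a steady state", {
  d <- c(6L, 6L, 6L)
  occ <- array(1L, d)
  lt <- latticeD3Q19()
  fInit <- aperm(array(rep(as.vector(equilibriumD3Q19(1,
    c(0.05, 0.02, -0.03), lt)), each = prod(d)), c(d, 19)), c(4, 1, 2, 3))
  fl <- lbmRun(voxelLattice(occ), "srt", tau = 0.8,
    periodic = c(TRUE, TRUE, TRUE), maxSteps = 100L, rampSteps = 0L,
    convInterval = 0L, avgSteps = 0L, fInit = fInit, returnF = TRUE)
  f <- attr(fl, "f")
  expect_lt(max(abs(f - as.vector(fInit))), 1e-12)
})

test_that("body-force channel flow reproduces the parabolic profile", {
  ny <- 23L
  occ <- array(1L, c(3L, ny, 3L))
  occ[, 1, ] <- 0L
  occ[, ny, ] <- 0L
  fl <- lbmRun(voxelLattice(occ), "srt", tau = 0.9,
    bodyForce = c(0, 0, 1e-5), periodic = c(TRUE, FALSE, TRUE),
    maxSteps = 20000L, rampSteps = 0L, convTol = 1e-9, avgSteps = 10L)
  nu <- (0.9 - 0.5) / 3
  H <- ny - 2L
  y <- (1:H) - 0.5
  ana <- 1e-5 / (2 * nu) * y * (H - y)
  num <- fl@uz[2, 2:(ny - 1), 2]
  expect_lt(max(abs(num - ana)) / max(ana), 0.02)
  # mid-link wall velocity extrapolates to zero
  uWall <- (3 * num[1] - num[2]) / 2
  expect_lt(abs(uWall), 1e-3)
})

test_that("MRT and SRT channel flows agree at matched viscosity", {
  ny <- 15L
  occ <- array(1L, c(3L, ny, 3L))
  occ[, 1, ] <- 0L
  occ[, ny, ] <- 0L
  lat <- voxelLattice(occ)
  a <- lbmRun(lat, "srt", tau = 0.8, bodyForce = c(0, 0, 1e-5),
    periodic = c(TRUE, FALSE, TRUE), maxSteps = 12000L, rampSteps = 0L,
    convTol = 1e-9, avgSteps = 10L)
  b <- lbmRun(lat, "mrt", tau = 0.8, bodyForce = c(0, 0, 1e-5),
    periodic = c(TRUE, FALSE, TRUE), maxSteps = 12000L, rampSteps = 0L,
    convTol = 1e-9, avgSteps = 10L)
  ua <- a@uz[2, 8, 2]
  ub <- b@uz[2, 8, 2]
  expect_lt(abs(ua - ub) / ua, 0.01)
})

test_that("constricted tube obeys continuity and inflow sets the mean speed", {
  z <- seq(0, 30, by = 0.5)
  rOfZ <- function(z) 5 - 1.46 * exp(-((z - 15) / 4)^2)  # area halved
  surf <- tubeSurface(rOfZ, z, n = 96L)
  lat <- suppressWarnings(voxelize(surf, 1))
  fl <- lbmRun(lat, "srt", tau = 0.65, uInlet = 0.02, maxSteps = 10000L,
    rampSteps = 300L, convTol = 1e-8, avgSteps = 100L)
  occ <- occupancy(lat)
  zVox <- lat@origin[3] + (seq_len(dim(occ)[3]) - 1L)
  # steady state: mass flux is identical through every cross-section
  flux <- vapply(1:dim(occ)[3], function(k) {
    m <- fl@rho[, , k] * fl@uz[, , k]
    sum(m[occ[, , k] != 0L], na.rm = TRUE)
  }, 0)
  mid <- which(apply(occ != 0L, 3, sum) > 0)
  mid <- mid[3:(length(mid) - 2)]
  expect_lt(max(abs(flux[mid] / stats::median(flux[mid]) - 1)), 1e-6)
  # mean axial velocity scales with the analytic area ratio (continuity)
  kThroat <- mid[which.min(rOfZ(zVox[mid]))]
  kIn <- mid[2]
  uMean <- function(k) flux[k] /
    (mean(fl@rho[, , k][occ[, , k] != 0L], na.rm = TRUE) * pi * rOfZ(zVox[k])^2)
  expect_equal(uMean(kThroat) / uMean(kIn),
    rOfZ(zVox[kIn])^2 / rOfZ(zVox[kThroat])^2, tolerance = 0.05)

  # physical unit bookkeeping: inlet mean speed equals Q / A
  fl2 <- runSimulation(lat, inflowLpm = 9.45, Re = 50, uLat = 0.02,
    collision = "srt", maxSteps = 200L, avgSteps = 0L)
  cv <- conversions(fl2)
  expect_equal(cv$u_phys_per_lat * cv$u_inlet_lat,
    9.45 / 60000 / (cv$inlet_area_mm2 * 1e-6), tolerance = 1e-12)
})

test_that("instability is reported with a diagnostic", {
  z <- seq(0, 10, by = 1)
  surf <- tubeSurface(function(z) 4, z, n = 64L)
  lat <- suppressWarnings(voxelize(surf, 1))
  expect_error(lbmRun(lat, "srt", tau = 0.501, uInlet = 0.25,
    maxSteps = 3000L, rampSteps = 10L), "unstable")
})
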