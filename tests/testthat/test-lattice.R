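# D3Q19 lattice identities, equilibrium, SRT/MRT collisions, and agreement
# between the R reference operators and the compiled kernel.

lt <- latticeD3Q19()

test_that("velocity set satisfies the weight and isotropy identities", {
  expect_equal(sum(lt@w), 1, tolerance = 1e-14)
  expect_lt(max(abs(colSums(lt@w * lt@c))), 1e-14)
  second <- t(lt@c) %*% diag(lt@w) %*% lt@c
  expect_lt(max(abs(second - diag(3) / 3)), 1e-14)
  expect_equal(lt@csSq, 1 / 3)
  # opposite map really negates velocities
  expect_true(all(lt@c[lt@opp, ] == -lt@c))
  # moment basis is orthogonal and invertible
  expect_lt(max(abs(lt@M %*% lt@Minv - diag(19))), 1e-12)
  offDiag <- lt@M %*% t(lt@M)
  expect_lt(max(abs(offDiag[upper.tri(offDiag)])), 1e-10)
})

test_that("equilibrium reproduces weights at rest and conserves moments", {
  expect_equal(as.vector(equilibriumD3Q19(1, c(0, 0, 0), lt)), lt@w,
    tolerance = 1e-15)
  expect_equal(equilibriumD3Q19(1, c(0.1, 0, 0), lt)[1],
    (1 / 3) * (1 - 0.015), tolerance = 1e-15)
  set.seed(2)
  for (k in 1:10) {
    rho <- runif(4, 0.9, 1.1)
    u <- matrix(runif(12, -0.05, 0.05), 4)
    feq <- suppressWarnings(equilibriumD3Q19(rho, u, lt))
    expect_equal(rowSums(feq), rho, tolerance = 1e-14)
    expect_equal(feq %*% lt@c, rho * u, tolerance = 1e-14,
      ignore_attr = TRUE)
  }
  expect_error(equilibriumD3Q19(1, c(0.4, 0, 0), lt), "0.3")
})

test_that("SRT collision conserves mass/momentum with feq fixed point", {
  set.seed(3)
  f <- matrix(abs(rnorm(6 * 19, 1 / 19, 0.005)), 6)
  fp <- collideSRT(f, 0.8, lt)
  expect_equal(rowSums(fp), rowSums(f), tolerance = 1e-13)
  expect_equal(fp %*% lt@c, f %*% lt@c, tolerance = 1e-13)
  mac <- macroscopics(f, lt)
  feq <- equilibriumD3Q19(mac$rho, mac$u, lt)
  expect_equal(collideSRT(feq, 0.7, lt), feq, tolerance = 1e-14)
  expect_equal(collideSRT(f, 1.0, lt), feq, tolerance = 1e-14)
  expect_error(collideSRT(f, 0.5, lt), "0.5")
})

test_that("MRT with equal rates reduces to SRT; rates are validated", {
  set.seed(4)
  f <- matrix(abs(rnorm(8 * 19, 1 / 19, 0.005)), 8)
  for (tau in c(0.6, 0.8, 1.3)) {
    expect_lt(max(abs(collideMRT(f, rep(1 / tau, 19), lt) -
      collideSRT(f, tau, lt))), 1e-12)
  }
  mac <- macroscopics(f, lt)
  feq <- equilibriumD3Q19(mac$rho, mac$u, lt)
  expect_equal(collideMRT(feq, mrtRates(0.7), lt), feq, tolerance = 1e-13)
  fp <- collideMRT(f, mrtRates(0.62), lt)
  expect_equal(rowSums(fp), rowSums(f), tolerance = 1e-13)
  expect_equal(fp %*% lt@c, f %*% lt@c, tolerance = 1e-13)
  expect_error(collideMRT(f, rep(2.5, 19), lt), "\\(0, 2\\)")
  expect_error(collideMRT(f, rep(-0.1, 19), lt), "\\(0, 2\\)")
})

test_that("macroscopics extracts density, velocity and pressure", {
  m <- macroscopics(matrix(lt@w, 1), lt)
  expect_equal(m$rho, 1)
  expect_equal(as.vector(m$u), c(0, 0, 0))
  expect_equal(m$p, 0)
  feq <- equilibriumD3Q19(1.02, c(0, 0, 0), lt)
  expect_equal(macroscopics(feq, lt)$p, 0.02 / 3, tolerance = 1e-14)
  expect_error(macroscopics(matrix(-lt@w, 1), lt), "unstable")
})

test_that("compiled kernel matches the R reference step for SRT and MRT", {
  d <- c(4L, 4L, 4L)
  occ <- array(1L, d)
  set.seed(7)
  u0 <- matrix(runif(prod(d) * 3, -0.03, 0.03), ncol = 3)
  rho0 <- runif(prod(d), 0.95, 1.05)
  f0 <- equilibriumD3Q19(rho0, u0, lt)
  f0 <- f0 * matrix(runif(length(f0), 0.98, 1.02), nrow(f0))  # off-equilibrium
  fArr <- array(as.vector(f0), c(d, 19))
  # note: kernel stores f per cell contiguously; reorder accordingly
  fInit <- aperm(fArr, c(4, 1, 2, 3))
  lat <- voxelLattice(occ)

  out <- lbmRun(lat, "srt", tau = 0.8, periodic = c(TRUE, TRUE, TRUE),
    maxSteps = 1L, rampSteps = 0L, convInterval = 0L, avgSteps = 0L,
    fInit = fInit, returnF = TRUE)
  ref <- refLbmStep(fArr, occ, 0.8, lt)
  got <- aperm(attr(out, "f"), c(2, 3, 4, 1))
  expect_lt(max(abs(got - ref)), 1e-12)

  # with a solid plug in the middle (bounce-back links exercised)
  occ2 <- occ
  occ2[2, 2:3, 2] <- 0L
  f2 <- fInit
  out2 <- lbmRun(voxelLattice(occ2), "srt", tau = 0.7,
    periodic = c(TRUE, TRUE, TRUE), maxSteps = 1L, rampSteps = 0L,
    convInterval = 0L, avgSteps = 0L, fInit = f2, returnF = TRUE)
  ref2 <- refLbmStep(fArr, occ2, 0.7, lt)
  got2 <- aperm(attr(out2, "f"), c(2, 3, 4, 1))
  live <- array(rep(occ2 != 0L, 19), c(dim(occ2), 19))
  expect_lt(max(abs(got2[live] - ref2[live])), 1e-12)
})
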