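# Centerline smoothing, rotation-minimizing frames, lofting, areas, and
# awake/asleep comparison.

test_that("centerline smoothing is exact on noiseless lines and arcs", {
  z <- seq(0, 100, by = 1)
  cl <- smoothCenterline(cbind(0, 0, z), spacing = 0.5)
  expect_lt(cl@residualRms, 1e-9)
  cl <- framesAlongCenterline(cl)
  expect_true(all(abs(cl@tangent[, 3] - 1) < 1e-9))

  # planar arc, radius 50 mm
  th <- seq(0, 2.4, length.out = 200)
  arc <- cbind(50 * sin(th), 0, 50 - 50 * cos(th))
  cla <- smoothCenterline(arc, spacing = 0.5)
  d <- sqrt(cla@samples[, 1]^2 + (cla@samples[, 3] - 50)^2)
  expect_lt(max(abs(d - 50)), 0.05)

  expect_error(smoothCenterline(cbind(0, 0, 1:3)), "4")
})

test_that("noisy straight tracker recovers the line within 0.2 mm", {
  set.seed(3)
  z <- seq(0, 150, by = 0.5)
  s <- cbind(0, 0, z) + matrix(rnorm(3 * length(z), 0, 0.5), ncol = 3)
  cl <- smoothCenterline(s)
  expect_equal(cl@residualRms, 0.5, tolerance = 0.2)
  expect_lt(max(sqrt(cl@samples[, 1]^2 + cl@samples[, 2]^2)), 0.2)
})

test_that("rotation-minimizing frames are orthonormal and twist-free", {
  # straight line: identical frames everywhere
  cl <- straightCenterline(seq(0, 10, by = 0.5))
  expect_true(all(abs(sweep(cl@normal1, 2, cl@normal1[1, ])) < 1e-12))

  # planar arc: the out-of-plane normal never flips and twist < 1 deg/100 mm
  th <- seq(0, 2.0, length.out = 300)
  arc <- smoothCenterline(cbind(80 * sin(th), 0, 80 - 80 * cos(th)),
    spacing = 0.5)
  arc <- framesAlongCenterline(arc)
  outOfPlane <- arc@normal2[, 2] * arc@normal2[1, 2] +
    arc@normal1[, 2] * arc@normal1[1, 2]
  ey <- abs(cbind(arc@normal1[, 2], arc@normal2[, 2]))
  ang <- acos(pmin(1, apply(ey, 1, max)))          # tilt of the frame's
  span <- diff(range(arc@arcLength))               # out-of-plane axis vs y
  expect_lt(max(ang) * 180 / pi, 1 * span / 100)

  # orthogonality at every station, any input
  set.seed(9)
  s <- cbind(cumsum(rnorm(50, 1, .1)), cumsum(rnorm(50, .3, .1)),
    cumsum(rnorm(50, 1, .1)))
  cl2 <- framesAlongCenterline(smoothCenterline(s, spacing = 1))
  expect_lt(max(abs(rowSums(cl2@tangent * cl2@normal1))), 1e-10)
  expect_lt(max(abs(rowSums(cl2@tangent * cl2@normal2))), 1e-10)
  expect_lt(max(abs(rowSums(cl2@normal1 * cl2@normal2))), 1e-10)
})

test_that("lofted cylinders match closed-form volumes, with and without trim", {
  z <- seq(0, 10, by = 0.5)
  contours <- lapply(seq_along(z), function(i)
    circleContour(6, n = 128L, frameIndex = i - 1L, z = z[i]))
  cl <- straightCenterline(z)
  surf <- loftSurface(contours, cl, trim = c(0, 0))
  expect_equal(meshVolume(surf), pi * 36 * 10, tolerance = 0.01)
  expect_identical(attr(surf, "roll_offsets"), integer(length(z)))

  surfT <- loftSurface(contours, cl, trim = c(2, 2))
  expect_equal(meshVolume(surfT), pi * 36 * 6, tolerance = 0.01)

  expect_error(loftSurface(contours[-1], cl), "one contour per")
})

test_that("rigid placement preserves contour area to 1e-9 relative", {
  z <- seq(0, 20, by = 0.5)
  th <- seq(0, 1.0, length.out = 300)
  cl <- framesAlongCenterline(smoothCenterline(
    cbind(60 * sin(th), 0, 60 - 60 * cos(th)), spacing = 0.5))
  n <- nrow(cl@samples)
  set.seed(11)
  contours <- lapply(seq_len(n), function(i)
    circleContour(4 + 0.5 * sin(i / 5), center = c(0.3, -0.2), n = 96L,
      frameIndex = i - 1L, z = cl@arcLength[i]))
  surf <- loftSurface(contours, cl, trim = c(0, 0))
  # re-measure each placed ring in its own frame plane
  for (i in c(1, n %/% 2, n)) {
    rows <- which(surf@stationOfVertex == i)
    v3 <- surf@vertices[rows, ]
    ctr <- cl@samples[i, ]
    v2 <- cbind((v3 - matrix(ctr, length(rows), 3, byrow = TRUE)) %*%
      cl@normal1[i, ],
      (v3 - matrix(ctr, length(rows), 3, byrow = TRUE)) %*% cl@normal2[i, ])
    expect_equal(crossSectionalArea(v2, check = FALSE),
      as.numeric(crossSectionalArea(contours[[i]])), tolerance = 1e-9)
  }
})

test_that("shoelace area matches polygon closed forms", {
  expect_identical(crossSectionalArea(rbind(c(0, 0), c(1, 0), c(1, 1),
    c(0, 1))), 1)
  n <- 2000L
  phi <- 2 * pi * (seq_len(n) - 1) / n
  gon <- cbind(cos(phi), sin(phi))
  expect_equal(crossSectionalArea(gon), (n / 2) * sin(2 * pi / n),
    tolerance = 1e-12)
  expect_equal(crossSectionalArea(gon), pi, tolerance = 1e-4)
  expect_equal(crossSectionalArea(gon[n:1, ]), crossSectionalArea(gon))
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(crossSectionalArea(bowtie), "self-intersecting")
})

test_that("compareStates reports per-region reductions and is antisymmetric", {
  aw <- data.frame(z_mm = 0:10, area_mm2 = rep(100, 11))
  as_ <- data.frame(z_mm = 0:10, area_mm2 = rep(44, 11))
  w <- list(region = c(0, 10))
  expect_equal(compareStates(aw, as_, w)$reduction_pct, 56)
  expect_equal(compareStates(aw, aw, w)$reduction_pct, 0)
  expect_error(compareStates(aw, as_, list(r = c(20, 30))), "no stations")

  set.seed(5)
  a <- data.frame(z_mm = 0:20, area_mm2 = runif(21, 50, 150))
  b <- data.frame(z_mm = 0:20, area_mm2 = runif(21, 50, 150))
  w2 <- list(r1 = c(0, 8), r2 = c(9, 20))
  rab <- compareStates(a, b, w2)$reduction_pct
  rba <- compareStates(b, a, w2)$reduction_pct
  expect_equal(rab, 100 - 100^2 / (100 - rba), tolerance = 1e-9)

  # different station grids are resampled onto the awake grid
  b2 <- data.frame(z_mm = seq(0, 20, by = 0.25),
    area_mm2 = approx(b$z_mm, b$area_mm2, seq(0, 20, by = 0.25))$y)
  expect_equal(compareStates(a, b2, w2)$reduction_pct, rab, tolerance = 1e-9)
})

test_that("lofted phantom volume matches the area integral within 3%", {
  g <- deskGeometry()
  ph <- makePhantom("asleep", 0)
  gt <- groundTruth(ph, g, nVertices = 96)
  zMid <- seq(0.25, 149.75, by = 0.5)
  expect_equal(meshVolume(gt$surface), sum(phantomArea(ph, zMid)) * 0.5,
    tolerance = 0.03)
})
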