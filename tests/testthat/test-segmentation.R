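# Lumen-wall detection, contour assembly, and missing-sector filling.

test_that("first-crossing detector finds the wall edge and reports missing", {
  pitch <- 0.025
  aline <- rep(0, 512)
  aline[(round(4 / pitch) + 1):(round(4.5 / pitch) + 1)] <- 1
  d <- detectWall(aline, list(mean = 0, sd = 0.001), exclusionMm = 1.3,
    pixelPitch = pitch)
  expect_equal(d, 4.0, tolerance = pitch)

  set.seed(1)
  noiseOnly <- abs(rnorm(512, 0, 0.02))
  expect_true(is.na(detectWall(noiseOnly, list(mean = 0.016, sd = 0.012),
    1.3, pitch)))

  # short bursts above threshold do not qualify as a wall
  burst <- rep(0, 512)
  burst[200:202] <- 1
  expect_true(is.na(detectWall(burst, list(mean = 0, sd = 0.001), 1.3, pitch)))

  expect_error(detectWall(aline, list(mean = 0, sd = 0), 20, pitch),
    "exclusion")
})

test_that("per-angle wall depths match analytic radii on a speckled frame", {
  g <- deskGeometry(nA = 360L)
  ph <- makePhantom("asleep", 0, span = 150)
  f <- maskSheathArtifact(renderBScan(ph, g, 87, seed = 5))
  ns <- noiseStats(f)
  depths <- vapply(seq_len(360), function(k)
    detectWall(intensity(f)[k, ], ns, 1.3, f@pixelPitch), 0)
  theta <- 2 * pi * (0:359) / 360
  truth <- airwayflow:::.wall_distance(cbind(cos(theta), sin(theta)),
    -phantomOffset(ph, 87)[1, ], phantomRadius(ph, 87))
  expect_gte(mean(abs(depths - truth) <= f@pixelPitch), 0.99)
})

test_that("contours recover circles, eccentricity, and flag missing sectors", {
  g <- deskGeometry(nA = 360L)
  ph <- makePhantom("awake", 0, span = 10, baseRadius = 4,
    offsetAmplitude = 0, curved = FALSE)
  ct <- contourFromFrame(maskSheathArtifact(renderBScan(ph, g, 5, seed = 2)))
  r <- sqrt(rowSums(vertices(ct)^2))
  expect_true(all(abs(r - 4) <= 2 * pixelPitch(g)))
  expect_true(ct@usable)
  expect_equal(crossSectionalArea(ct), pi * 16, tolerance = 0.02,
    ignore_attr = TRUE)

  # eccentric catheter: polygon centroid sits at minus the offset
  ph2 <- makePhantom("awake", 0, span = 10, baseRadius = 4,
    offsetAmplitude = 1, curved = FALSE)
  off <- phantomOffset(ph2, 5)[1, ]
  ct2 <- contourFromFrame(maskSheathArtifact(renderBScan(ph2, g, 5, seed = 2)))
  r2 <- sqrt(rowSums(vertices(ct2)^2))
  expect_true(max(r2) <= 4 + sqrt(sum(off^2)) + 0.1)
  expect_true(min(r2) >= 4 - sqrt(sum(off^2)) - 0.1)
  expect_equal(polyCentroid(vertices(ct2)), -off, tolerance = 0.05,
    ignore_attr = TRUE)

  # out-of-range sector: flagged invalid, remaining vertices accurate
  ph3 <- makePhantom("awake", 0, span = 10, baseRadius = 12.2,
    offsetAmplitude = 1, curved = FALSE)
  f3 <- maskSheathArtifact(renderBScan(ph3, g, 5, seed = 2))
  ct3 <- contourFromFrame(f3)
  expect_true(any(!ct3@sectorValid))
  expect_true(all(!ct3@sectorValid[!sectorValid(f3)]))
  ok <- ct3@sectorValid
  truthR <- airwayflow:::.wall_distance(
    cbind(cos(2 * pi * (0:359) / 360), sin(2 * pi * (0:359) / 360)),
    -phantomOffset(ph3, 5)[1, ], 12.2)
  expect_lt(stats::median(abs(sqrt(rowSums(vertices(ct3)[ok, ]^2)) -
    truthR[ok])), 2 * pixelPitch(g))
})

test_that("quality triage flags contours with too many missing sectors", {
  g <- deskGeometry(nA = 360L)
  ph <- makePhantom("awake", 0, span = 10, baseRadius = 14,
    offsetAmplitude = 0, curved = FALSE)  # everything out of range
  ct <- contourFromFrame(maskSheathArtifact(renderBScan(ph, g, 5, seed = 2)))
  expect_false(ct@usable)
})

test_that("missing sectors fill from neighbor frames, then angles", {
  n <- 64L
  cts <- list(circleContour(5, n = n, frameIndex = 0L, z = 0),
              circleContour(5, n = n, frameIndex = 1L, z = 0.5),
              circleContour(5, n = n, frameIndex = 2L, z = 1))
  bad <- 10:17
  cts[[2]]@sectorValid[bad] <- FALSE
  cts[[2]]@vertices[bad, ] <- cts[[2]]@vertices[bad, ] * 0.5  # corrupt
  out <- fillMissingSectors(cts)
  rFilled <- sqrt(rowSums(out[[2]]@vertices^2))
  expect_equal(rFilled[bad], rep(5, length(bad)), tolerance = 1e-12)
  expect_true(all(out[[2]]@extrapolated[bad]))
  # valid vertices of every frame are untouched (exact equality)
  expect_identical(out[[1]]@vertices, cts[[1]]@vertices)
  expect_identical(out[[2]]@vertices[-bad, ], cts[[2]]@vertices[-bad, ])

  # midpoint interpolation between radii 4 and 6
  cts2 <- list(circleContour(4, n = n, frameIndex = 0L),
               circleContour(1, n = n, frameIndex = 1L),
               circleContour(6, n = n, frameIndex = 2L))
  cts2[[2]]@sectorValid[] <- FALSE
  cts2[[2]]@sectorValid[1:40] <- TRUE
  out2 <- fillMissingSectors(cts2)
  r2 <- sqrt(rowSums(out2[[2]]@vertices^2))
  expect_equal(r2[41:64], rep(5, 24), tolerance = 1e-12)

  # fully missing beyond the search limit errors with frame indices
  cts3 <- lapply(0:2, function(i) circleContour(5, n = n, frameIndex = i))
  cts3[[2]]@sectorValid[] <- FALSE
  expect_error(fillMissingSectors(cts3, searchLimit = 0L), "frame indices: 1")

  expect_error(fillMissingSectors(list(circleContour(5, n = 64L),
    circleContour(5, n = 128L))), "vertex count")
})

test_that("filled areas track truth within 3% when a sector is range-clipped", {
  g <- deskGeometry(nA = 180L)
  ph <- makePhantom("awake", 0, span = 6, baseRadius = 11.9,
    offsetAmplitude = 1, curved = FALSE)
  pull <- simulatePullback(ph, g, seed = 4)
  cts <- lapply(pull$stack, function(f) contourFromFrame(maskSheathArtifact(f)))
  cts <- fillMissingSectors(cts)
  areas <- vapply(cts, function(ct) as.numeric(crossSectionalArea(ct)), 0)
  truth <- phantomArea(ph, pull$z)
  expect_true(all(abs(areas / truth - 1) < 0.03))
  expect_true(any(vapply(cts, function(ct) any(ct@extrapolated), TRUE)))
})

test_that("contour area is invariant under rotation of the start index", {
  ct <- circleContour(3, center = c(0.7, -0.2), n = 128L)
  a0 <- crossSectionalArea(ct)
  v <- vertices(ct)
  rot <- rbind(v[40:128, ], v[1:39, ])
  expect_equal(crossSectionalArea(rot), as.numeric(a0), tolerance = 1e-12)
})
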