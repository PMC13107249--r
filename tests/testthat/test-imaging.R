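# Post-processing: polar/Cartesian conversion, artifact masking, alignment.

mkFrame <- function(img, pitch = 0.05, frameIndex = 0L) {
  new("PolarBScan", intensity = img, pixelPitch = pitch,
    frameIndex = frameIndex, zNominal = frameIndex * 0.5,
    sectorValid = rep(TRUE, nrow(img)))
}

test_that("polar to Cartesian maps (theta, d) to (d cos, d sin)", {
  nA <- 64L
  nD <- 128L
  img <- matrix(0, nA, nD)
  img[1, round(4 / 0.05) + 1] <- 1          # theta = 0, d = 4 mm
  out <- polarToCartesian(mkFrame(img), 0.05)
  ctr <- attr(out, "center")
  pk <- which(out == max(out), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric((pk - ctr) * 0.05), c(4, 0), tolerance = 0.06)

  img2 <- matrix(0, nA, nD)
  img2[nA / 4 + 1, round(2 / 0.05) + 1] <- 1  # theta = pi/2, d = 2 mm
  out2 <- polarToCartesian(mkFrame(img2), 0.05)
  pk2 <- which(out2 == max(out2), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric((pk2 - ctr) * 0.05), c(0, 2), tolerance = 0.06)

  expect_error(polarToCartesian(mkFrame(img), -1), "positive")
})

test_that("polar -> Cartesian -> polar round trip is interpolation-stable", {
  g <- deskGeometry()
  ph <- makePhantom("awake", 0, span = 10, baseRadius = 4, curved = FALSE)
  f <- renderBScan(ph, g, 5, sheath = TRUE, speckle = FALSE)
  cart <- polarToCartesian(f, 0.04)
  back <- cartesianToPolar(cart, nAlines = nrow(intensity(f)),
    depthPixels = ncol(intensity(f)), pixelPitch = f@pixelPitch)
  expect_gte(stats::cor(as.vector(back), as.vector(intensity(f))), 0.98)
})

test_that("sheath masking changes only the band and preserves wall detection", {
  g <- deskGeometry()
  ph <- makePhantom("awake", 0, span = 10, baseRadius = 4, curved = FALSE)
  f <- renderBScan(ph, g, 5, sheath = TRUE, sheathRadius = 0.9)
  fm <- maskSheathArtifact(f, c(0.7, 1.1))
  depth <- (seq_len(ncol(intensity(f))) - 1L) * f@pixelPitch
  outside <- depth < 0.7 | depth > 1.1
  expect_identical(intensity(fm)[, outside], intensity(f)[, outside])
  expect_lt(max(intensity(fm)[, !outside]), max(intensity(f)[, !outside]))

  # wall depths after masking match detection on an artifact-free render
  fClean <- renderBScan(ph, g, 5, sheath = FALSE)
  dMasked <- airwayflow:::.wall_signature(fm)
  dClean <- airwayflow:::.wall_signature(fClean)
  expect_true(all(abs(dMasked - dClean) <= f@pixelPitch + 1e-12))

  expect_error(maskSheathArtifact(f, c(1.1, 0.7)), "r_min")
})

test_that("alignment recovers injected rotations and is inverse-consistent", {
  g <- deskGeometry(nA = 360L)
  ph <- makePhantom("awake", 0, span = 5, baseRadius = 4, curved = FALSE,
    offsetAmplitude = 0.8)
  # same-station frames with independent speckle: structurally identical up
  # to rotation, so the recovered offsets have a known truth
  stack <- lapply(0:2, function(i) {
    f <- renderBScan(ph, g, 2.5, seed = 10 + i)
    f@frameIndex <- i
    f
  })

  # no injected rotation: offsets within one angular step
  al0 <- alignFrames(stack)
  expect_true(all(abs(al0$offsets) <= 1))

  # rotate the second frame by 90 degrees (90 A-lines of 360)
  rot <- stack
  rot[[2]]@intensity <- airwayflow:::.rotate_rows(rot[[2]]@intensity, 90L)
  rot[[2]]@sectorValid <- rep(TRUE, 360)
  al <- alignFrames(rot)
  expect_lte(abs(al$offsets[2] - 90L), 2L)
  # cumulative rotation is undone for the following frame as well
  expect_lte(abs(al$cumulative[3]), 2L)
  # the reported cumulative rotation is exactly what was applied
  expect_identical(al$stack[[2]]@intensity,
    airwayflow:::.rotate_rows(rot[[2]]@intensity, -al$cumulative[2]))

  # inverse consistency on the frame pair
  s1 <- airwayflow:::.wall_signature(rot[[1]])
  s2 <- airwayflow:::.wall_signature(rot[[2]])
  o12 <- airwayflow:::.circular_shift(s1, s2)
  o21 <- airwayflow:::.circular_shift(s2, s1)
  expect_lte(abs(o12 + o21) %% 360L, 2L)

  # dimensions and metadata preserved
  expect_identical(dim(al$stack[[2]]@intensity), dim(stack[[2]]@intensity))
  expect_identical(al$stack[[2]]@frameIndex, stack[[2]]@frameIndex)

  # single frame: identity
  al1 <- alignFrames(stack[1])
  expect_identical(al1$offsets, 0L)
})
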