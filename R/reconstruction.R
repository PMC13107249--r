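# Curved 3D reconstruction: tracker-path smoothing, rotation-minimizing
# frames, contour lofting into a watertight surface, per-station areas and
# awake/asleep comparison.

#' Smooth and resample the tracked catheter path
#'
#' Fits a smoothing spline per coordinate against (chord) arc length,
#' resamples the fitted curve at uniform arc-length spacing, and reports the
#' residual RMS of the fit.
#'
#' @param samples tracker samples: an n x 3 matrix or a data.frame with
#'   columns `x_mm`, `y_mm`, `z_mm` (n >= 4).
#' @param spacing resampling spacing (mm).
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default is generalized cross-validation.
#' @return a [Centerline-class] without frames (see
#'   [framesAlongCenterline()]).
#' @export
smoothCenterline <- function(samples, spacing = 0.5, spar = NULL) {
  if (is.data.frame(samples))
    samples <- as.matrix(samples[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(samples) < 4) stop("need at least 4 tracker samples")
  t0 <- c(0, cumsum(sqrt(rowSums(diff(samples)^2))))
  fits <- lapply(1:3, function(j) {
    if (is.null(spar)) stats::smooth.spline(t0, samples[, j])
    else stats::smooth.spline(t0, samples[, j], spar = spar)
  })
  resid <- vapply(1:3, function(j)
    samples[, j] - stats::predict(fits[[j]], t0)$y, numeric(nrow(samples)))
  rms <- sqrt(mean(resid^2))
  tFine <- seq(0, max(t0), length.out = max(2000L, 10L * nrow(samples)))
  pFine <- vapply(fits, function(f) stats::predict(f, tFine)$y, tFine)
  sFine <- c(0, cumsum(sqrt(rowSums(diff(pFine)^2))))
  L <- max(sFine)
  sOut <- seq(0, L, by = spacing)
  pts <- vapply(1:3, function(j) stats::approx(sFine, pFine[, j], sOut)$y,
    sOut)
  new("Centerline",
    samples = pts, arcLength = sOut,
    tangent = matrix(0, 0, 3), normal1 = matrix(0, 0, 3),
    normal2 = matrix(0, 0, 3), residualRms = rms)
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length tangent encountered")
  v / n
}

#' Attach rotation-minimizing frames to a centerline
#'
#' Computes per-station orthonormal triads (tangent, normal1, normal2) by
#' the double-reflection method, which transports the normal along the curve
#' without spurious twist (unlike the Frenet frame). The first normal is the
#' projection of the world x-axis onto the first normal plane (y-axis
#' fallback when the tangent is nearly parallel to x).
#'
#' @param centerline a [Centerline-class] from [smoothCenterline()].
#' @return the centerline with `tangent`, `normal1`, `normal2` filled.
#' @export
framesAlongCenterline <- function(centerline) {
  p <- centerline@samples
  n <- nrow(p)
  if (n < 2) stop("need at least 2 stations")
  tg <- matrix(0, n, 3)
  tg[1, ] <- .normalize(p[2, ] - p[1, ])
  tg[n, ] <- .normalize(p[n, ] - p[n - 1, ])
  if (n > 2)
    for (i in 2:(n - 1)) tg[i, ] <- .normalize(p[i + 1, ] - p[i - 1, ])
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tg[1, ])) > 0.99) ref <- c(0, 1, 0)
  n1 <- matrix(0, n, 3)
  n1[1, ] <- .normalize(ref - sum(ref * tg[1, ]) * tg[1, ])
  for (i in seq_len(n - 1)) {
    v1 <- p[i + 1, ] - p[i, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-20) stop("coincident centerline stations")
    rL <- n1[i, ] - (2 / c1) * sum(v1 * n1[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1, ] - tL
    c2 <- sum(v2^2)
    n1[i + 1, ] <- if (c2 < 1e-20) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # guard against drift out of the normal plane
    n1[i + 1, ] <- .normalize(n1[i + 1, ] -
      sum(n1[i + 1, ] * tg[i + 1, ]) * tg[i + 1, ])
  }
  n2 <- cbind(
    tg[, 2] * n1[, 3] - tg[, 3] * n1[, 2],
    tg[, 3] * n1[, 1] - tg[, 1] * n1[, 3],
    tg[, 1] * n1[, 2] - tg[, 2] * n1[, 1]
  )
  centerline@tangent <- tg
  centerline@normal1 <- n1
  centerline@normal2 <- n2
  centerline
}

# Cyclic shift of contour-2 vertex indices minimizing the summed squared
# vertex distance to contour 1 (both as complex planar coordinates).
.roll_shift <- function(v1, v2) {
  z1 <- complex(real = v1[, 1], imaginary = v1[, 2])
  z2 <- complex(real = v2[, 1], imaginary = v2[, 2])
  n <- length(z1)
  cc <- Re(stats::fft(Conj(stats::fft(z1)) * stats::fft(z2), inverse = TRUE)) / n
  which.max(cc) - 1L
}

#' Loft lumen contours along a centerline into a watertight surface
#'
#' Each contour is placed rigidly in its station's normal plane with the
#' catheter center at the centerline point, roll-registered to the previous
#' station by the cyclic vertex shift minimizing summed vertex distance,
#' stitched to its neighbor with triangle strips, and the two ends are
#' capped with triangle fans. `trim` drops the stated arc length from each
#' end before lofting. Rigid placement preserves every contour's area
#' exactly.
#'
#' @param contours list of [LumenContour-class], one per centerline station,
#'   all with the same vertex count.
#' @param centerline a [Centerline-class] with frames attached; must have as
#'   many stations as there are contours.
#' @param trim `c(proximal_mm, distal_mm)` arc length removed from the ends.
#' @return an [AirwaySurface-class] (watertight, outward-oriented).
#' @export
loftSurface <- function(contours, centerline, trim = c(5, 5)) {
  if (nrow(centerline@tangent) == 0)
    centerline <- framesAlongCenterline(centerline)
  nS <- length(contours)
  if (nS != nrow(centerline@samples))
    stop("need one contour per centerline station (",
      nS, " contours vs ", nrow(centerline@samples), " stations)")
  nV <- nrow(contours[[1]]@vertices)
  if (any(vapply(contours, function(ct) nrow(ct@vertices), 0L) != nV))
    stop("contour vertex counts differ")
  s <- centerline@arcLength
  keep <- which(s >= s[1] + trim[1] & s <= s[length(s)] - trim[2])
  if (length(keep) < 2) stop("trim leaves fewer than 2 stations")
  contours <- contours[keep]
  nS <- length(keep)
  ctr <- centerline@samples[keep, , drop = FALSE]
  n1 <- centerline@normal1[keep, , drop = FALSE]
  n2 <- centerline@normal2[keep, , drop = FALSE]
  tg <- centerline@tangent[keep, , drop = FALSE]

  # roll registration in the 2D contour plane, propagated cumulatively
  rolls <- integer(nS)
  vPrev <- contours[[1]]@vertices
  local2d <- vector("list", nS)
  local2d[[1]] <- vPrev
  for (i in seq_len(nS)[-1]) {
    v <- contours[[i]]@vertices
    sft <- .roll_shift(vPrev, v)
    if (sft != 0)
      v <- v[((seq_len(nV) - 1L + sft) %% nV) + 1L, , drop = FALSE]
    rolls[i] <- sft
    local2d[[i]] <- v
    vPrev <- v
  }

  # warn about section planes crossing inside the lumen on tight bends
  maxR <- vapply(local2d, function(v) max(sqrt(rowSums(v^2))), 0)
  if (nS > 2) {
    ang <- acos(pmin(1, rowSums(tg[-nS, ] * tg[-1, ])))
    ds <- diff(s[keep])
    bad <- which(maxR[-nS] * ang > ds)
    if (length(bad))
      warning("section planes may cross inside the lumen near stations: ",
        paste(utils::head(bad, 10), collapse = ", "))
  }

  verts <- matrix(0, nS * nV + 2L, 3)
  stationOf <- integer(nS * nV + 2L)
  for (i in seq_len(nS)) {
    v <- local2d[[i]]
    rows <- (i - 1L) * nV + seq_len(nV)
    verts[rows, ] <- matrix(ctr[i, ], nV, 3, byrow = TRUE) +
      v[, 1] %o% n1[i, ] + v[, 2] %o% n2[i, ]
    stationOf[rows] <- i
  }
  capP <- nS * nV + 1L
  capD <- nS * nV + 2L
  verts[capP, ] <- colMeans(verts[seq_len(nV), , drop = FALSE])
  verts[capD, ] <- colMeans(verts[(nS - 1L) * nV + seq_len(nV), , drop = FALSE])

  k <- seq_len(nV)
  kn <- c(seq_len(nV)[-1], 1L)
  tris <- vector("list", nS + 1L)
  for (i in seq_len(nS - 1L)) {
    a <- (i - 1L) * nV
    b <- i * nV
    tris[[i]] <- rbind(
      cbind(a + k, a + kn, b + kn),
      cbind(a + k, b + kn, b + k)
    )
  }
  tris[[nS]] <- cbind(capP, kn, k)                     # proximal cap
  tris[[nS + 1L]] <- cbind(capD, (nS - 1L) * nV + k, (nS - 1L) * nV + kn)
  tri <- do.call(rbind, tris)

  surf <- new("AirwaySurface",
    vertices = verts, triangles = tri, stationOfVertex = stationOf)
  if (.signed_volume(surf) < 0)
    surf@triangles <- surf@triangles[, c(1, 3, 2)]
  attr(surf, "roll_offsets") <- rolls
  surf
}

.signed_volume <- function(surface) {
  v <- surface@vertices
  t <- surface@triangles
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Volume enclosed by a watertight surface
#'
#' Divergence-theorem volume integral over the triangle mesh.
#'
#' @param surface an [AirwaySurface-class].
#' @return volume in mm^3.
#' @export
meshVolume <- function(surface) abs(.signed_volume(surface))

# TRUE when the polygon is simple; cheap star-shaped test first, full
# segment-pair test only as fallback.
.is_simple_polygon <- function(v) {
  ctr <- colMeans(v)
  th <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  th <- (th - th[1]) %% (2 * pi)
  d <- diff(th)
  if (all(d > 0) || all(d < 0)) return(TRUE)
  n <- nrow(v)
  if (n > 2048) return(TRUE)  # angle-ordered contours never reach here
  a <- v
  b <- v[c(2:n, 1), ]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      if (.segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Cross-sectional area of a closed contour
#'
#' Shoelace area of the vertex polygon (absolute value, so vertex order
#' does not matter). For a [LumenContour-class] the returned value carries a
#' `pct_extrapolated` attribute with the percentage of extrapolated
#' vertices, so downstream area reports stay traceable.
#'
#' @param contour a [LumenContour-class] or an n x 2 vertex matrix.
#' @param check verify the polygon is simple (error if self-intersecting).
#' @return area in mm^2.
#' @examples
#' crossSectionalArea(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
crossSectionalArea <- function(contour, check = TRUE) {
  v <- if (is(contour, "LumenContour")) contour@vertices else as.matrix(contour)
  if (check && !.is_simple_polygon(v)) stop("polygon is self-intersecting")
  n <- nrow(v)
  j <- c(2:n, 1)
  a <- abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  if (is(contour, "LumenContour"))
    attr(a, "pct_extrapolated") <- 100 * mean(contour@extrapolated)
  a
}

#' Per-region percent area reduction between awake and asleep states
#'
#' Computes, for each named region window, `100 * (1 - mean asleep area /
#' mean awake area)` using station means within the window. Profiles on
#' different station grids are resampled onto the awake grid first.
#' Negative values (expansion) are allowed and reported.
#'
#' @param areasAwake,areasAsleep data.frames with columns `z_mm`,
#'   `area_mm2`.
#' @param regionWindows named list of `c(lo, hi)` arc-length windows (mm).
#' @return data.frame with columns `region`, `lo_mm`, `hi_mm`,
#'   `mean_awake_mm2`, `mean_asleep_mm2`, `reduction_pct`.
#' @examples
#' aw <- data.frame(z_mm = 0:10, area_mm2 = 100)
#' as <- data.frame(z_mm = 0:10, area_mm2 = 44)
#' compareStates(aw, as, list(region = c(0, 10)))$reduction_pct  # 56
#' @export
compareStates <- function(areasAwake, areasAsleep, regionWindows) {
  z <- areasAwake$z_mm
  aw <- areasAwake$area_mm2
  as_ <- if (isTRUE(all.equal(z, areasAsleep$z_mm))) areasAsleep$area_mm2
  else stats::approx(areasAsleep$z_mm, areasAsleep$area_mm2, z, rule = 2)$y
  res <- lapply(names(regionWindows), function(nm) {
    w <- regionWindows[[nm]]
    i <- which(z >= w[1] & z <= w[2])
    if (!length(i)) stop("region window '", nm, "' contains no stations")
    mW <- mean(aw[i])
    mS <- mean(as_[i])
    data.frame(region = nm, lo_mm = w[1], hi_mm = w[2],
      mean_awake_mm2 = mW, mean_asleep_mm2 = mS,
      reduction_pct = 100 * (1 - mS / mW))
  })
  do.call(rbind, res)
}
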