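# Shared fixtures: a coarse desk-scale acquisition geometry, small analytic
# phantoms, contour/mesh builders, and a plain-R reference LBM step used as
# the independent oracle for the compiled kernel.

deskGeometry <- function(nA = 128L, nD = 256L) {
  acquisitionGeometry(alinesPerFrame = nA, depthPixels = nD)
}

# circular contour of radius r centered at `center` relative to the catheter
circleContour <- function(r, center = c(0, 0), n = 128L, frameIndex = 0L,
                          z = 0) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  new("LumenContour", frameIndex = as.integer(frameIndex), z = z,
    vertices = cbind(center[1] + r * cos(phi), center[2] + r * sin(phi)),
    sectorValid = rep(TRUE, n), extrapolated = rep(FALSE, n), usable = TRUE)
}

straightCenterline <- function(z) {
  framesAlongCenterline(new("Centerline",
    samples = cbind(0, 0, z), arcLength = z,
    tangent = matrix(0, 0, 3), normal1 = matrix(0, 0, 3),
    normal2 = matrix(0, 0, 3), residualRms = 0))
}

# tube mesh with a radius profile r(z), lofted on a straight axis
tubeSurface <- function(rOfZ, z, n = 96L) {
  contours <- lapply(seq_along(z), function(i)
    circleContour(rOfZ(z[i]), n = n, frameIndex = i - 1L, z = z[i]))
  loftSurface(contours, straightCenterline(z), trim = c(0, 0))
}

# polygon area centroid (for eccentricity checks)
polyCentroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

# ---- plain-R D3Q19 reference step (independent of the compiled kernel) ----

refStreamBounceBack <- function(fArr, occ, lattice, periodic) {
  d <- dim(occ)
  out <- fArr
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (occ[x, y, z] == 0L) next
    for (i in 1:19) {
      s <- c(x, y, z) - lattice@c[i, ]
      okDim <- s >= 1 & s <= d
      if (!all(okDim)) {
        if (all(periodic[!okDim])) s <- ((s - 1) %% d) + 1
        else {
          out[x, y, z, i] <- fArr[x, y, z, lattice@opp[i]]
          next
        }
      }
      if (occ[s[1], s[2], s[3]] == 0L)
        out[x, y, z, i] <- fArr[x, y, z, lattice@opp[i]]
      else
        out[x, y, z, i] <- fArr[s[1], s[2], s[3], i]
    }
  }
  out
}

refLbmStep <- function(fArr, occ, tau, lattice, periodic = c(TRUE, TRUE, TRUE)) {
  d <- dim(occ)
  fm <- matrix(fArr, ncol = 19)
  live <- as.vector(occ) != 0L
  fm[live, ] <- collideSRT(fm[live, , drop = FALSE], tau, lattice)
  refStreamBounceBack(array(fm, c(d, 19)), occ, lattice, periodic)
}
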