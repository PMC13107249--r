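# Reduction of the flow solution to the obstruction statistic:
# cross-section-averaged pressure at stations along the airway, its first
# and second axial derivatives, and a ranked list of obstruction sites.

#' Cross-section-averaged pressure at arc-length stations
#'
#' Averages the (time-averaged) pressure over the fluid voxels of a slab of
#' thickness `dx` centered on each station plane, and reports it relative
#' to the first station (the "pressure difference" convention; derivatives
#' are offset-invariant, so the reference is harmless). Stations falling in
#' a fully occluded slab get `NA` with a warning and are skipped by the
#' derivative stencils.
#'
#' @param field a [FlowField-class] from a straight-axis airway run (flow
#'   along +z, z equal to arc length).
#' @param stations either a station count (equally spaced across the fluid
#'   extent, default 7, labeled A..G) or a numeric vector of z positions
#'   (mm).
#' @param labels optional station labels.
#' @return data.frame with columns `station`, `z_mm`, `p_bar_pa`,
#'   `area_mm2`.
#' @export
stationPressures <- function(field, stations = 7L, labels = NULL) {
  occ <- field@occupancy
  dx <- field@conversions$dx_mm
  origin <- field@conversions$origin_mm
  if (is.null(origin)) origin <- c(0, 0, 0)
  zVox <- origin[3] + (seq_len(dim(occ)[3]) - 1L) * dx
  fluidSlice <- apply(occ != 0L, 3, any)
  if (length(stations) == 1L && stations == floor(stations)) {
    zr <- range(zVox[fluidSlice])
    stations <- seq(zr[1], zr[2], length.out = as.integer(stations))
  }
  n <- length(stations)
  if (is.null(labels)) labels <- make.unique(LETTERS[((seq_len(n) - 1L) %% 26L) + 1L])
  p <- pressureField(field)
  pBar <- area <- numeric(n)
  for (i in seq_len(n)) {
    k <- which(abs(zVox - stations[i]) <= dx / 2)
    sel <- occ[, , k, drop = FALSE] != 0L
    if (!any(sel)) {
      pBar[i] <- NA_real_
      area[i] <- 0
      warning("station ", labels[i], " (z=", stations[i],
        " mm) lies in a fully occluded slab; skipped in derivatives")
    } else {
      pBar[i] <- mean(p[, , k, drop = FALSE][sel])
      area[i] <- sum(sel) * dx^2 / length(k)
    }
  }
  ref <- pBar[which(!is.na(pBar))[1]]
  data.frame(station = labels, z_mm = stations, p_bar_pa = pBar - ref,
    area_mm2 = area, stringsAsFactors = FALSE)
}

#' First and second axial pressure derivatives
#'
#' Three-point Lagrange stencils on (possibly non-uniform) stations:
#' central, second-order `dp/dz` at interior stations with one-sided
#' second-order ends; `d2p/dz2` from the interpolating quadratic, undefined
#' at the ends. The operator is linear and exact for quadratics.
#'
#' @param pBar pressure per station (any consistent unit).
#' @param z station positions (mm), strictly increasing, length >= 3.
#' @return list with `dpDz` and `d2pDz2` (same length as `pBar`, `d2pDz2`
#'   `NA` at the two ends).
#' @examples
#' pressureGradients(c(3, 2, 1), 0:2)      # dpDz -1 everywhere, d2 = 0
#' pressureGradients((0:2)^2, 0:2)$d2pDz2  # 2 at the middle
#' @export
pressureGradients <- function(pBar, z) {
  ok <- !is.na(pBar)
  zz <- z[ok]
  pp <- pBar[ok]
  n <- length(pp)
  if (n < 3) stop("need at least 3 stations with pressure values")
  if (any(diff(zz) <= 0)) stop("stations must be strictly increasing in z")
  d1 <- d2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- if (i == 1) 1:3 else if (i == n) (n - 2):n else (i - 1):(i + 1)
    za <- zz[j[1]]; zb <- zz[j[2]]; zc <- zz[j[3]]
    pa <- pp[j[1]]; pb <- pp[j[2]]; pc <- pp[j[3]]
    la <- pa / ((za - zb) * (za - zc))
    lb <- pb / ((zb - za) * (zb - zc))
    lc <- pc / ((zc - za) * (zc - zb))
    zi <- zz[i]
    d1[i] <- la * (2 * zi - zb - zc) + lb * (2 * zi - za - zc) +
      lc * (2 * zi - za - zb)
    if (i > 1 && i < n) d2[i] <- 2 * (la + lb + lc)
  }
  dpDz <- d2pDz2 <- rep(NA_real_, length(pBar))
  dpDz[ok] <- d1
  d2pDz2[ok] <- d2
  list(dpDz = dpDz, d2pDz2 = d2pDz2)
}

#' Assemble an obstruction profile
#'
#' Combines station pressures with their derivatives into an
#' [ObstructionProfile-class]; call [rankObstructions()] to fill the site
#' ranking.
#'
#' @param stationDf data.frame from [stationPressures()].
#' @return an [ObstructionProfile-class] (ranking not yet computed).
#' @export
obstructionProfile <- function(stationDf) {
  g <- pressureGradients(stationDf$p_bar_pa, stationDf$z_mm)
  new("ObstructionProfile",
    stations = stationDf$station,
    z = stationDf$z_mm,
    pBar = stationDf$p_bar_pa,
    dpDz = g$dpDz,
    d2pDz2 = g$d2pDz2,
    area = stationDf$area_mm2,
    ranking = data.frame(),
    dominantSite = NA_character_,
    noFocalObstruction = FALSE)
}

#' Rank obstruction sites by |d2p/dz2|
#'
#' Interior stations are ranked by descending `|d2p/dz2|`; ties are broken
#' by the lower section-averaged pressure, then by the more distal
#' position. The per-station lumen area is carried along to corroborate
#' the ranking (a focal obstruction should pair a high score with a small
#' area), reported but not enforced. When the pressure profile is
#' essentially linear (no curvature above numerical noise) the profile is
#' flagged `noFocalObstruction`.
#'
#' @param profile an [ObstructionProfile-class].
#' @param flatTol curvature below `flatTol * range(pBar) / span^2` counts
#'   as no focal obstruction.
#' @return the profile with `ranking` and `dominantSite` filled.
#' @export
rankObstructions <- function(profile, flatTol = 0.05) {
  i <- which(!is.na(profile@d2pDz2))
  if (!length(i)) stop("no interior stations with derivatives; need >= 3 stations")
  score <- abs(profile@d2pDz2[i])
  ord <- order(-score, profile@pBar[i], -profile@z[i])
  ranking <- data.frame(
    station = profile@stations[i][ord],
    z_mm = profile@z[i][ord],
    score = score[ord],
    p_bar_pa = profile@pBar[i][ord],
    area_mm2 = profile@area[i][ord],
    stringsAsFactors = FALSE)
  span <- diff(range(profile@z))
  pRange <- diff(range(profile@pBar, na.rm = TRUE))
  profile@noFocalObstruction <-
    pRange == 0 || max(score) < flatTol * pRange / span^2
  profile@ranking <- ranking
  profile@dominantSite <- ranking$station[1]
  profile
}
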