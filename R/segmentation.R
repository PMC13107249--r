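# Automated lumen-wall detection: per-A-line first-crossing detector,
# per-frame contour assembly, and cross-frame filling of missing sectors.

#' Detect the lumen wall on one A-line
#'
#' Returns the depth of the first run of at least `m` consecutive samples
#' exceeding `noise mean + k * noise sd` beyond the exclusion zone — the
#' near edge of the wall echo, which is the lumen boundary. Returns `NA`
#' (missing) when no such run exists; missing is a value, not an error.
#'
#' @param aline numeric depth profile (one A-line).
#' @param noise list with `mean` and `sd` of the noise floor (see
#'   [noiseStats()]).
#' @param exclusionMm depth excluded from the search (sheath zone), less
#'   than the depth range.
#' @param pixelPitch depth sampling of `aline` (mm/pixel).
#' @param k threshold in noise SDs above the noise mean.
#' @param m minimum run length (samples).
#' @return wall depth in mm, or `NA_real_` if missing.
#' @export
detectWall <- function(aline, noise, exclusionMm, pixelPitch, k = 4, m = 5L) {
  nD <- length(aline)
  if (exclusionMm >= nD * pixelPitch) stop("exclusion zone exceeds the depth range")
  thr <- noise$mean + k * noise$sd
  excl <- ceiling(exclusionMm / pixelPitch) + 1L
  above <- aline[excl:nD] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= m)
  if (!length(hit)) return(NA_real_)
  start <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  (start + excl - 2L) * pixelPitch
}

# Circular moving average over valid entries only; invalid entries and
# entries with no valid neighbor in the window are returned unchanged.
.smooth_circular_valid <- function(r, valid, window) {
  n <- length(r)
  if (window < 2 || !any(valid)) return(r)
  h <- window %/% 2
  out <- r
  idx <- which(valid)
  off <- -h:h
  for (k in idx) {
    j <- ((k - 1 + off) %% n) + 1
    j <- j[valid[j]]
    out[k] <- mean(r[j])
  }
  out
}

# Circular linear interpolation of NA radii from the nearest valid angular
# neighbors.
.interp_circular <- function(r) {
  n <- length(r)
  bad <- which(is.na(r))
  good <- which(!is.na(r))
  if (!length(bad) || !length(good)) return(r)
  for (k in bad) {
    dPrev <- (k - good) %% n
    dNext <- (good - k) %% n
    iPrev <- good[which.min(dPrev)]
    iNext <- good[which.min(dNext)]
    a <- min(dPrev)
    b <- min(dNext)
    r[k] <- if (a + b == 0) r[iPrev] else (b * r[iPrev] + a * r[iNext]) / (a + b)
  }
  r
}

#' Assemble a lumen contour from one preprocessed B-scan
#'
#' Runs the first-crossing wall detector on every A-line, smooths the
#' radius signature with a periodic moving average applied to valid runs
#' only, and converts to catheter-centered Cartesian vertices. Missing
#' sectors receive provisional angularly interpolated radii but stay
#' flagged invalid so [fillMissingSectors()] can replace them from
#' neighboring frames. A contour with more than `maxMissingFrac` of its
#' sectors missing is flagged unusable (quality triage).
#'
#' @param frame a [PolarBScan-class], artifact-masked.
#' @param exclusionMm depth excluded from the search (sheath zone).
#' @param k,m detector threshold (noise SDs) and run length.
#' @param smoothWindow periodic moving-average window (A-lines).
#' @param maxMissingFrac missing-sector fraction above which the contour is
#'   flagged unusable.
#' @return a [LumenContour-class].
#' @export
contourFromFrame <- function(frame, exclusionMm = 1.3, k = 4, m = 5L,
                             smoothWindow = 9L, maxMissingFrac = 0.5) {
  depths <- .wall_signature(frame, exclusionMm, k = k, m = m)
  nA <- length(depths)
  valid <- !is.na(depths)
  usable <- mean(!valid) <= maxMissingFrac
  r <- .smooth_circular_valid(depths, valid, smoothWindow)
  r <- .interp_circular(r)
  if (all(is.na(r))) r[] <- 1  # fully missing frame: placeholder geometry
  theta <- 2 * pi * (seq_len(nA) - 1L) / nA
  new("LumenContour",
    frameIndex = frame@frameIndex,
    z = frame@zNominal,
    vertices = cbind(r * cos(theta), r * sin(theta)),
    sectorValid = valid,
    extrapolated = !valid,
    usable = usable
  )
}

#' Fill missing contour sectors from neighboring frames
#'
#' For each invalid vertex, the radius is replaced by linear interpolation
#' in frame index between the nearest valid same-angle vertices within
#' `searchLimit` frames (flat extension when only one side exists); vertices
#' still unfillable are interpolated angularly within their own frame.
#' Valid vertices are never modified; filled vertices remain flagged
#' `extrapolated`.
#'
#' @param contours ordered list of [LumenContour-class] sharing the vertex
#'   count and angular grid.
#' @param searchLimit frame-index search radius.
#' @return the list with invalid radii filled.
#' @export
fillMissingSectors <- function(contours, searchLimit = 10L) {
  nF <- length(contours)
  if (!nF) return(contours)
  nA <- nrow(contours[[1]]@vertices)
  if (any(vapply(contours, function(ct) nrow(ct@vertices), 0L) != nA))
    stop("contours must share the vertex count and angular grid")
  R <- t(vapply(contours, function(ct) sqrt(rowSums(ct@vertices^2)), numeric(nA)))
  V <- t(vapply(contours, function(ct) ct@sectorValid, logical(nA)))
  fullyMissing <- which(rowSums(V) == 0)
  if (length(fullyMissing)) {
    reachable <- vapply(fullyMissing, function(i) {
      any(rowSums(V[max(1, i - searchLimit):min(nF, i + searchLimit), ,
        drop = FALSE]) > 0)
    }, logical(1))
    if (any(!reachable))
      stop("contours fully missing beyond the search limit at frame indices: ",
        paste(vapply(contours[fullyMissing[!reachable]], frameIndex, 0L),
          collapse = ", "))
  }
  Rf <- R
  for (a in seq_len(nA)) {
    bad <- which(!V[, a])
    if (!length(bad)) next
    good <- which(V[, a])
    for (i in bad) {
      lo <- good[good < i]
      hi <- good[good > i]
      lo <- if (length(lo)) max(lo) else NA_integer_
      hi <- if (length(hi)) min(hi) else NA_integer_
      if (!is.na(lo) && i - lo > searchLimit) lo <- NA_integer_
      if (!is.na(hi) && hi - i > searchLimit) hi <- NA_integer_
      Rf[i, a] <- if (!is.na(lo) && !is.na(hi)) {
        ((hi - i) * R[lo, a] + (i - lo) * R[hi, a]) / (hi - lo)
      } else if (!is.na(lo)) R[lo, a] else if (!is.na(hi)) R[hi, a] else NA_real_
    }
  }
  theta <- 2 * pi * (seq_len(nA) - 1L) / nA
  for (i in seq_len(nF)) {
    ri <- Rf[i, ]
    if (anyNA(ri)) {
      ri[is.na(ri) & !V[i, ]] <- NA_real_
      ri <- .interp_circular(ri)
    }
    fill <- !V[i, ]
    if (any(fill)) {
      v <- contours[[i]]@vertices
      v[fill, 1] <- ri[fill] * cos(theta[fill])
      v[fill, 2] <- ri[fill] * sin(theta[fill])
      contours[[i]]@vertices <- v
      contours[[i]]@extrapolated <- fill
    }
  }
  contours
}
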