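# Post-processing of raw polar B-scan stacks: coordinate conversion,
# sheath-artifact masking, and rotational frame-to-frame alignment.

# Bilinear sampling of `mat` at fractional (row, col) positions. Rows can
# wrap (angular axis); out-of-range columns return `fill`.
.bilinear <- function(mat, ri, ci, wrapRows = FALSE, fill = 0) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0;  fc <- ci - c0
  idx <- function(r, c) {
    r <- if (wrapRows) ((r - 1) %% nr) + 1 else pmin(pmax(r, 1), nr)
    ok <- c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- mat[cbind(r[ok], c[ok])]
    v[!ok] <- fill
    v
  }
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
       (1 - fr) * fc       * idx(r0, c0 + 1) +
       fr       * (1 - fc) * idx(r0 + 1, c0) +
       fr       * fc       * idx(r0 + 1, c0 + 1)
  v
}

#' Convert between polar and Cartesian B-scan representations
#'
#' The native B-scan indexes intensity by (A-line angle, depth). A point at
#' angle `theta` and depth `d` maps to Cartesian `(d cos(theta),
#' d sin(theta))` on a square grid centered on the catheter axis; the
#' inverse resamples a Cartesian image back onto the polar grid. Both use
#' bilinear interpolation (with angular wrap-around) and are round-trip
#' stable to within interpolation error.
#'
#' @param frame a [PolarBScan-class].
#' @param outPixelMm Cartesian pixel size (mm), `> 0`.
#' @return `polarToCartesian`: a square matrix with attributes `pixel_mm`
#'   and `center` (pixel coordinates of the catheter axis).
#' @export
polarToCartesian <- function(frame, outPixelMm) {
  if (outPixelMm <= 0) stop("outPixelMm must be positive")
  nA <- nrow(frame@intensity)
  nD <- ncol(frame@intensity)
  rangeMm <- frame@pixelPitch * nD
  half <- ceiling(rangeMm / outPixelMm)
  ax <- (-half:half) * outPixelMm
  xy <- expand.grid(x = ax, y = ax)
  r <- sqrt(xy$x^2 + xy$y^2)
  th <- atan2(xy$y, xy$x) %% (2 * pi)
  ri <- th / (2 * pi) * nA + 1      # fractional A-line index
  ci <- r / frame@pixelPitch + 1    # fractional depth index
  v <- .bilinear(frame@intensity, ri, ci, wrapRows = TRUE)
  out <- matrix(v, nrow = length(ax))
  attr(out, "pixel_mm") <- outPixelMm
  attr(out, "center") <- c(half + 1, half + 1)
  out
}

#' @rdname polarToCartesian
#' @param image a Cartesian image as produced by [polarToCartesian()].
#' @param pixelMm Cartesian pixel size of `image` (mm).
#' @param nAlines,depthPixels,pixelPitch polar grid to resample onto.
#' @return `cartesianToPolar`: an `nAlines x depthPixels` intensity matrix.
#' @export
cartesianToPolar <- function(image, pixelMm = attr(image, "pixel_mm"),
                             nAlines, depthPixels, pixelPitch) {
  if (is.null(pixelMm) || pixelMm <= 0) stop("pixelMm must be positive")
  center <- attr(image, "center")
  if (is.null(center)) center <- (dim(image) + 1) / 2
  theta <- 2 * pi * (seq_len(nAlines) - 1L) / nAlines
  depth <- (seq_len(depthPixels) - 1L) * pixelPitch
  x <- outer(cos(theta), depth)
  y <- outer(sin(theta), depth)
  ri <- x / pixelMm + center[1]
  ci <- y / pixelMm + center[2]
  v <- .bilinear(image, as.vector(ri), as.vector(ci), wrapRows = FALSE)
  matrix(pmax(v, 0), nAlines, depthPixels)
}

#' Noise-floor statistics of a B-scan
#'
#' Robust noise level and spread (median and MAD) over all samples beyond
#' the exclusion zone. The wall echo and tissue tail occupy a minority of
#' the imaging range, so the median and MAD estimate the noise floor even
#' when the wall sits near the end of the range.
#'
#' @param frame a [PolarBScan-class].
#' @param exclusionMm depth excluded (sheath zone).
#' @return list with `mean` and `sd`.
#' @export
noiseStats <- function(frame, exclusionMm = 1.3) {
  nD <- ncol(frame@intensity)
  from <- min(nD, ceiling(exclusionMm / frame@pixelPitch) + 1L)
  tail <- frame@intensity[, from:nD]
  list(mean = stats::median(tail), sd = stats::mad(tail))
}

#' Mask the sheath-reflection ring artifact
#'
#' Replaces intensities with depth inside `band` by the frame's per-A-line
#' noise-floor level; every pixel outside the band is left exactly
#' unchanged.
#'
#' @param frame a [PolarBScan-class].
#' @param band `c(r_min, r_max)` in mm, `0 <= r_min < r_max < depth range`.
#' @return the masked [PolarBScan-class].
#' @export
maskSheathArtifact <- function(frame, band = c(0.7, 1.1)) {
  nD <- ncol(frame@intensity)
  rangeMm <- frame@pixelPitch * nD
  if (band[1] < 0 || band[2] <= band[1] || band[2] >= rangeMm)
    stop("band must satisfy 0 <= r_min < r_max < depth range (", rangeMm, " mm)")
  depth <- (seq_len(nD) - 1L) * frame@pixelPitch
  cols <- which(depth >= band[1] & depth <= band[2])
  if (length(cols)) {
    ns <- noiseStats(frame)
    frame@intensity[, cols] <- ns$mean
  }
  frame
}

# Fast per-A-line wall-depth signature (mm) used for registration: first
# sample of the first run of >= m consecutive samples above
# noise_mean + k * noise_sd, beyond the exclusion depth. NA where none.
.wall_signature <- function(frame, exclusionMm = 1.3, k = 4, m = 5L,
                            noise = NULL) {
  if (is.null(noise)) noise <- noiseStats(frame)
  thr <- noise$mean + k * noise$sd
  img <- frame@intensity
  nD <- ncol(img)
  excl <- ceiling(exclusionMm / frame@pixelPitch) + 1L
  above <- img[, excl:nD, drop = FALSE] > thr
  # run-length trick: a sample starts a qualifying run iff the forward
  # m-window is all TRUE; cumulative sums give windowed counts.
  cs <- t(apply(above, 1, cumsum))
  nW <- ncol(above) - m + 1L
  if (nW < 1) return(rep(NA_real_, nrow(img)))
  wins <- cs[, m:ncol(above), drop = FALSE] -
    cbind(0, cs[, seq_len(nW - 1L), drop = FALSE])
  first <- apply(wins == m, 1, function(r) {
    i <- which(r)
    if (length(i)) i[1] else NA_integer_
  })
  (first + excl - 2L) * frame@pixelPitch
}

# Rotate the A-line axis of a matrix by `s` rows: row k of the result is
# row (k - s) of the input (cyclically).
.rotate_rows <- function(mat, s) {
  n <- nrow(mat)
  mat[((seq_len(n) - 1L - s) %% n) + 1L, , drop = FALSE]
}

# Circular cross-correlation argmax: the rotation s by which b is rotated
# relative to a, i.e. s maximizing sum_k a[k] * b[k + s] so that
# b[k] ~= a[k - s].
.circular_shift <- function(a, b) {
  n <- length(a)
  a <- a - mean(a)
  b <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / n
  s <- which.max(cc) - 1L
  if (s > n / 2) s <- s - n
  as.integer(s)
}

#' Rotationally align a B-scan stack
#'
#' Registers each frame to its predecessor by maximizing the circular
#' cross-correlation of the per-A-line wall-distance signatures, then
#' applies the cumulative rotation. Robust to speckle because only the wall
#' geometry enters the correlation.
#'
#' @param stack list of [PolarBScan-class] frames.
#' @param exclusionMm depth excluded from wall detection (sheath zone).
#' @return list with `stack` (aligned frames), `offsets` (per-frame
#'   frame-to-predecessor rotation in A-lines; first entry 0) and
#'   `cumulative` (rotation applied to each frame).
#' @export
alignFrames <- function(stack, exclusionMm = 1.3) {
  nF <- length(stack)
  if (nF < 2)
    return(list(stack = stack, offsets = integer(nF), cumulative = integer(nF)))
  sig <- lapply(stack, function(f) {
    s <- .wall_signature(f, exclusionMm)
    if (all(is.na(s))) s[] <- 0 else s[is.na(s)] <- stats::median(s, na.rm = TRUE)
    s
  })
  offsets <- integer(nF)
  for (i in 2:nF) offsets[i] <- .circular_shift(sig[[i - 1]], sig[[i]])
  cumulative <- cumsum(offsets)
  aligned <- stack
  for (i in seq_len(nF)) {
    if (cumulative[i] != 0) {
      s <- -cumulative[i]
      aligned[[i]]@intensity <- .rotate_rows(stack[[i]]@intensity, s)
      n <- length(stack[[i]]@sectorValid)
      aligned[[i]]@sectorValid <-
        stack[[i]]@sectorValid[((seq_len(n) - 1L + cumulative[i]) %% n) + 1L]
    }
  }
  list(stack = aligned, offsets = offsets, cumulative = cumulative)
}
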