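# Readers and writers for the pipeline's on-disk formats. Every writer has
# a reader that round-trips losslessly (32-bit float TIFF for image stacks;
# full-precision ASCII is available for STL when exactness matters).

#' Write / read a B-scan stack as multi-page TIFF
#'
#' Intensities are stored as 32-bit float samples (lossless); per-frame
#' metadata (pixel pitch, nominal z, sector validity) goes to a JSON
#' sidecar `<path>.json`.
#'
#' @param stack list of [PolarBScan-class].
#' @param path TIFF file path.
#' @return `writeBScanStack`: the path, invisibly; `readBScanStack`: the
#'   stack.
#' @export
writeBScanStack <- function(stack, path) {
  imgs <- lapply(stack, function(f) f@intensity)
  mx <- max(1e-12, vapply(imgs, max, 0))
  tiff::writeTIFF(lapply(imgs, function(m) m / mx), path,
    bits.per.sample = 32L, compression = "none", reduce = FALSE)
  meta <- list(
    scale = mx,
    pixel_pitch = stack[[1]]@pixelPitch,
    frame_index = vapply(stack, function(f) f@frameIndex, 0L),
    z_nominal = vapply(stack, function(f) f@zNominal, 0),
    sector_valid = lapply(stack, function(f) f@sectorValid)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
    auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeBScanStack
#' @export
readBScanStack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sv <- meta$sector_valid   # equal-length flags simplify into a matrix
  lapply(seq_along(imgs), function(i) {
    new("PolarBScan",
      intensity = imgs[[i]] * meta$scale,
      pixelPitch = meta$pixel_pitch,
      frameIndex = as.integer(meta$frame_index[i]),
      zNominal = meta$z_nominal[i],
      sectorValid = as.logical(if (is.matrix(sv)) sv[i, ] else sv[[i]]))
  })
}

#' Write / read lumen contours (JSON and flat CSV)
#'
#' The JSON form is lossless (full double precision); the CSV form is a
#' flat per-vertex table convenient for spreadsheets.
#'
#' @param contours list of [LumenContour-class].
#' @param path output path (`.json` or `.csv` decides the format).
#' @export
writeContours <- function(contours, path) {
  if (grepl("\\.csv$", path)) {
    df <- do.call(rbind, lapply(contours, function(ct) {
      data.frame(frame_index = ct@frameIndex, z_mm = ct@z,
        vertex = seq_len(nrow(ct@vertices)),
        x_mm = ct@vertices[, 1], y_mm = ct@vertices[, 2],
        valid = ct@sectorValid, extrapolated = ct@extrapolated,
        usable = ct@usable)
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    obj <- lapply(contours, function(ct) list(
      frame_index = ct@frameIndex, z_mm = ct@z,
      x_mm = ct@vertices[, 1], y_mm = ct@vertices[, 2],
      sector_valid = ct@sectorValid, extrapolated = ct@extrapolated,
      usable = ct@usable))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  mk <- function(fi, z, x, y, valid, extr, usable) {
    new("LumenContour", frameIndex = as.integer(fi), z = as.numeric(z),
      vertices = cbind(as.numeric(x), as.numeric(y)),
      sectorValid = as.logical(valid), extrapolated = as.logical(extr),
      usable = as.logical(usable))
  }
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path)
    lapply(split(df, df$frame_index)[order(unique(df$frame_index))], function(d) {
      d <- d[order(d$vertex), ]
      mk(d$frame_index[1], d$z_mm[1], d$x_mm, d$y_mm, d$valid,
        d$extrapolated, d$usable[1])
    })
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(seq_len(nrow(obj)), function(i) {
      mk(obj$frame_index[i], obj$z_mm[i], obj$x_mm[[i]], obj$y_mm[[i]],
        obj$sector_valid[[i]], obj$extrapolated[[i]], obj$usable[i])
    })
  }
}

#' Write / read a centerline as CSV
#'
#' Columns `s_mm`, `x_mm`, `y_mm`, `z_mm`; frames are recomputed on read
#' when the written centerline had them.
#'
#' @param centerline a [Centerline-class].
#' @param path CSV path.
#' @export
writeCenterlineCSV <- function(centerline, path) {
  df <- data.frame(s_mm = centerline@arcLength,
    x_mm = centerline@samples[, 1], y_mm = centerline@samples[, 2],
    z_mm = centerline@samples[, 3])
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCenterlineCSV
#' @param withFrames attach rotation-minimizing frames after reading.
#' @export
readCenterlineCSV <- function(path, withFrames = FALSE) {
  df <- utils::read.csv(path)
  cl <- new("Centerline",
    samples = cbind(df$x_mm, df$y_mm, df$z_mm), arcLength = df$s_mm,
    tangent = matrix(0, 0, 3), normal1 = matrix(0, 0, 3),
    normal2 = matrix(0, 0, 3), residualRms = NA_real_)
  if (withFrames) framesAlongCenterline(cl) else cl
}

#' Write / read a triangle mesh as STL
#'
#' `format = "binary"` writes the compact 32-bit-float binary STL;
#' `format = "ascii"` writes full-precision ASCII STL and round-trips the
#' coordinates exactly. Reading reconstructs shared vertices by exact
#' coordinate matching.
#'
#' @param surface an [AirwaySurface-class].
#' @param path STL path.
#' @param format `"binary"` or `"ascii"`.
#' @export
writeSTL <- function(surface, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  v <- surface@vertices
  tr <- surface@triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  nT <- nrow(tr)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nT), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, a, b, cc))  # 12 floats per triangle
    for (t in seq_len(nT)) {
      writeBin(as.numeric(dat[, t]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    fmt <- function(x) sprintf("%.17g", x)
    lines <- c("solid airwayflow",
      unlist(lapply(seq_len(nT), function(t) c(
        paste("facet normal", fmt(nrm[t, 1]), fmt(nrm[t, 2]), fmt(nrm[t, 3])),
        "  outer loop",
        paste("    vertex", fmt(a[t, 1]), fmt(a[t, 2]), fmt(a[t, 3])),
        paste("    vertex", fmt(b[t, 1]), fmt(b[t, 2]), fmt(b[t, 3])),
        paste("    vertex", fmt(cc[t, 1]), fmt(cc[t, 2]), fmt(cc[t, 3])),
        "  endloop",
        "endfacet"))),
      "endsolid airwayflow")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname writeSTL
#' @export
readSTL <- function(path) {
  head4 <- readBin(path, "raw", 5)
  isAscii <- identical(rawToChar(head4), "solid")
  if (isAscii) {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nT <- readBin(con, "integer", 1, size = 4, endian = "little")
    xyz <- matrix(0, 3 * nT, 3)
    for (t in seq_len(nT)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      xyz[3 * t - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  key <- apply(xyz, 1, function(r) paste(sprintf("%.9e", r), collapse = "_"))
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  new("AirwaySurface", vertices = verts, triangles = tris,
    stationOfVertex = integer(nrow(verts)))
}

#' Write a mesh as legacy-ASCII VTK PolyData
#'
#' @param surface an [AirwaySurface-class].
#' @param path `.vtk` path.
#' @export
writeVTKPolyData <- function(surface, path) {
  v <- surface@vertices
  tr <- surface@triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "airway lumen surface",
    "ASCII", "DATASET POLYDATA",
    paste("POINTS", nrow(v), "double")), con)
  utils::write.table(format(v, digits = 17, trim = TRUE), con,
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("POLYGONS", nrow(tr), 4 * nrow(tr)), con)
  utils::write.table(cbind(3L, tr), con, row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeVTKPolyData
#' @export
readVTKPolyData <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nP <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + nP)], quiet = TRUE)
  verts <- matrix(pts, ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  nT <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  tv <- scan(text = lines[(it + 1):(it + nT)], quiet = TRUE)
  tris <- matrix(tv, ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  new("AirwaySurface", vertices = verts, triangles = tris,
    stationOfVertex = integer(nrow(verts)))
}

#' Write / read a flow field as legacy-ASCII VTK structured points
#'
#' Stores pressure (Pa) as point scalars and velocity (m/s) as point
#' vectors on the voxel grid; solid voxels carry 0. The occupancy grid is
#' written as a second scalar field so the read-back can restore the
#' fluid mask.
#'
#' @param field a [FlowField-class].
#' @param path `.vtk` path.
#' @export
writeVTKImageData <- function(field, path) {
  d <- dim(field@rho)
  dx <- field@conversions$dx_mm
  org <- field@conversions$origin_mm
  if (is.null(org)) org <- c(0, 0, 0)
  p <- pressureField(field)
  u <- velocityField(field)
  p[is.na(p)] <- 0
  u[is.na(u)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "airway flow field", "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("ORIGIN", org[1], org[2], org[3]),
    paste("SPACING", dx, dx, dx),
    paste("POINT_DATA", prod(d)),
    "SCALARS pressure_pa double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.17g", as.vector(p)), con)
  writeLines(c("SCALARS occupancy int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.vector(field@occupancy)), con)
  writeLines("VECTORS velocity_m_s double", con)
  writeLines(sprintf("%.17g %.17g %.17g", as.vector(u[, , , 1]),
    as.vector(u[, , , 2]), as.vector(u[, , , 3])), con)
  invisible(path)
}

#' @rdname writeVTKImageData
#' @return `readVTKImageData`: list with `pressure_pa` (3D array),
#'   `velocity_m_s` (4D array), `occupancy`, `origin_mm`, `dx_mm`.
#' @export
readVTKImageData <- function(path) {
  lines <- readLines(path)
  d <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE)[1],
    "\\s+")[[1]][2:4])
  org <- as.numeric(strsplit(grep("^ORIGIN", lines, value = TRUE)[1],
    "\\s+")[[1]][2:4])
  dx <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE)[1],
    "\\s+")[[1]][2])
  n <- prod(d)
  ip <- grep("^SCALARS pressure_pa", lines)[1] + 2L
  p <- array(as.numeric(lines[ip:(ip + n - 1)]), d)
  io <- grep("^SCALARS occupancy", lines)[1] + 2L
  occ <- array(as.integer(lines[io:(io + n - 1)]), d)
  iv <- grep("^VECTORS velocity_m_s", lines)[1] + 1L
  uv <- do.call(rbind, lapply(strsplit(lines[iv:(iv + n - 1)], "\\s+"),
    as.numeric))
  u <- array(0, c(d, 3L))
  u[, , , 1] <- array(uv[, 1], d)
  u[, , , 2] <- array(uv[, 2], d)
  u[, , , 3] <- array(uv[, 3], d)
  list(pressure_pa = p, velocity_m_s = u, occupancy = occ,
    origin_mm = org, dx_mm = dx)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config a configuration list (see [defaultPipelineConfig()]).
#' @param path `.yaml` path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .merge_config(defaultPipelineConfig(), cfg)
}

# recursive default-filling merge (NULL overrides are kept, not dropped)
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[nm] <- list(.merge_config(base[[nm]], override[[nm]]))
    else base[nm] <- list(override[[nm]])
  }
  base
}
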