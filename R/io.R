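.dialects <- c("long_csv", "wide_csv", "container")

#' Read a hyperspectral cube
#'
#' Supported dialects: \code{long_csv} (columns
#' \code{row,col,wavenumber,intensity}, header required, 0-based
#' indices), \code{wide_csv} (instrument-export style: first column
#' \code{wavenumber}, one column per pixel named \code{px_<row>_<col>})
#' and \code{container} (a portable JSON container with fields
#' \code{axis}, \code{cube}, \code{mask}, \code{width}, \code{height},
#' \code{pixel_size_nm}).  Non-finite intensities are rejected by
#' default; with \code{nonFinite = "mask"} the affected pixels are
#' masked instead — silent NaN propagation would corrupt area
#' statistics.  Intensity units are never rescaled at I/O; the only
#' sanctioned normalization is the explicit internal-standard ratio.
#'
#' @param path input file.
#' @param dialect one of \code{"long_csv"}, \code{"wide_csv"},
#'   \code{"container"}.
#' @param nonFinite \code{"error"} (default) or \code{"mask"}.
#' @param pixelSize pixel spacing in nm for the text dialects (the
#'   container stores its own).
#' @return A \linkS4class{RamanCube}.
#' @export
readCube <- function(path, dialect = c("long_csv", "wide_csv", "container"),
                     nonFinite = c("error", "mask"), pixelSize = 450) {
  dialect <- match.arg(dialect)
  nonFinite <- match.arg(nonFinite)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (dialect == "container") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    S <- if (is.matrix(obj$cube)) obj$cube else
      do.call(rbind, obj$cube)
    mask <- if (!is.null(obj$mask)) as.logical(obj$mask) else NULL
    ax <- as.numeric(obj$axis)
    if (any(diff(ax) <= 0))
      stop("axis error: wavenumber axis must be strictly increasing")
    S[!is.finite(S)] <- NA_real_
    return(.finishCube(S, ax, obj$width, obj$height,
                       obj$pixel_size_nm, mask, nonFinite))
  }
  dt <- data.table::fread(path)
  if (dialect == "long_csv") {
    need <- c("row", "col", "wavenumber", "intensity")
    miss <- setdiff(need, names(dt))
    if (length(miss))
      stop("format error: missing column(s): ", paste(miss, collapse = ", "))
    width <- max(dt$col) + 1L
    height <- max(dt$row) + 1L
    data.table::setorder(dt, row, col, wavenumber)
    ax <- sort(unique(dt$wavenumber))
    if (any(diff(ax) <= 0) || length(ax) < 2L)
      stop("axis error: wavenumber axis must be strictly increasing")
    if (nrow(dt) != width * height * length(ax))
      stop("format error: pixels do not share a complete common axis")
    S <- matrix(dt$intensity, nrow = width * height, byrow = TRUE)
    return(.finishCube(S, ax, width, height, pixelSize, NULL, nonFinite))
  }
  # wide_csv
  if (names(dt)[1] != "wavenumber")
    stop("format error: first column must be 'wavenumber', found '",
         names(dt)[1], "'")
  pxCols <- names(dt)[-1]
  if (!all(grepl("^px_\\d+_\\d+$", pxCols)))
    stop("format error: pixel columns must be named px_<row>_<col>; ",
         "offending column: ",
         pxCols[!grepl("^px_\\d+_\\d+$", pxCols)][1])
  ax <- dt$wavenumber
  if (any(diff(ax) <= 0))
    stop("axis error: wavenumber axis must be strictly increasing")
  rc <- do.call(rbind, lapply(strsplit(sub("^px_", "", pxCols), "_"),
                              as.integer))
  width <- max(rc[, 2]) + 1L
  height <- max(rc[, 1]) + 1L
  S <- matrix(NA_real_, width * height, length(ax))
  for (j in seq_along(pxCols))
    S[rc[j, 1] * width + rc[j, 2] + 1L, ] <- dt[[pxCols[j]]]
  .finishCube(S, ax, width, height, pixelSize, NULL, nonFinite)
}

.finishCube <- function(S, ax, width, height, pixelSize, mask, nonFinite) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(S))
  bad <- mask & apply(S, 1L, function(x) any(!is.finite(x)))
  if (any(bad)) {
    if (nonFinite == "error")
      stop("non-finite intensities at ", sum(bad),
           " pixel(s); use nonFinite = \"mask\" to mask them")
    mask[bad] <- FALSE
  }
  if (any(!mask)) {
    sub <- S[!mask, , drop = FALSE]
    sub[!is.finite(sub)] <- 0
    S[!mask, ] <- sub
  }
  RamanCube(S, ax, width, height, pixelSize, mask)
}

#' Write a hyperspectral cube
#'
#' Inverse of \code{\link{readCube}}; see there for the dialects.  The
#' text dialects write masked pixels as NA (restored via
#' \code{nonFinite = "mask"}); the container dialect stores the mask
#' explicitly and round-trips bit-exactly.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param path output file.
#' @param dialect one of \code{"long_csv"}, \code{"wide_csv"},
#'   \code{"container"}.
#' @return invisibly, the path.
#' @export
writeCube <- function(cube, path,
                      dialect = c("long_csv", "wide_csv", "container")) {
  dialect <- match.arg(dialect)
  if (dir.exists(path)) stop("I/O error: target path is a directory: ", path)
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  S <- spectra(cube)
  mask <- validMask(cube)
  d <- cubeDim(cube)
  if (dialect == "container") {
    obj <- list(axis = wavenumber(cube),
                cube = lapply(seq_len(nrow(S)), function(i) S[i, ]),
                mask = as.integer(mask),
                width = unname(d["width"]), height = unname(d["height"]),
                pixel_size_nm = pixelSize(cube))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  Sout <- S
  Sout[!mask, ] <- NA_real_
  npix <- nrow(S)
  r <- (seq_len(npix) - 1L) %/% d["width"]
  c_ <- (seq_len(npix) - 1L) %% d["width"]
  if (dialect == "long_csv") {
    nch <- ncol(S)
    dt <- data.table::data.table(
      row = rep(r, each = nch), col = rep(c_, each = nch),
      wavenumber = rep(wavenumber(cube), npix),
      intensity = as.vector(t(Sout)))
    data.table::fwrite(dt, path)
  } else {
    dt <- data.table::data.table(wavenumber = wavenumber(cube))
    for (i in seq_len(npix))
      data.table::set(dt, j = sprintf("px_%d_%d", r[i], c_[i]),
                      value = Sout[i, ])
    data.table::fwrite(dt, path)
  }
  invisible(path)
}

.mapMatrix <- function(map) {
  if (is(map, "ClusterResult"))
    asImage(as.numeric(clusterLabels(map)), map)
  else
    asImage(map@values, map)
}

.mapValid <- function(map) {
  if (is(map, "ClusterResult")) asImage(!is.na(clusterLabels(map)), map)
  else asImage(map@valid, map)
}

#' Export a map as a raster or table
#'
#' Renders an \linkS4class{AreaMap}, \linkS4class{RatioMap} or
#' \linkS4class{ClusterResult} label map as a heat map / composite.
#' Formats: \code{tiff} (32-bit float, values min-max scaled to [0, 1]
#' with an alpha channel carrying validity and a sidecar JSON recording
#' the scale), \code{png} (8-bit heatmap through a 256-color ramp for
#' value maps, or the compartment palette for label maps; invalid
#' pixels transparent; sidecar JSON with the color scale) and
#' \code{csv} (lossless: row, col, value, valid).
#'
#' @param map the map to export.
#' @param path output file; the sidecar is written to \code{path.json}.
#' @param format \code{"tiff"}, \code{"png"} or \code{"csv"}.
#' @param palette for label maps, a vector of colors (one per cluster;
#'   default: compartment palette order red, yellow, green, cyan,
#'   blue, ...).
#' @return invisibly, the path.
#' @export
exportMap <- function(map, path, format = c("png", "tiff", "csv"),
                      palette = NULL) {
  if (!is.character(format) || !format[1] %in% c("png", "tiff", "csv"))
    stop("usage error: unsupported format '", format[1], "'")
  format <- format[1]
  m <- .mapMatrix(map)
  ok <- .mapValid(map)
  if (format == "csv") {
    d <- cubeDim(map)
    npix <- prod(d)
    vals <- as.vector(t(m))
    dt <- data.table::data.table(
      row = (seq_len(npix) - 1L) %/% d["width"],
      col = (seq_len(npix) - 1L) %% d["width"],
      value = vals, valid = as.integer(as.vector(t(ok))))
    data.table::fwrite(dt, path)
    return(invisible(path))
  }
  isLabels <- is(map, "ClusterResult")
  if (format == "tiff") {
    v <- m[ok]
    lo <- if (length(v)) min(v) else 0
    hi <- if (length(v)) max(v) else 1
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    scaled[!ok] <- 0
    img <- array(0, dim = c(nrow(m), ncol(m), 2))
    img[, , 1] <- scaled
    img[, , 2] <- ok * 1
    tiff::writeTIFF(img, path, bits.per.sample = 32, reduce = FALSE)
    jsonlite::write_json(list(min = lo, max = hi, invalid = "alpha=0"),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  # png
  img <- array(0, dim = c(nrow(m), ncol(m), 4))
  if (isLabels) {
    k <- map@k
    if (is.null(palette))
      palette <- c("red", "yellow", "green", "cyan", "blue", "magenta",
                   "orange", "gray")[seq_len(k)]
    rgbm <- grDevices::col2rgb(palette) / 255
    for (i in seq_len(k)) {
      sel <- ok & m == i - 1
      img[, , 1][sel] <- rgbm[1, i]
      img[, , 2][sel] <- rgbm[2, i]
      img[, , 3][sel] <- rgbm[3, i]
    }
    scale <- list(type = "labels", palette = palette)
  } else {
    v <- m[ok]
    lo <- if (length(v)) min(v) else 0
    hi <- if (length(v)) max(v) else 1
    ramp <- grDevices::hcl.colors(256, "viridis")
    idx <- matrix(1L, nrow(m), ncol(m))
    if (hi > lo)
      idx[ok] <- pmin(255L, pmax(0L,
        as.integer(round(255 * (m[ok] - lo) / (hi - lo))))) + 1L
    rgbm <- grDevices::col2rgb(ramp) / 255
    img[, , 1] <- matrix(rgbm[1, idx], nrow(m))
    img[, , 2] <- matrix(rgbm[2, idx], nrow(m))
    img[, , 3] <- matrix(rgbm[3, idx], nrow(m))
    scale <- list(type = "heatmap", min = lo, max = hi,
                  palette = "viridis")
  }
  img[, , 4] <- ok * 1
  png::writePNG(img, path)
  jsonlite::write_json(scale, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
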