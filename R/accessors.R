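#' @name accessors
#' @title Accessors for ramanMQA objects
#' @description Slot accessors for the core classes; user code should use
#'   these rather than \code{@}.
#' @param object a ramanMQA object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumber", function(object) standardGeneric("wavenumber"))
#' @rdname accessors
#' @export
setMethod("wavenumber", "Spectrum", function(object) object@wavenumber)
#' @rdname accessors
#' @export
setMethod("wavenumber", "RamanCube", function(object) object@wavenumber)
#' @rdname accessors
#' @export
setMethod("wavenumber", "ClusterResult", function(object) object@wavenumber)
#' @rdname accessors
#' @export
setMethod("wavenumber", "UnmixResult", function(object) object@wavenumber)

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))
#' @rdname accessors
#' @export
setMethod("spectra", "RamanCube", function(object) object@spectra)

#' @rdname accessors
#' @export
setGeneric("cubeDim", function(object) standardGeneric("cubeDim"))
.dimMethod <- function(object) c(height = object@height, width = object@width)
#' @rdname accessors
#' @export
setMethod("cubeDim", "RamanCube", .dimMethod)
#' @rdname accessors
#' @export
setMethod("cubeDim", "SpatialMap", .dimMethod)
#' @rdname accessors
#' @export
setMethod("cubeDim", "ClusterResult", .dimMethod)
#' @rdname accessors
#' @export
setMethod("cubeDim", "UnmixResult", .dimMethod)
#' @rdname accessors
#' @export
setMethod("cubeDim", "PhantomTruth", .dimMethod)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "RamanCube", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "RamanCube", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("validMask", "SpatialMap", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "SpatialMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "PhantomTruth",
          function(object) object@labels - 1L)

#' @rdname accessors
#' @export
setGeneric("meanSpectra", function(object) standardGeneric("meanSpectra"))
#' @rdname accessors
#' @export
setMethod("meanSpectra", "ClusterResult", function(object) object@meanSpectra)

#' @rdname accessors
#' @export
setGeneric("endmembers", function(object) standardGeneric("endmembers"))
#' @rdname accessors
#' @export
setMethod("endmembers", "UnmixResult", function(object) object@endmembers)

#' @rdname accessors
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "UnmixResult", function(object) object@abundances)

#' @rdname accessors
#' @export
setGeneric("unmixResiduals", function(object) standardGeneric("unmixResiduals"))
#' @rdname accessors
#' @export
setMethod("unmixResiduals", "UnmixResult", function(object) object@residual)

#' @rdname accessors
#' @export
setGeneric("windowCenter", function(object) standardGeneric("windowCenter"))
#' @rdname accessors
#' @export
setMethod("windowCenter", "PeakWindow", function(object) object@center)

#' @rdname accessors
#' @export
setGeneric("windowHalfWidth",
           function(object) standardGeneric("windowHalfWidth"))
#' @rdname accessors
#' @export
setMethod("windowHalfWidth", "PeakWindow", function(object) object@halfWidth)

#' @rdname accessors
#' @export
setGeneric("windowLabel", function(object) standardGeneric("windowLabel"))
#' @rdname accessors
#' @export
setMethod("windowLabel", "PeakWindow", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("libraryEntries", function(object) standardGeneric("libraryEntries"))
#' @rdname accessors
#' @export
setMethod("libraryEntries", "PeakLibrary", function(object) object@entries)

#' @rdname accessors
#' @export
setGeneric("libraryExclusions",
           function(object) standardGeneric("libraryExclusions"))
#' @rdname accessors
#' @export
setMethod("libraryExclusions", "PeakLibrary",
          function(object) object@exclusions)

#' @rdname accessors
#' @export
setGeneric("calibrationSlope",
           function(object) standardGeneric("calibrationSlope"))
#' @rdname accessors
#' @export
setMethod("calibrationSlope", "CalibrationFit", function(object) object@slope)

#' @rdname accessors
#' @export
setGeneric("calibrationIntercept",
           function(object) standardGeneric("calibrationIntercept"))
#' @rdname accessors
#' @export
setMethod("calibrationIntercept", "CalibrationFit",
          function(object) object@intercept)

#' @rdname accessors
#' @export
setGeneric("calibrationRSquared",
           function(object) standardGeneric("calibrationRSquared"))
#' @rdname accessors
#' @export
setMethod("calibrationRSquared", "CalibrationFit",
          function(object) object@rSquared)

#' @rdname accessors
#' @export
setGeneric("trueConcentrations",
           function(object) standardGeneric("trueConcentrations"))
#' @rdname accessors
#' @export
setMethod("trueConcentrations", "PhantomTruth",
          function(object) object@concentrations)

#' @rdname accessors
#' @export
setGeneric("compartmentMasks",
           function(object) standardGeneric("compartmentMasks"))
#' @rdname accessors
#' @export
setMethod("compartmentMasks", "PhantomTruth", function(object) {
  out <- lapply(seq_along(object@compartments), function(i)
    !is.na(object@labels) & object@labels == i)
  names(out) <- object@compartments
  out
})

#' Convert between 0-based (row, col) and pixel index
#'
#' Pixels are row-major with the origin at the top-left: pixel (row, col)
#' (0-based) is element \code{row * width + col + 1} of a per-pixel vector.
#'
#' @param object an object with a pixel grid.
#' @param row,col 0-based pixel coordinates.
#' @return 1-based linear index into per-pixel vectors.
#' @export
pixelIndex <- function(object, row, col) {
  d <- cubeDim(object)
  stopifnot(all(row >= 0), all(row < d["height"]),
            all(col >= 0), all(col < d["width"]))
  as.integer(row) * as.integer(d["width"]) + as.integer(col) + 1L
}

#' Reshape a per-pixel vector to a height x width matrix
#'
#' @param values per-pixel vector in row-major order.
#' @param object an object with a pixel grid (supplies the dimensions).
#' @return matrix with \code{height} rows and \code{width} columns.
#' @export
asImage <- function(values, object) {
  d <- cubeDim(object)
  matrix(values, nrow = d["height"], ncol = d["width"], byrow = TRUE)
}

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumber
  cat(sprintf("Spectrum: %d channels, %.1f..%.1f cm^-1\n",
              length(w), min(w), max(w)))
})

setMethod("show", "RamanCube", function(object) {
  w <- object@wavenumber
  cat(sprintf(
    "RamanCube: %d x %d pixels (%.0f nm), %d channels %.1f..%.1f cm^-1, %d/%d valid\n",
    object@height, object@width, object@pixelSize, length(w), min(w), max(w),
    sum(object@mask), length(object@mask)))
})

setMethod("show", "PeakWindow", function(object) {
  cat(sprintf("PeakWindow: %g +/- %g cm^-1%s\n", object@center,
              object@halfWidth,
              if (nzchar(object@label)) paste0(" [", object@label, "]") else ""))
})

setMethod("show", "AreaMap", function(object) {
  cat(sprintf("AreaMap (%g +/- %g cm^-1): %d x %d, %d valid pixels\n",
              object@window@center, object@window@halfWidth,
              object@height, object@width, sum(object@valid)))
})

setMethod("show", "RatioMap", function(object) {
  cat(sprintf(
    "RatioMap (%g/%g cm^-1): %d x %d, %d valid, %d negative-flagged\n",
    object@numeratorWindow@center, object@denominatorWindow@center,
    object@height, object@width, sum(object@valid),
    sum(object@flaggedNegative)))
})

setMethod("show", "ClusterResult", function(object) {
  tab <- table(object@labels)
  cat(sprintf("ClusterResult: k = %d on %d x %d grid (seed %d)\n",
              object@k, object@height, object@width, object@seed))
  cat("  pixels per cluster:", paste(as.integer(tab), collapse = ", "), "\n")
})

setMethod("show", "UnmixResult", function(object) {
  cat(sprintf(
    "UnmixResult: %d endmembers, %d x %d grid, median residual %.3g\n",
    object@nComponents, object@height, object@width,
    median(object@residual, na.rm = TRUE)))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit: dA = %.4g * c + %.4g  (R^2 = %.6f, n = %d)\n",
    object@slope, object@intercept, object@rSquared, object@nPoints))
})

setMethod("show", "PeakLibrary", function(object) {
  cat(sprintf("PeakLibrary: %d metabolites, %d exclusion windows, tol %g cm^-1\n",
              length(object@entries), length(object@exclusions),
              object@matchTolerance))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d x %d grid, seed %d, compartments: %s\n",
              object@height, object@width, object@seed,
              paste(object@compartments, collapse = ", ")))
})
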