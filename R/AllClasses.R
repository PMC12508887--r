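#' @import methods
#' @importFrom stats kmeans prcomp lm median mad sd var coef dist approx
#' @importFrom utils head modifyList
#' @useDynLib ramanMQA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.checkAxis <- function(w) {
  if (length(w) < 16L)
    return("wavenumber axis must have at least 16 channels")
  if (anyNA(w) || any(!is.finite(w)))
    return("wavenumber axis must be finite")
  if (any(diff(w) <= 0))
    return("wavenumber axis must be strictly increasing")
  TRUE
}

#' Spectrum: a single Raman spectrum
#'
#' A single spectrum on a wavenumber axis (Raman shift, cm^-1).  The axis
#' must be strictly increasing with at least 16 channels; intensities are
#' in arbitrary units and must be finite.
#'
#' @slot wavenumber numeric, strictly increasing Raman shifts (cm^-1).
#' @slot intensity numeric, same length as \code{wavenumber}.
#' @export
setClass("Spectrum",
  representation(wavenumber = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    ax <- .checkAxis(object@wavenumber)
    if (is.character(ax)) msg <- c(msg, ax)
    if (length(object@intensity) != length(object@wavenumber))
      msg <- c(msg, "intensity length must equal axis length")
    if (anyNA(object@intensity) || any(!is.finite(object@intensity)))
      msg <- c(msg, "intensity must be finite (no NaN/Inf)")
    if (length(msg)) msg else TRUE
  })

#' Construct a Spectrum
#'
#' @param wavenumber strictly increasing Raman shifts in cm^-1 (>= 16 channels).
#' @param intensity intensities, one per channel (arbitrary units).
#' @return A \linkS4class{Spectrum}.
#' @examples
#' s <- Spectrum(seq(400, 1800, by = 2), dnorm(seq(400, 1800, by = 2), 1006, 6))
#' @export
Spectrum <- function(wavenumber, intensity) {
  new("Spectrum", wavenumber = as.numeric(wavenumber),
      intensity = as.numeric(intensity))
}

#' RamanCube: a hyperspectral Raman image
#'
#' A width x height pixel grid where every pixel holds a full Raman
#' spectrum on one shared wavenumber axis.  Pixels are stored row-major
#' with the origin at the top-left and 0-based (row, col) addressing;
#' spectra are the rows of the \code{spectra} matrix (pixels x channels).
#' The optional mask marks valid pixels; masked pixels carry no meaning
#' in downstream statistics.
#'
#' @slot wavenumber shared axis, strictly increasing cm^-1, >= 16 channels.
#' @slot spectra numeric matrix, one pixel per row (row-major order),
#'   one channel per column.
#' @slot width,height integer pixel counts.
#' @slot pixelSize pixel spacing in nm (> 0; 450 by default, the scan
#'   step of a typical confocal area scan).
#' @slot mask logical, TRUE for valid pixels.
#' @export
setClass("RamanCube",
  representation(wavenumber = "numeric", spectra = "matrix",
                 width = "integer", height = "integer",
                 pixelSize = "numeric", mask = "logical"),
  validity = function(object) {
    msg <- character()
    ax <- .checkAxis(object@wavenumber)
    if (is.character(ax)) msg <- c(msg, ax)
    npix <- object@width * object@height
    if (nrow(object@spectra) != npix)
      msg <- c(msg, sprintf("spectra has %d rows; expected width*height = %d",
                            nrow(object@spectra), npix))
    if (ncol(object@spectra) != length(object@wavenumber))
      msg <- c(msg, "spectra column count must equal axis length")
    if (length(object@mask) != npix)
      msg <- c(msg, "mask length must equal pixel count")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number (nm)")
    if (!length(msg) && any(object@mask) &&
        !all(is.finite(object@spectra[object@mask, , drop = FALSE])))
      msg <- c(msg, "unmasked spectra must be finite (no NaN/Inf)")
    if (length(msg)) msg else TRUE
  })

#' Construct a RamanCube
#'
#' @param spectra pixels x channels matrix, pixels in row-major order
#'   (index of pixel (row, col), 0-based, is \code{row * width + col + 1}).
#' @param wavenumber shared wavenumber axis (cm^-1).
#' @param width,height grid size in pixels.
#' @param pixelSize pixel spacing in nm; default 450.
#' @param mask optional logical vector of valid pixels (default all valid).
#' @return A \linkS4class{RamanCube}.
#' @export
RamanCube <- function(spectra, wavenumber, width, height,
                      pixelSize = 450, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, width * height)
  new("RamanCube", spectra = as.matrix(spectra),
      wavenumber = as.numeric(wavenumber),
      width = as.integer(width), height = as.integer(height),
      pixelSize = as.numeric(pixelSize), mask = as.logical(mask))
}

#' PeakWindow: a closed wavenumber integration window
#'
#' A metabolite band described as center +/- half-width (cm^-1), the
#' interval over which band area is integrated.
#'
#' @slot center band center in cm^-1.
#' @slot halfWidth half-width in cm^-1 (> 0; default 8).
#' @slot label metabolite name or "".
#' @export
setClass("PeakWindow",
  representation(center = "numeric", halfWidth = "numeric",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 1L || !is.finite(object@center))
      msg <- c(msg, "center must be a single finite number")
    if (length(object@halfWidth) != 1L || !is.finite(object@halfWidth) ||
        object@halfWidth <= 0)
      msg <- c(msg, "halfWidth must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a PeakWindow
#'
#' @param center band center (cm^-1).
#' @param halfWidth half-width (cm^-1), default 8.
#' @param label metabolite name, default "".
#' @return A \linkS4class{PeakWindow}.
#' @examples
#' PeakWindow(484, label = "glycogen")
#' @export
PeakWindow <- function(center, halfWidth = 8, label = "") {
  new("PeakWindow", center = as.numeric(center),
      halfWidth = as.numeric(halfWidth), label = as.character(label))
}

#' SpatialMap: per-pixel scalar maps over a cube grid
#'
#' Virtual parent of \linkS4class{AreaMap} and \linkS4class{RatioMap}:
#' a per-pixel value plus a validity flag, on the same grid as the
#' source cube.  Invalid pixels carry no numeric meaning downstream.
#'
#' @slot values per-pixel values (row-major; NA where invalid).
#' @slot valid logical per-pixel validity flags.
#' @slot width,height grid size.
#' @export
setClass("SpatialMap",
  representation("VIRTUAL", values = "numeric", valid = "logical",
                 width = "integer", height = "integer"),
  validity = function(object) {
    npix <- object@width * object@height
    msg <- character()
    if (length(object@values) != npix)
      msg <- c(msg, "values length must equal width*height")
    if (length(object@valid) != npix)
      msg <- c(msg, "valid length must equal width*height")
    if (any(object@valid) && anyNA(object@values[object@valid]))
      msg <- c(msg, "valid pixels must carry finite values")
    if (length(msg)) msg else TRUE
  })

#' AreaMap: per-pixel integrated band area
#'
#' Per-pixel trapezoidal integral A of intensity over a
#' \linkS4class{PeakWindow} (arbitrary units x cm^-1).
#'
#' @slot window the integrated \linkS4class{PeakWindow}.
#' @export
setClass("AreaMap", contains = "SpatialMap",
  representation(window = "PeakWindow"))

#' RatioMap: internal-standard-normalized band area
#'
#' Per-pixel ratio dA = A_metabolite / A_internal_standard; dimensionless
#' and invariant under per-pixel multiplicative rescaling of the source
#' spectra.  Valid only where both operand areas are valid and the
#' denominator exceeds the floor epsilon; negative operand areas are kept
#' but flagged.
#'
#' @slot numeratorWindow,denominatorWindow the operand windows.
#' @slot flaggedNegative logical, TRUE where an operand area was negative.
#' @export
setClass("RatioMap", contains = "SpatialMap",
  representation(numeratorWindow = "PeakWindow",
                 denominatorWindow = "PeakWindow",
                 flaggedNegative = "logical"))

#' ClusterResult: K-means compartment map
#'
#' Hard per-pixel labels in [0, k) with per-cluster mean spectra (the
#' arithmetic mean over member pixels of the clustered cube).
#'
#' @slot k cluster count.
#' @slot labels integer per-pixel labels, 0-based; NA where masked.
#' @slot meanSpectra k x channels matrix of cluster mean spectra.
#' @slot wavenumber shared axis of the mean spectra.
#' @slot inertia total within-cluster sum of squares (in the clustered
#'   feature space).
#' @slot seed RNG seed used.
#' @slot width,height grid size.
#' @export
setClass("ClusterResult",
  representation(k = "integer", labels = "integer", meanSpectra = "matrix",
                 wavenumber = "numeric", inertia = "numeric",
                 seed = "integer", width = "integer", height = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) != object@width * object@height)
      msg <- c(msg, "labels length must equal width*height")
    lab <- object@labels[!is.na(object@labels)]
    if (length(lab) && (min(lab) < 0L || max(lab) >= object@k))
      msg <- c(msg, "labels must lie in [0, k)")
    if (nrow(object@meanSpectra) != object@k)
      msg <- c(msg, "meanSpectra must have one row per cluster")
    if (ncol(object@meanSpectra) != length(object@wavenumber))
      msg <- c(msg, "meanSpectra columns must match axis length")
    if (length(msg)) msg else TRUE
  })

#' UnmixResult: endmember spectra and non-negative abundances
#'
#' Linear-unmixing ("true component analysis") result: component spectra
#' (endmembers) with per-pixel non-negative least-squares abundances and
#' the per-pixel reconstruction RMS residual.
#'
#' @slot nComponents component count.
#' @slot endmembers nComponents x channels matrix of component spectra.
#' @slot abundances pixels x nComponents non-negative coefficients.
#' @slot residual per-pixel reconstruction RMS (NA where masked).
#' @slot wavenumber shared axis.
#' @slot width,height grid size.
#' @slot seed RNG seed recorded for provenance.
#' @export
setClass("UnmixResult",
  representation(nComponents = "integer", endmembers = "matrix",
                 abundances = "matrix", residual = "numeric",
                 wavenumber = "numeric", width = "integer",
                 height = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@endmembers) != object@nComponents)
      msg <- c(msg, "endmembers must have one row per component")
    if (ncol(object@abundances) != object@nComponents)
      msg <- c(msg, "abundances must have one column per component")
    a <- object@abundances[!is.na(object@abundances)]
    if (length(a) && min(a) < 0)
      msg <- c(msg, "abundances must be non-negative")
    if (length(object@residual) != object@width * object@height)
      msg <- c(msg, "residual length must equal width*height")
    if (length(msg)) msg else TRUE
  })

#' CalibrationFit: ordinary least-squares calibration line
#'
#' Fit of dA = slope * concentration + intercept over a calibration
#' series, with the coefficient of determination.
#'
#' @slot slope,intercept OLS coefficients (per concentration unit).
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot nPoints number of calibration points.
#' @export
setClass("CalibrationFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nPoints = "integer"),
  validity = function(object) {
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
      "rSquared must lie in [0, 1]" else TRUE
  })

#' PeakLibrary: curated metabolite band table
#'
#' Named metabolite bands (each a list of \linkS4class{PeakWindow}s with
#' a free-text assignment note, kept deliberately tentative) plus
#' fixation-artifact exclusion windows.  No entry window may overlap an
#' exclusion window.
#'
#' @slot entries named list; each element is \code{list(windows = list of
#'   PeakWindow, note = character)}.
#' @slot exclusions list of \linkS4class{PeakWindow} to exclude from
#'   assignment (fixation artifacts).
#' @slot matchTolerance assignment tolerance in cm^-1 (default 8).
#' @export
setClass("PeakLibrary",
  representation(entries = "list", exclusions = "list",
                 matchTolerance = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in names(object@entries)) {
      e <- object@entries[[nm]]
      if (!length(e$windows))
        msg <- c(msg, sprintf("entry '%s' has no windows", nm))
      for (w in e$windows) for (x in object@exclusions) {
        if (abs(w@center - x@center) < w@halfWidth + x@halfWidth)
          msg <- c(msg, sprintf(
            "entry '%s' window %g overlaps exclusion window %g",
            nm, w@center, x@center))
      }
    }
    if (length(object@matchTolerance) != 1L || object@matchTolerance <= 0)
      msg <- c(msg, "matchTolerance must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: ground truth for a synthetic cell phantom
#'
#' Everything needed to score an analysis of a synthetic cube against
#' its construction: compartment labels, per-metabolite concentration
#' fields, the per-pixel gain field, reference spectra, and the noise,
#' baseline and spike parameters together with the seed, so every
#' phantom is reproducible bit-exactly.
#'
#' @slot labels integer per-pixel compartment labels (1 = nucleus,
#'   2 = lipid droplets, 3 = symbiont strain A, 4 = symbiont strain B,
#'   5 = cytoplasm; NA outside the cell).
#' @slot compartments character names for the label codes.
#' @slot concentrations pixels x metabolites matrix of true
#'   concentration fields (arbitrary concentration units, >= 0).
#' @slot gain per-pixel multiplicative gain field (> 0).
#' @slot referenceSpectra metabolites x channels matrix of the pure
#'   reference spectra used to mix the cube.
#' @slot wavenumber shared axis.
#' @slot noise,baseline,spikes generation parameters (lists / data.frame).
#' @slot seed integer seed.
#' @slot width,height grid size.
#' @export
setClass("PhantomTruth",
  representation(labels = "integer", compartments = "character",
                 concentrations = "matrix", gain = "numeric",
                 referenceSpectra = "matrix", wavenumber = "numeric",
                 noise = "list", baseline = "list", spikes = "data.frame",
                 seed = "integer", width = "integer", height = "integer"),
  validity = function(object) {
    msg <- character()
    npix <- object@width * object@height
    if (length(object@labels) != npix)
      msg <- c(msg, "labels length must equal width*height")
    if (nrow(object@concentrations) != npix)
      msg <- c(msg, "concentrations must have one row per pixel")
    cc <- object@concentrations[!is.na(object@concentrations)]
    if (length(cc) && min(cc) < 0)
      msg <- c(msg, "concentration fields must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' PreprocessConfig: preprocessing stage parameters
#'
#' Parameters for despiking, baseline correction, Savitzky-Golay
#' smoothing and PCA denoising, plus the stage order.
#'
#' @slot crrZscoreThreshold modified z-score threshold for cosmic-ray
#'   flagging (dimensionless, default 8).
#' @slot baselineMethod "asls" (asymmetric least squares) or "poly"
#'   (iterative polynomial).
#' @slot aslsLambda,aslsP,aslsMaxIter AsLS smoother weight, asymmetry
#'   and iteration cap.
#' @slot polyDegree polynomial degree for the "poly" method.
#' @slot sgWindow,sgOrder Savitzky-Golay window (odd channel count) and
#'   polynomial order.
#' @slot pcaVariance cumulative explained-variance target in (0, 1].
#' @slot pcaComponents explicit component count (NA = use pcaVariance).
#' @slot stageOrder permutation of subset of c("crr","baseline","sg","pca").
#' @export
setClass("PreprocessConfig",
  representation(crrZscoreThreshold = "numeric", baselineMethod = "character",
                 aslsLambda = "numeric", aslsP = "numeric",
                 aslsMaxIter = "integer", polyDegree = "integer",
                 sgWindow = "integer", sgOrder = "integer",
                 pcaVariance = "numeric", pcaComponents = "integer",
                 stageOrder = "character"),
  validity = function(object) {
    msg <- character()
    if (object@crrZscoreThreshold <= 0)
      msg <- c(msg, "crrZscoreThreshold must be strictly positive")
    if (!object@baselineMethod %in% c("asls", "poly"))
      msg <- c(msg, "baselineMethod must be 'asls' or 'poly'")
    if (object@aslsLambda <= 0 || object@aslsP <= 0 || object@aslsP >= 1)
      msg <- c(msg, "aslsLambda must be > 0 and aslsP in (0, 1)")
    if (object@sgWindow %% 2L == 0L)
      msg <- c(msg, "sgWindow must be odd")
    if (object@sgWindow <= object@sgOrder)
      msg <- c(msg, "sgWindow must exceed sgOrder")
    if (!is.na(object@pcaVariance) &&
        (object@pcaVariance <= 0 || object@pcaVariance > 1))
      msg <- c(msg, "pcaVariance must lie in (0, 1]")
    if (!all(object@stageOrder %in% c("crr", "baseline", "sg", "pca")))
      msg <- c(msg, "stageOrder entries must be crr/baseline/sg/pca")
    if (anyDuplicated(object@stageOrder))
      msg <- c(msg, "stageOrder must not repeat stages")
    if (length(msg)) msg else TRUE
  })

#' Construct a PreprocessConfig
#'
#' Defaults: despike first (spikes corrupt baseline estimation), then
#' AsLS baseline correction (lambda 1e6, p 0.01; the stiff smoother
#' keeps the correction idempotent and preserves band tails), then
#' Savitzky-Golay
#' smoothing (window 9, order 3).  PCA denoising is off by default in
#' quantification paths because low-rank reconstruction can redistribute
#' band area; include "pca" in \code{stageOrder} to enable it.
#'
#' @param crrZscoreThreshold cosmic-ray modified z-score threshold.
#' @param baselineMethod "asls" or "poly".
#' @param aslsLambda,aslsP,aslsMaxIter AsLS parameters.
#' @param polyDegree degree for the polynomial baseline.
#' @param sgWindow,sgOrder Savitzky-Golay window and order.
#' @param pcaVariance explained-variance target in (0, 1].
#' @param pcaComponents explicit PCA component count (overrides
#'   \code{pcaVariance} when not NA).
#' @param stageOrder character vector of stages to run, in order.
#' @return A \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(crrZscoreThreshold = 8,
                             baselineMethod = "asls",
                             aslsLambda = 1e6, aslsP = 0.01,
                             aslsMaxIter = 20L, polyDegree = 3L,
                             sgWindow = 9L, sgOrder = 3L,
                             pcaVariance = 0.99, pcaComponents = NA_integer_,
                             stageOrder = c("crr", "baseline", "sg")) {
  new("PreprocessConfig",
      crrZscoreThreshold = as.numeric(crrZscoreThreshold),
      baselineMethod = baselineMethod,
      aslsLambda = as.numeric(aslsLambda), aslsP = as.numeric(aslsP),
      aslsMaxIter = as.integer(aslsMaxIter),
      polyDegree = as.integer(polyDegree),
      sgWindow = as.integer(sgWindow), sgOrder = as.integer(sgOrder),
      pcaVariance = as.numeric(pcaVariance),
      pcaComponents = as.integer(pcaComponents),
      stageOrder = as.character(stageOrder))
}
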