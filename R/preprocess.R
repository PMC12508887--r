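#' Calibrate the wavenumber axis against a silicon reference
#'
#' Locates the apex of the reference band (by quadratic interpolation of
#' the three channels around the grid maximum) within a search window
#' around \code{referencePosition}, and applies the rigid offset that
#' maps the detected apex onto \code{referencePosition} to the target's
#' axis.  The shipped default reference position is the 520 cm^-1
#' first-order phonon band of a silicon wafer, the conventional
#' single-point calibrant for Raman microscopes.
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{RamanCube} whose
#'   axis is to be shifted.
#' @param reference a \linkS4class{Spectrum} of the calibrant, measured
#'   on the same raw axis.
#' @param referencePosition true band position in cm^-1 (default 520).
#' @param searchHalfWidth half-width of the apex search window (cm^-1).
#' @return list with \code{result} (x with shifted axis), \code{offset}
#'   (cm^-1 added to the axis) and \code{apex} (detected raw apex).
#' @examples
#' w <- seq(400, 700, by = 2)
#' si <- Spectrum(w, exp(-(w - 522.5)^2 / (2 * 4^2)))
#' cal <- calibrateAxis(si, si)
#' cal$offset    # -2.5
#' @export
calibrateAxis <- function(x, reference, referencePosition = 520,
                          searchHalfWidth = 30) {
  w <- wavenumber(reference)
  y <- intensity(reference)
  win <- which(abs(w - referencePosition) <= searchHalfWidth)
  if (length(win) < 3L)
    stop("calibration error: search window covers fewer than 3 channels")
  i <- win[which.max(y[win])]
  if (i <= 1L || i >= length(w) ||
      y[i] <= y[max(1L, i - 1L)] && y[i] <= y[min(length(w), i + 1L)])
    stop("calibration error: no interior peak in the search window")
  if (i == win[1L] || i == win[length(win)])
    stop("calibration error: maximum lies on the search-window boundary")
  apex <- .quadApex(w[(i - 1L):(i + 1L)], y[(i - 1L):(i + 1L)])
  offset <- referencePosition - apex
  if (abs(offset) > 15)
    warning(sprintf("axis calibration offset %.2f cm^-1 exceeds 15 cm^-1",
                    offset))
  result <- x
  result@wavenumber <- wavenumber(x) + offset
  validObject(result)
  list(result = result, offset = offset, apex = apex)
}

# channel-wise median spectrum of the valid 8-connected neighbors of
# pixel (r, c); NULL when fewer than minNeighbors are available
.neighborMedian <- function(S, mask, width, height, r, c,
                            minNeighbors = 3L) {
  rr <- rep(r + (-1:1), each = 3L)
  cc <- rep(c + (-1:1), times = 3L)
  keep <- (rr >= 0 & rr < height & cc >= 0 & cc < width) &
    !(rr == r & cc == c)
  idx <- rr[keep] * width + cc[keep] + 1L
  idx <- idx[mask[idx]]
  if (length(idx) < minNeighbors) return(NULL)
  .colMedianCpp(S[idx, , drop = FALSE])
}

#' Remove cosmic-ray spikes from a cube
#'
#' Detector hits produce one- or few-channel intensity spikes unrelated
#' to the sample.  For each pixel the deviation from the channel-wise
#' median spectrum of its valid 8-connected spatial neighbors is scored
#' with a modified z-score (0.6745 * (d - median d) / MAD d).  Because
#' genuine spectral differences between neighboring pixels (compartment
#' boundaries, gain variation) are spectrally broad while detector hits
#' are one-to-few channels wide, a channel is only flagged when it also
#' exceeds the threshold on the modified z-score of the spectral second
#' difference; flagged channels are replaced by linear interpolation
#' across each flagged run.  Where fewer than 3 valid neighbors exist
#' (single-pixel inputs, isolated pixels), the spectral score alone is
#' used.  Unflagged channels are never altered.
#'
#' @param cube a \linkS4class{RamanCube} (>= 2 channels).
#' @param config a \linkS4class{PreprocessConfig}.
#' @return list with \code{cube} (despiked) and \code{report}, a
#'   data.frame of every replacement (row, col, channel, wavenumber,
#'   original, replaced).
#' @export
removeCosmicRays <- function(cube, config = preprocessConfig()) {
  S <- spectra(cube)
  if (ncol(S) < 2L) stop("cube must have at least 2 channels")
  mask <- validMask(cube)
  w <- wavenumber(cube)
  d <- cubeDim(cube)
  thr <- config@crrZscoreThreshold
  rows <- integer(0); cols <- integer(0); chans <- integer(0)
  orig <- numeric(0); repl <- numeric(0)
  newMask <- mask
  # modified z-score with a channel-local scale: the shot-noise variance
  # tracks the signal, so a global MAD over-flags strong-signal channels;
  # a running-median MAD adapts while staying immune to isolated spikes
  modZ <- function(dev) {
    n <- length(dev)
    win <- min(15L, if (n %% 2L) n else n - 1L)
    ctr <- if (n >= 3L) stats::runmed(dev, win, endrule = "constant") else
      rep(median(dev), n)
    res <- dev - ctr
    sc <- if (n >= 3L) stats::runmed(abs(res), win, endrule = "constant") else
      rep(median(abs(res)), n)
    gl <- median(abs(res))
    # flat (e.g. noiseless) stretches: fall back to the mean absolute
    # residual so isolated spikes are still scored and 0/0 is avoided
    if (gl == 0) gl <- mean(abs(res))
    if (gl == 0) return(rep(0, n))
    sc <- pmax(sc, 0.25 * gl)
    0.6745 * res / sc
  }
  for (px in which(mask)) {
    r <- (px - 1L) %/% d["width"]
    c <- (px - 1L) %% d["width"]
    ref <- .neighborMedian(S, mask, d["width"], d["height"], r, c)
    x <- S[px, ]
    # spectral second difference: spikes are one-to-few channels wide,
    # so they are outliers of this score too, while genuine band
    # differences between neighboring pixels are spectrally broad
    nx <- length(x)
    specDev <- c(x[1L] - x[2L],
                 x[-c(1L, nx)] - 0.5 * (x[-((nx - 1L):nx)] + x[-(1:2)]),
                 x[nx] - x[nx - 1L])
    zSpec <- modZ(specDev)
    flag <- if (is.null(ref)) zSpec > thr else
      (modZ(x - ref) > thr) & (zSpec > thr)
    if (!any(flag)) next
    if (all(flag)) {
      newMask[px] <- FALSE
      warning(sprintf("all channels flagged at pixel (%d, %d); pixel masked",
                      r, c))
      next
    }
    good <- which(!flag)
    if (length(good) < 2L) {
      newMask[px] <- FALSE
      warning(sprintf("too few clean channels at pixel (%d, %d); pixel masked",
                      r, c))
      next
    }
    fixed <- x
    fixed[flag] <- approx(good, x[good], xout = which(flag), rule = 2)$y
    rows <- c(rows, rep(as.integer(r), sum(flag)))
    cols <- c(cols, rep(as.integer(c), sum(flag)))
    chans <- c(chans, which(flag))
    orig <- c(orig, x[flag]); repl <- c(repl, fixed[flag])
    S[px, ] <- fixed
  }
  out <- cube
  out@spectra <- S
  out@mask <- newMask
  list(cube = out,
       report = data.frame(row = rows, col = cols, channel = chans,
                           wavenumber = w[chans], original = orig,
                           replaced = repl))
}

.aslsBaseline <- function(y, lambda, p, maxIter) {
  .aslsBaselineCpp(as.numeric(y), lambda, p, as.integer(maxIter))
}

# iterative polynomial baseline: fit, clip the signal to the fit, refit
.polyBaseline <- function(y, w, degree, maxIter = 10L) {
  u <- (w - w[1]) / (w[length(w)] - w[1])
  yy <- y
  fit <- y
  for (i in seq_len(maxIter)) {
    fit <- stats::fitted(lm(yy ~ stats::poly(u, degree)))
    yy <- pmin(yy, fit)
  }
  fit
}

#' Subtract a smooth fluorescence baseline
#'
#' Default method is asymmetric least squares (AsLS): a Whittaker
#' smoother with asymmetric weights (p for points above the baseline,
#' 1 - p below) that relaxes under peaks while following the smooth
#' background, the de-facto standard for Raman fluorescence
#' backgrounds.  An iterative-polynomial alternative is provided for
#' gently curved backgrounds.  The estimated baseline is returned for
#' audit.
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{RamanCube}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return list with \code{result} (baseline-subtracted x) and
#'   \code{baseline} (numeric vector for a Spectrum, pixels x channels
#'   matrix for a cube).
#' @export
correctBaseline <- function(x, config = preprocessConfig()) {
  if (is(x, "Spectrum")) {
    if (length(x@wavenumber) < 2L * config@sgWindow)
      stop("too few channels for baseline estimation")
    bl <- switch(config@baselineMethod,
      asls = .aslsBaseline(x@intensity, config@aslsLambda, config@aslsP,
                           config@aslsMaxIter),
      poly = .polyBaseline(x@intensity, x@wavenumber, config@polyDegree))
    out <- Spectrum(x@wavenumber, x@intensity - bl)
    return(list(result = out, baseline = bl))
  }
  stopifnot(is(x, "RamanCube"))
  if (length(x@wavenumber) < 2L * config@sgWindow)
    stop("too few channels for baseline estimation")
  S <- spectra(x)
  mask <- validMask(x)
  B <- matrix(0, nrow(S), ncol(S))
  if (config@baselineMethod == "asls") {
    if (any(mask))
      B[mask, ] <- .aslsBaselineMatCpp(S[mask, , drop = FALSE],
                                       config@aslsLambda, config@aslsP,
                                       as.integer(config@aslsMaxIter))
  } else {
    for (px in which(mask))
      B[px, ] <- .polyBaseline(S[px, ], x@wavenumber, config@polyDegree)
  }
  out <- x
  out@spectra <- S - B
  list(result = out, baseline = B)
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay convolution (local least-squares polynomial
#' refit).  Edges are handled by refitting the truncated window rather
#' than mirror-padding, so no intensity is invented outside the measured
#' range; polynomials up to the filter order are reproduced exactly.
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{RamanCube}.
#' @param config a \linkS4class{PreprocessConfig} (uses \code{sgWindow},
#'   \code{sgOrder}).
#' @return smoothed object of the same class.
#' @export
smoothSavitzkyGolay <- function(x, config = preprocessConfig()) {
  n <- length(wavenumber(x))
  if (config@sgWindow > n)
    stop("config error: sgWindow exceeds channel count")
  if (config@sgWindow %% 2L == 0L || config@sgWindow <= config@sgOrder)
    stop("config error: sgWindow must be odd and greater than sgOrder")
  # projection matrix whose end rows refit the truncated window
  filt <- signal::sgolay(p = config@sgOrder, n = config@sgWindow)
  smooth1 <- function(y) as.numeric(signal::sgolayfilt(y, filt))
  if (is(x, "Spectrum"))
    return(Spectrum(x@wavenumber, smooth1(x@intensity)))
  stopifnot(is(x, "RamanCube"))
  out <- x
  S <- spectra(x)
  for (px in which(validMask(x))) S[px, ] <- smooth1(S[px, ])
  out@spectra <- S
  out
}

#' PCA denoising of a cube
#'
#' Reconstructs every valid spectrum from the leading principal
#' components, either an explicit count or the smallest count reaching
#' the configured cumulative explained variance.  The per-channel mean
#' spectrum is preserved exactly.  Off by default in quantification
#' paths, because low-rank reconstruction can redistribute band area.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return list with \code{cube} (reconstructed), \code{nComponents}
#'   and \code{explainedVariance} (cumulative fraction per component).
#' @export
pcaDenoise <- function(cube, config = preprocessConfig()) {
  if (!is.na(config@pcaVariance) &&
      (config@pcaVariance <= 0 || config@pcaVariance > 1))
    stop("config error: pcaVariance must lie in (0, 1]")
  mask <- validMask(cube)
  X <- spectra(cube)[mask, , drop = FALSE]
  if (!is.na(config@pcaComponents) && nrow(X) <= config@pcaComponents)
    stop("pixel count must exceed the retained component count")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- if (!is.na(config@pcaComponents)) min(config@pcaComponents, ncol(pc$x))
       else which(cum >= config@pcaVariance)[1L]
  Xhat <- pc$x[, seq_len(k), drop = FALSE] %*%
    t(pc$rotation[, seq_len(k), drop = FALSE])
  Xhat <- sweep(Xhat, 2L, pc$center, "+")
  out <- cube
  S <- spectra(cube)
  S[mask, ] <- Xhat
  out@spectra <- S
  list(cube = out, nComponents = k, explainedVariance = cum)
}

#' Run the preprocessing pipeline
#'
#' Applies the configured stages in \code{stageOrder}.  The default
#' order is crr, baseline, sg: despiking runs first because spikes
#' corrupt the baseline estimate; the order is configurable (e.g.
#' \code{c("baseline","crr","sg")}).  An empty stage list is the
#' identity.  A per-stage provenance log is attached.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return list with \code{cube} and \code{provenance} (one entry per
#'   stage: parameters plus stage-specific summaries such as the spike
#'   count or the PCA component count).
#' @export
runPreprocess <- function(cube, config = preprocessConfig()) {
  validObject(config)
  prov <- list()
  for (stage in config@stageOrder) {
    if (stage == "crr") {
      res <- removeCosmicRays(cube, config)
      cube <- res$cube
      prov[[length(prov) + 1L]] <- list(
        stage = "crr", threshold = config@crrZscoreThreshold,
        nReplacements = nrow(res$report))
    } else if (stage == "baseline") {
      res <- correctBaseline(cube, config)
      cube <- res$result
      prov[[length(prov) + 1L]] <- list(
        stage = "baseline", method = config@baselineMethod,
        lambda = config@aslsLambda, p = config@aslsP)
    } else if (stage == "sg") {
      cube <- smoothSavitzkyGolay(cube, config)
      prov[[length(prov) + 1L]] <- list(
        stage = "sg", window = config@sgWindow, order = config@sgOrder)
    } else if (stage == "pca") {
      res <- pcaDenoise(cube, config)
      cube <- res$cube
      prov[[length(prov) + 1L]] <- list(
        stage = "pca", nComponents = res$nComponents)
    }
  }
  list(cube = cube, provenance = prov)
}
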