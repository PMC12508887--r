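#' ReferenceSpectrum: a rendered pure-component spectrum
#'
#' A \linkS4class{Spectrum} rendered as a sum of pseudo-Voigt bands,
#' keeping the band table as metadata.
#'
#' @slot metabolite component name.
#' @slot bands data.frame with columns center, amplitude, sigma, eta.
#' @export
setClass("ReferenceSpectrum", contains = "Spectrum",
  representation(metabolite = "character", bands = "data.frame"))

#' Pseudo-Voigt profile
#'
#' Weighted Gaussian/Lorentzian mixture, unit amplitude at the center:
#' eta * Lorentzian + (1 - eta) * Gaussian, both with width parameter
#' sigma (the Lorentzian half-width is matched to sigma).
#'
#' @param x positions (cm^-1).
#' @param center band center.
#' @param sigma width (cm^-1).
#' @param eta Lorentzian fraction in [0, 1].
#' @return intensities (>= 0).
#' @export
pseudoVoigt <- function(x, center, sigma, eta = 0.3) {
  g <- exp(-(x - center)^2 / (2 * sigma^2))
  l <- 1 / (1 + ((x - center) / sigma)^2)
  eta * l + (1 - eta) * g
}

#' Render a reference spectrum from a band table
#'
#' Sum of pseudo-Voigt profiles; non-negative everywhere and exactly
#' linear in the band amplitudes.
#'
#' @param bands data.frame with columns center, amplitude, sigma and
#'   optionally eta (default 0.3).
#' @param axis wavenumber axis.
#' @param metabolite name stored with the result.
#' @return A \linkS4class{ReferenceSpectrum}.
#' @export
makeReferenceSpectrum <- function(bands, axis, metabolite = "") {
  stopifnot(all(bands$sigma > 0))
  if (is.null(bands$eta)) bands$eta <- rep(0.3, nrow(bands))
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amplitude[i] *
      pseudoVoigt(axis, bands$center[i], bands$sigma[i], bands$eta[i])
  new("ReferenceSpectrum", wavenumber = as.numeric(axis), intensity = y,
      metabolite = metabolite, bands = bands)
}

#' Band tables for the phantom's reference spectra
#'
#' Each metabolite combines its library marker bands with a few fixed
#' "filler" background bands (positions chosen away from every library
#' analysis window) so the simulated spectra overlap realistically
#' instead of being orthogonal indicator functions.  Amplitudes are
#' relative Raman cross-sections per concentration unit; widths are
#' sigma in cm^-1 (broader in the C-H stretch region).
#'
#' @return named list of band data.frames (center, amplitude, sigma, eta).
#' @export
defaultReferenceBands <- function() {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], amplitude = m[, 2], sigma = m[, 3],
               eta = 0.3)
  }
  list(
    nucleicAcid = b(1078, 1.0, 6,  1423, 0.8, 6,  780, 0.35, 6,
                    820, 0.20, 6),
    triglyceride = b(1746, 1.0, 6,  1300, 0.30, 6,  2850, 0.50, 10,
                     2890, 0.35, 10),
    palmitoleicAcid = b(1263, 0.7, 6,  1656, 0.9, 6,  3009, 0.8, 10,
                        2930, 0.50, 10,  1450, 0.30, 6),
    cholesterol = b(1083, 1.0, 6,  700, 0.35, 6,  2930, 0.40, 10,
                    1450, 0.25, 6),
    phenylalanine = b(1006, 1.0, 6,  620, 0.25, 6,  1030, 0.30, 6,
                      1600, 0.25, 6),
    lanosterol = b(930, 0.6, 6,  943, 0.7, 6,  1643, 1.0, 6,
                   700, 0.30, 6,  1450, 0.30, 6),
    squalene = b(1379, 0.8, 6,  1666, 1.0, 6,  1200, 0.30, 6,
                 2890, 0.40, 10),
    glycogen = b(484, 1.0, 6,  860, 0.40, 6,  1450, 0.35, 6),
    NADH = b(1114, 1.0, 6,  740, 0.30, 6,  1600, 0.30, 6),
    glucose = b(1127, 1.0, 6,  860, 0.35, 6,  1450, 0.30, 6),
    tryptophan = b(1557, 1.0, 6,  760, 0.40, 6,  1230, 0.30, 6),
    threonine = b(1341, 1.0, 6,  870, 0.30, 6,  1450, 0.30, 6))
}

#' Default per-compartment concentration profiles
#'
#' Relative concentrations (arbitrary units) for the five bacteriocyte
#' compartments.  Only ordinal relations carry meaning: symbiont strain
#' A carries more glycogen than strain B, the nucleus is dominated by
#' nucleic acid, lipid droplets by storage lipid, the cytoplasm by
#' protein, and threonine (the internal standard) is constant across
#' the whole cell.
#'
#' @return named list (compartment -> named concentration vector).
#' @export
defaultPhantomConcentrations <- function() {
  list(
    nucleus = c(nucleicAcid = 1.0, phenylalanine = 0.45,
                cholesterol = 0.10, threonine = 1),
    `lipid droplet` = c(triglyceride = 1.0, palmitoleicAcid = 0.85,
                        cholesterol = 0.55, phenylalanine = 0.20,
                        threonine = 1),
    `symbiont A` = c(glycogen = 1.1, squalene = 0.65, lanosterol = 0.60,
                     NADH = 0.55, phenylalanine = 0.25, threonine = 1),
    `symbiont B` = c(glycogen = 0.30, squalene = 0.80, lanosterol = 0.75,
                     NADH = 0.20, phenylalanine = 0.25, threonine = 1),
    cytoplasm = c(phenylalanine = 0.90, glucose = 0.30,
                  tryptophan = 0.35, cholesterol = 0.20, threonine = 1))
}

.defaultAxis <- function() seq(400, 3100, by = 2)

# smooth deterministic per-pixel gain field in about [0.75, 1.25]
.gainField <- function(r, c, width, height) {
  1 + 0.15 * sin(2 * pi * c / width) * cos(pi * r / height) +
    0.10 * (c / width - 0.5)
}

#' Generate a synthetic bacteriocyte phantom
#'
#' Builds a single-cell hyperspectral cube with known ground truth: an
#' elliptical cell containing a nucleus disc at the basal pole, small
#' lipid-droplet discs beside the nucleus, an outer (apical) symbiont
#' zone split into strain A (outermost, glycogen-rich) and strain B
#' (inward), and cytoplasm.  Per pixel,
#' spectrum = gain x sum_m conc_m x ref_m + baseline + noise, with a
#' smooth polynomial-like fluorescence baseline, heteroscedastic
#' Gaussian noise (variance proportional to signal plus a floor,
#' approximating shot noise) and sparse cosmic-ray spikes.  Pixels
#' outside the cell are masked.  Bit-reproducible from (parameters,
#' seed); with \code{snr = Inf}, \code{baseline = FALSE},
#' \code{nSpikes = 0}, \code{gain = FALSE} each pixel equals its
#' mixture exactly, so the phantom is exactly linear in the
#' concentrations.
#'
#' @param width,height grid size in pixels (>= 16 each).
#' @param pixelSize pixel spacing in nm (default 450).
#' @param snr signal-to-noise ratio: peak of the mean in-cell clean
#'   spectrum divided by the noise SD at that peak (default 20;
#'   \code{Inf} for noiseless).
#' @param seed integer seed.
#' @param baseline include the fluorescence baseline.
#' @param nSpikes number of injected cosmic-ray spikes.
#' @param gain include the smooth per-pixel gain field.
#' @param concentrations per-compartment concentration profiles
#'   (default \code{\link{defaultPhantomConcentrations}}).
#' @param symbiontFraction fraction in [0, 1] scaling the symbiont-zone
#'   thickness (1 = fully colonized; used by the de-symbiosis series).
#' @param stageMultipliers optional named numeric vector of global
#'   per-metabolite concentration multipliers.
#' @param axis wavenumber axis (default 400..3100 cm^-1 at 2 cm^-1).
#' @param bands band tables (default \code{\link{defaultReferenceBands}}).
#' @return list with \code{cube} (\linkS4class{RamanCube}) and
#'   \code{truth} (\linkS4class{PhantomTruth}).
#' @examples
#' ph <- makeCellPhantom(width = 24, height = 24, snr = 50, seed = 7)
#' ph$cube
#' @export
makeCellPhantom <- function(width = 48, height = 48, pixelSize = 450,
                            snr = 20, seed = 1L, baseline = TRUE,
                            nSpikes = 12L, gain = TRUE,
                            concentrations = NULL,
                            symbiontFraction = 1,
                            stageMultipliers = NULL,
                            axis = NULL, bands = defaultReferenceBands()) {
  if (width < 16L || height < 16L) stop("grid must be at least 16 x 16")
  if (!is.finite(snr) && !is.infinite(snr)) stop("snr must be > 0")
  if (snr <= 0) stop("snr must be > 0")
  stopifnot(symbiontFraction >= 0, symbiontFraction <= 1)
  if (is.null(axis)) axis <- .defaultAxis()
  if (is.null(concentrations)) concentrations <- defaultPhantomConcentrations()
  set.seed(childSeed(seed, "phantom"))

  npix <- width * height
  px <- seq_len(npix) - 1L
  r <- px %/% width
  c_ <- px %% width
  r0 <- (height - 1) / 2; c0 <- (width - 1) / 2
  a <- 0.42 * height; b <- 0.42 * width
  rho <- sqrt(((r - r0) / a)^2 + ((c_ - c0) / b)^2)
  cell <- rho <= 1

  labels <- rep(NA_integer_, npix)
  labels[cell] <- 5L                                   # cytoplasm
  # symbiont zone: apical (top) half, outer shell; thickness scales
  # with the colonization fraction
  thick <- 0.55 * symbiontFraction
  apical <- r <= r0
  if (thick > 0) {
    zoneA <- cell & apical & rho >= 1 - 0.5 * thick
    zoneB <- cell & apical & rho >= 1 - thick & rho < 1 - 0.5 * thick
    labels[zoneA] <- 3L
    labels[zoneB] <- 4L
  }
  # nucleus: disc at the basal pole
  rn <- r0 + 0.5 * a; cn <- c0
  radn <- 0.30 * a
  nuc <- cell & ((r - rn)^2 + (c_ - cn)^2 <= radn^2)
  labels[nuc] <- 1L
  # lipid droplets: small discs between nucleus and cell center
  radd <- max(1, round(0.11 * a))
  angles <- c(-2.4, -1.57, -0.75)
  for (ang in angles) {
    dr <- rn + (radn + radd + 1.5) * sin(ang) + stats::runif(1, -1, 1)
    dc <- cn + (radn + radd + 1.5) * cos(ang) + stats::runif(1, -1, 1)
    drop_ <- cell & ((r - dr)^2 + (c_ - dc)^2 <= radd^2) & !nuc
    labels[drop_ & labels %in% c(4L, 5L)] <- 2L
  }
  compartments <- c("nucleus", "lipid droplet", "symbiont A",
                    "symbiont B", "cytoplasm")

  mets <- names(bands)
  R <- t(vapply(mets, function(m)
    intensity(makeReferenceSpectrum(bands[[m]], axis, m)),
    numeric(length(axis))))
  C <- matrix(0, npix, length(mets), dimnames = list(NULL, mets))
  for (i in seq_along(compartments)) {
    prof <- concentrations[[compartments[i]]]
    if (is.null(prof)) prof <- concentrations[[i]]
    bad <- setdiff(names(prof), mets)
    if (length(bad))
      stop("config error: unknown metabolites in concentrations: ",
           paste(bad, collapse = ", "))
    idx <- which(labels == i)
    for (m in names(prof)) C[idx, m] <- prof[[m]]
  }
  if (!is.null(stageMultipliers))
    for (m in names(stageMultipliers)) {
      if (!m %in% mets)
        stop("config error: unknown metabolite in stageMultipliers: ", m)
      C[, m] <- C[, m] * stageMultipliers[[m]]
    }

  signal <- C %*% R
  g <- if (gain) .gainField(r, c_, width, height) else rep(1, npix)
  S <- signal * g

  sRef <- max(colMeans(S[cell, , drop = FALSE]))
  floorVar <- 0.05 * sRef
  blParams <- list(enabled = baseline)
  if (baseline) {
    u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
    shape <- 0.7 * exp(-1.5 * u) + 0.3
    amp <- 0.5 * sRef * (0.8 + 0.4 * (r + c_) / (height + width))
    S <- S + outer(amp, shape)
    blParams <- list(enabled = TRUE, shape = "0.7*exp(-1.5u)+0.3",
                     ampRange = range(amp))
  }
  s0 <- if (is.infinite(snr)) 0 else sRef / (snr * sqrt(sRef + floorVar))
  if (s0 > 0) {
    sdM <- s0 * sqrt(pmax(signal * g, 0) + floorVar)
    S <- S + matrix(stats::rnorm(npix * length(axis)), npix) * sdM
  }
  spikes <- data.frame(pixel = integer(0), channel = integer(0),
                       amplitude = numeric(0))
  if (nSpikes > 0) {
    spix <- sample(which(cell), nSpikes)
    schan <- sample(length(axis), nSpikes, replace = TRUE)
    samp <- numeric(nSpikes)
    for (i in seq_len(nSpikes)) {
      local <- signal[spix[i], schan[i]] * g[spix[i]]
      samp[i] <- stats::runif(1, 30, 60) * (local + 0.25 * sRef)
      S[spix[i], schan[i]] <- S[spix[i], schan[i]] + samp[i]
    }
    spikes <- data.frame(pixel = spix, channel = schan, amplitude = samp)
  }

  cube <- RamanCube(S, axis, width, height, pixelSize, mask = cell)
  truth <- new("PhantomTruth", labels = labels,
               compartments = compartments, concentrations = C,
               gain = g, referenceSpectra = R, wavenumber = axis,
               noise = list(snr = snr, s0 = s0, floorVar = floorVar,
                            sRef = sRef),
               baseline = blParams, spikes = spikes,
               seed = as.integer(seed), width = as.integer(width),
               height = as.integer(height))
  list(cube = cube, truth = truth)
}

#' Generate a de-symbiosis phantom series
#'
#' A sequence of phantoms with shrinking symbiont zones and
#' stage-specific global concentration multipliers, emulating
#' progressive symbiont loss under substrate deprivation (fully
#' colonized, then partially and heavily depleted stages).  Default
#' multipliers raise cholesterol, glucose and tryptophan and lower
#' squalene and lanosterol in later stages.  Stage i uses seed
#' \code{seed + i - 1}, so the first stage with fraction 1 and unit
#' multipliers reproduces \code{\link{makeCellPhantom}} exactly.
#'
#' @param fractions non-increasing symbiont fractions in [0, 1].
#' @param stageTags labels carried into group statistics.
#' @param multipliers list (one element per stage) of named
#'   per-metabolite multipliers; NULL for the defaults.
#' @param seed integer seed.
#' @param ... further arguments to \code{\link{makeCellPhantom}}.
#' @return list of \code{list(cube, truth, tag)} per stage.
#' @export
makeDesymbiosisSeries <- function(fractions = c(1, 0.5, 0.1),
                                  stageTags = NULL, multipliers = NULL,
                                  seed = 1L, ...) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  if (any(diff(fractions) > 0))
    stop("fractions must be non-increasing")
  ns <- length(fractions)
  if (is.null(stageTags))
    stageTags <- paste0("stage", seq_len(ns))
  if (is.null(multipliers)) {
    ramp <- if (ns > 1) (seq_len(ns) - 1) / (ns - 1) else 0
    multipliers <- lapply(ramp, function(t) c(
      cholesterol = 1 + 1.2 * t, glucose = 1 + 1.0 * t,
      tryptophan = 1 + 0.8 * t, squalene = 1 - 0.5 * t,
      lanosterol = 1 - 0.5 * t))
  }
  lapply(seq_len(ns), function(i) {
    ph <- makeCellPhantom(seed = seed + i - 1L,
                          symbiontFraction = fractions[i],
                          stageMultipliers = multipliers[[i]], ...)
    list(cube = ph$cube, truth = ph$truth, tag = stageTags[i])
  })
}

# default SNR for the mock calibration series: the noisiest level on the
# sweep grid at which >= 95% of seeded replicates reach the linearity
# benchmark (see calibrationNoiseSweep and the methods vignette)
.calibrationSNRDefault <- 250

#' Generate a mock calibration series
#'
#' Emulates the mock-sample experiment validating the internal-standard
#' protocol: the analyte at varied concentration mixed with the
#' internal standard at fixed concentration.  Each level's spectrum is
#' c x ref_analyte + c_IS x ref_IS + baseline + heteroscedastic noise,
#' seeded per level.
#'
#' @param analyte metabolite name (default "glucose").
#' @param concentrations analyte levels (>= 3; default 6 levels 1..6).
#' @param isConcentration internal-standard concentration (default 2).
#' @param isName internal-standard metabolite (default "threonine").
#' @param snr signal-to-noise ratio as in
#'   \code{\link{makeCellPhantom}}; the default is the level at which
#'   the replicate sweep (\code{\link{calibrationNoiseSweep}}) keeps
#'   the linearity benchmark passing in at least 95\% of replicates.
#' @param seed integer seed.
#' @param baseline include a fluorescence baseline.
#' @param axis wavenumber axis.
#' @param bands band tables.
#' @return list with \code{series} (list of \code{list(concentration,
#'   spectrum)}) and \code{truth} (generation parameters).
#' @export
makeCalibrationSeries <- function(analyte = "glucose",
                                  concentrations = 1:6,
                                  isConcentration = 2,
                                  isName = "threonine",
                                  snr = .calibrationSNRDefault,
                                  seed = 1L, baseline = TRUE,
                                  axis = NULL,
                                  bands = defaultReferenceBands()) {
  if (length(concentrations) < 3L)
    stop("at least 3 concentration levels are required")
  if (is.null(axis)) axis <- .defaultAxis()
  refA <- intensity(makeReferenceSpectrum(bands[[analyte]], axis, analyte))
  refI <- intensity(makeReferenceSpectrum(bands[[isName]], axis, isName))
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  shape <- 0.7 * exp(-1.5 * u) + 0.3
  sRef <- max(max(concentrations) * refA + isConcentration * refI)
  floorVar <- 0.05 * sRef
  s0 <- if (is.infinite(snr)) 0 else sRef / (snr * sqrt(sRef + floorVar))
  series <- lapply(seq_along(concentrations), function(i) {
    set.seed(childSeed(seed, paste0("cal", i)))
    sig <- concentrations[i] * refA + isConcentration * refI
    y <- sig
    if (baseline) y <- y + 0.4 * sRef * shape
    if (s0 > 0)
      y <- y + stats::rnorm(length(axis)) * s0 * sqrt(pmax(sig, 0) + floorVar)
    list(concentration = concentrations[i], spectrum = Spectrum(axis, y))
  })
  list(series = series,
       truth = list(analyte = analyte, isName = isName,
                    isConcentration = isConcentration, snr = snr,
                    s0 = s0, seed = seed, baseline = baseline))
}

#' Compute the calibration curve from a series
#'
#' Baseline-corrects each level's spectrum, integrates the analyte and
#' internal-standard windows, and returns the per-level dA ratio ready
#' for \code{\link{fitCalibration}}.
#'
#' @param series output of \code{\link{makeCalibrationSeries}} (or any
#'   list of \code{list(concentration, spectrum)}).
#' @param analyteWindow,isWindow \linkS4class{PeakWindow}s (defaults:
#'   glucose 1127 +/- 8 and threonine 1341 +/- 8).
#' @param config \linkS4class{PreprocessConfig} for baseline correction.
#' @return data.frame with columns concentration, deltaA.
#' @export
calibrationCurve <- function(series,
                             analyteWindow = PeakWindow(1127, 8, "glucose"),
                             isWindow = PeakWindow(1341, 8, "threonine"),
                             config = preprocessConfig()) {
  if (!is.null(series$series)) series <- series$series
  rows <- lapply(series, function(lv) {
    sp <- correctBaseline(lv$spectrum, config)$result
    data.frame(concentration = lv$concentration,
               deltaA = peakArea(sp, analyteWindow) /
                 peakArea(sp, isWindow))
  })
  do.call(rbind, rows)
}

#' Replicate sweep for the calibration noise level
#'
#' For each candidate SNR, generates \code{nReplicates} seeded
#' calibration series, fits the calibration line, and reports the
#' fraction of replicates reaching the target R-squared.  Used to
#' choose (and to audit) the default calibration SNR.
#'
#' @param snrValues candidate SNR levels.
#' @param nReplicates replicates per level.
#' @param targetR2 the linearity benchmark (default 0.9998).
#' @param seed base seed; replicate j uses seed + j.
#' @param ... further arguments to \code{\link{makeCalibrationSeries}}.
#' @return data.frame with columns snr and passRate.
#' @export
calibrationNoiseSweep <- function(snrValues = c(125, 250, 500, 1000,
                                                2000, 4000),
                                  nReplicates = 50L, targetR2 = 0.9998,
                                  seed = 1L, ...) {
  rows <- lapply(snrValues, function(s) {
    pass <- vapply(seq_len(nReplicates), function(j) {
      ser <- makeCalibrationSeries(snr = s, seed = seed + j, ...)
      fit <- fitCalibration(calibrationCurve(ser))
      calibrationRSquared(fit) >= targetR2
    }, logical(1))
    data.frame(snr = s, passRate = mean(pass))
  })
  do.call(rbind, rows)
}
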