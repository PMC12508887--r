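# Linear weights over channels such that sum(w * y) equals the
# trapezoidal integral of y over the closed window [lo, hi], with the
# intensity linearly interpolated at the exact window bounds.  If
# localBaseline, the chord joining the window-endpoint intensities is
# subtracted (also a linear functional, folded into the weights).
.windowWeights <- function(w, lo, hi, localBaseline = FALSE) {
  n <- length(w)
  if (lo < w[1] || hi > w[n])
    stop(sprintf("config error: window [%g, %g] outside axis range [%g, %g]",
                 lo, hi, w[1], w[n]))
  if (sum(w >= lo & w <= hi) < 2L)
    stop("config error: window must intersect the axis in >= 2 channels")
  # interpolation weights for y(lo) and y(hi)
  interpW <- function(x0) {
    iL <- max(which(w <= x0))
    out <- numeric(n)
    if (w[iL] == x0 || iL == n) {
      out[iL] <- 1
    } else {
      a <- (x0 - w[iL]) / (w[iL + 1] - w[iL])
      out[iL] <- 1 - a
      out[iL + 1] <- a
    }
    out
  }
  wLo <- interpW(lo); wHi <- interpW(hi)
  inner <- which(w > lo & w < hi)
  grid <- c(lo, w[inner], hi)
  m <- length(grid)
  trap <- numeric(m)
  trap[1] <- (grid[2] - grid[1]) / 2
  trap[m] <- (grid[m] - grid[m - 1]) / 2
  if (m > 2)
    trap[2:(m - 1)] <- (grid[3:m] - grid[1:(m - 2)]) / 2
  wt <- trap[1] * wLo + trap[m] * wHi
  if (length(inner)) wt[inner] <- wt[inner] + trap[seq_along(inner) + 1L]
  if (localBaseline)                    # chord area, spread onto endpoints
    wt <- wt - (hi - lo) / 2 * (wLo + wHi)
  wt
}

#' Integrate a peak window over every pixel
#'
#' Per-pixel trapezoidal integral of intensity over the closed window
#' (units: intensity x cm^-1).  Channels partially covered at the window
#' bounds are handled by linear interpolation of intensity at the exact
#' bounds, so the integral is exact for piecewise-linear spectra and the
#' operation is linear in intensity.  With \code{localBaseline} the
#' chord joining the window's endpoint intensities is subtracted first
#' (for inputs that have not been globally baseline-corrected; off by
#' default).
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param window a \linkS4class{PeakWindow}.
#' @param localBaseline subtract the endpoint chord inside the window.
#' @return An \linkS4class{AreaMap}; masked pixels are invalid.
#' @export
integratePeak <- function(cube, window, localBaseline = FALSE) {
  wt <- .windowWeights(wavenumber(cube), window@center - window@halfWidth,
                       window@center + window@halfWidth, localBaseline)
  vals <- as.numeric(spectra(cube) %*% wt)
  mask <- validMask(cube)
  vals[!mask] <- NA_real_
  d <- cubeDim(cube)
  new("AreaMap", values = vals, valid = mask,
      width = as.integer(d["width"]), height = as.integer(d["height"]),
      window = window)
}

#' Band area of a single spectrum
#'
#' Scalar version of \code{\link{integratePeak}}.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param window a \linkS4class{PeakWindow}.
#' @param localBaseline subtract the endpoint chord.
#' @return numeric area (intensity x cm^-1).
#' @export
peakArea <- function(spectrum, window, localBaseline = FALSE) {
  wt <- .windowWeights(wavenumber(spectrum),
                       window@center - window@halfWidth,
                       window@center + window@halfWidth, localBaseline)
  sum(intensity(spectrum) * wt)
}

#' Internal-standard ratio map (dA)
#'
#' dA = A_metabolite / A_internal_standard per pixel.  A pixel is valid
#' only where both operand areas are valid and the denominator exceeds
#' the floor epsilon (default 1e-6 times the maximum denominator area,
#' preventing ratio blow-up at near-empty pixels without hiding genuine
#' signal).  Negative operand areas (baseline over-subtraction) are
#' retained but flagged rather than clipped.  dA is dimensionless and
#' invariant under per-pixel multiplicative rescaling of the source
#' spectrum, the property that makes the internal-standard ratio
#' comparable across pixels, cells and instruments.
#'
#' @param numerator,denominator \linkS4class{AreaMap}s on the same grid.
#' @param epsilon denominator floor; NULL for the default.
#' @return A \linkS4class{RatioMap}.
#' @export
ratioMap <- function(numerator, denominator, epsilon = NULL) {
  if (numerator@width != denominator@width ||
      numerator@height != denominator@height)
    stop("grid error: operand maps have different dimensions")
  den <- denominator@values
  if (is.null(epsilon))
    epsilon <- 1e-6 * max(den[denominator@valid], 0, na.rm = TRUE)
  if (epsilon < 0) stop("epsilon must be >= 0")
  valid <- numerator@valid & denominator@valid & !is.na(den) & den > epsilon
  vals <- rep(NA_real_, length(den))
  vals[valid] <- numerator@values[valid] / den[valid]
  flagged <- valid & (numerator@values < 0 | den < 0)
  flagged[is.na(flagged)] <- FALSE
  new("RatioMap", values = vals, valid = valid,
      width = numerator@width, height = numerator@height,
      numeratorWindow = numerator@window,
      denominatorWindow = denominator@window,
      flaggedNegative = flagged)
}

#' Rank internal-standard candidates by spatial uniformity
#'
#' A usable internal standard must be uniformly distributed and stable
#' in content, so its band-area map over the cell should have the lowest
#' spatial coefficient of variation (CV = SD/mean).  Candidates are
#' ranked ascending by CV over the masked pixels; negative-mean
#' candidates are disqualified; ties break toward the lower band center.
#'
#' @param cube a \linkS4class{RamanCube} (baseline-corrected).
#' @param candidates list of \linkS4class{PeakWindow}s.
#' @param cellMask logical per-pixel mask of the cell (default: the
#'   cube's valid mask).
#' @param localBaseline passed to \code{\link{integratePeak}}.
#' @return list with \code{ranking} (data.frame: label, center, mean,
#'   sd, cv, ascending cv) and \code{chosen} (the winning PeakWindow).
#' @export
selectInternalStandard <- function(cube, candidates, cellMask = NULL,
                                   localBaseline = FALSE) {
  if (!length(candidates)) stop("at least one candidate window is required")
  if (is.null(cellMask)) cellMask <- validMask(cube)
  if (!any(cellMask)) stop("cell mask is empty")
  rows <- lapply(candidates, function(win) {
    am <- integratePeak(cube, win, localBaseline)
    v <- am@values[cellMask & am@valid]
    data.frame(label = win@label, center = win@center,
               mean = mean(v), sd = sd(v), cv = sd(v) / mean(v))
  })
  tab <- do.call(rbind, rows)
  keep <- is.finite(tab$cv) & tab$mean > 0
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab))
    stop("selection error: all candidate windows disqualified")
  tab <- tab[order(tab$cv, tab$center), , drop = FALSE]
  rownames(tab) <- NULL
  list(ranking = tab, chosen = candidates[keep][[
    which(sapply(candidates[keep], function(w)
      w@center == tab$center[1]))[1]]])
}

.labelsVector <- function(labels, npix) {
  if (is(labels, "ClusterResult")) return(clusterLabels(labels))
  if (is(labels, "PhantomTruth")) return(clusterLabels(labels))
  if (is.logical(labels)) return(ifelse(labels, 0L, NA_integer_))
  stopifnot(length(labels) == npix)
  as.integer(labels)
}

#' Per-compartment statistics of a ratio map
#'
#' Mean, SD and n of valid dA values per label.  Invalid pixels reduce n
#' and never contribute; labels with zero valid pixels are omitted with
#' a warning.  Comparison across experimental groups is descriptive
#' (mean +/- SD); no hypothesis testing is bundled.
#'
#' @param ratio a \linkS4class{RatioMap} (or \linkS4class{AreaMap}).
#' @param labels a \linkS4class{ClusterResult}, \linkS4class{PhantomTruth},
#'   logical cell mask, or integer per-pixel labels (0-based, NA masked).
#' @param groupTag group identifier carried into the table (e.g. a
#'   treatment stage).
#' @param labelNames optional names for the label codes.
#' @param clipNegative set negative dA values to zero before averaging
#'   (off by default; negative areas are reported as-is).
#' @return data.frame with columns group, label, n, mean, sd.
#' @export
compartmentStats <- function(ratio, labels, groupTag = "",
                             labelNames = NULL, clipNegative = FALSE) {
  lab <- .labelsVector(labels, length(ratio@values))
  if (length(lab) != length(ratio@values))
    stop("labels do not align with the map grid")
  ok <- ratio@valid & !is.na(lab)
  vals <- ratio@values
  if (clipNegative) vals <- pmax(vals, 0)
  lev <- sort(unique(lab[!is.na(lab)]))
  out <- list()
  for (lv in lev) {
    v <- vals[ok & lab == lv]
    if (!length(v)) {
      warning(sprintf("label %d has no valid pixels; row omitted", lv))
      next
    }
    nm <- if (!is.null(labelNames)) labelNames[[lv + 1L]] else
      as.character(lv)
    out[[length(out) + 1L]] <- data.frame(
      group = groupTag, label = nm, n = length(v), mean = mean(v),
      sd = if (length(v) > 1L) sd(v) else 0)
  }
  do.call(rbind, out)
}

#' Fit a calibration line
#'
#' Ordinary least squares of dA on concentration over a calibration
#' series (an analyte at varied concentration mixed with the internal
#' standard at fixed concentration), with the coefficient of
#' determination R^2 = 1 - SS_res/SS_tot.
#'
#' @param series data.frame with columns \code{concentration} and
#'   \code{deltaA} (or a list of 2-element vectors).
#' @return A \linkS4class{CalibrationFit}.
#' @export
fitCalibration <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- do.call(rbind, lapply(series, function(p)
      data.frame(concentration = p[[1]], deltaA = p[[2]])))
  if (nrow(series) < 3L)
    stop("fit error: at least 3 calibration points are required")
  if (length(unique(series$concentration)) < 2L)
    stop("fit error: all concentrations identical")
  fit <- lm(deltaA ~ concentration, data = series)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((series$deltaA - mean(series$deltaA))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("CalibrationFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      rSquared = min(max(r2, 0), 1), nPoints = nrow(series))
}

#' End-to-end semi-quantitative analysis of a cube
#'
#' Runs the full pipeline: preprocessing, K-means compartmentalization
#' (plus optional unmixing), band-area integration of the internal
#' standard and every metabolite window, dA ratio maps, and
#' per-compartment statistics.  Results are returned as a bundle; if
#' \code{outDir} is given, maps, spectra, the stats table and a
#' provenance JSON are written there.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param config list with elements \code{windows} (named list of
#'   metabolite \linkS4class{PeakWindow}s; required),
#'   \code{internalStandard} (PeakWindow, default 1341 +/- 8,
#'   tentatively threonine), \code{preprocess}
#'   (\linkS4class{PreprocessConfig}), \code{k} (cluster count, default
#'   5), \code{nPcs}, \code{seed}, \code{unmixComponents} (NULL to skip
#'   unmixing), \code{epsilon}, \code{localBaseline}, \code{groupTag},
#'   \code{labels} (optional precomputed labels to use instead of
#'   clustering).
#' @param outDir optional output directory.
#' @return list of class \code{mqaBundle}: cube (preprocessed),
#'   clusters, unmix, areas, ratios, stats, provenance.
#' @export
runMQA <- function(cube, config, outDir = NULL) {
  if (is.null(config$windows) || !length(config$windows))
    stop("usage error: config must name at least one metabolite window")
  is_win <- config$internalStandard
  if (is.null(is_win)) is_win <- PeakWindow(1341, 8, "threonine")
  pp <- config$preprocess
  if (is.null(pp)) pp <- preprocessConfig()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  k <- if (is.null(config$k)) 5L else as.integer(config$k)
  nPcs <- if (is.null(config$nPcs)) 10L else as.integer(config$nPcs)
  localBaseline <- isTRUE(config$localBaseline)
  groupTag <- if (is.null(config$groupTag)) "" else config$groupTag

  pre <- runPreprocess(cube, pp)
  work <- pre$cube
  clusters <- if (!is.null(config$labels)) config$labels
              else kmeansCluster(work, k, seed = seed, nPcs = nPcs)
  unmix <- NULL
  if (!is.null(config$unmixComponents))
    unmix <- trueComponentAnalysis(work, config$unmixComponents, seed = seed)

  isArea <- integratePeak(work, is_win, localBaseline)
  areas <- list(); ratios <- list(); stats <- list()
  for (nm in names(config$windows)) {
    win <- config$windows[[nm]]
    am <- integratePeak(work, win, localBaseline)
    rm_ <- ratioMap(am, isArea, epsilon = config$epsilon)
    st <- compartmentStats(rm_, clusters, groupTag = groupTag,
                           labelNames = config$labelNames)
    st$metabolite <- nm
    areas[[nm]] <- am; ratios[[nm]] <- rm_; stats[[nm]] <- st
  }
  statsTab <- do.call(rbind, stats)
  rownames(statsTab) <- NULL
  bundle <- list(cube = work, clusters = clusters, unmix = unmix,
                 internalStandardArea = isArea, areas = areas,
                 ratios = ratios, stats = statsTab,
                 provenance = list(seed = seed, k = k, nPcs = nPcs,
                                   internalStandard = is_win@center,
                                   windows = names(config$windows),
                                   preprocess = pre$provenance,
                                   groupTag = groupTag))
  class(bundle) <- "mqaBundle"
  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

#' Write an analysis bundle to a directory
#'
#' Writes stats.csv, cluster labels (CSV + PNG), per-metabolite dA maps
#' (CSV + PNG), cluster mean spectra and a provenance JSON.
#'
#' @param bundle an \code{mqaBundle} from \code{\link{runMQA}}.
#' @param outDir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$stats, file.path(outDir, "stats.csv"),
                   row.names = FALSE)
  if (is(bundle$clusters, "ClusterResult")) {
    exportMap(bundle$clusters, file.path(outDir, "clusters.png"), "png")
    exportMap(bundle$clusters, file.path(outDir, "clusters.csv"), "csv")
    ms <- meanSpectra(bundle$clusters)
    df <- data.frame(wavenumber = wavenumber(bundle$clusters), t(ms))
    names(df) <- c("wavenumber", paste0("cluster", seq_len(nrow(ms)) - 1L))
    utils::write.csv(df, file.path(outDir, "cluster_mean_spectra.csv"),
                     row.names = FALSE)
  }
  for (nm in names(bundle$ratios)) {
    exportMap(bundle$ratios[[nm]],
              file.path(outDir, paste0("ratio_", nm, ".png")), "png")
    exportMap(bundle$ratios[[nm]],
              file.path(outDir, paste0("ratio_", nm, ".csv")), "csv")
  }
  jsonlite::write_json(bundle$provenance,
                       file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
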