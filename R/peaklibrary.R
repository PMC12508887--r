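.classMap <- list(
  nucleus = c(1078, 1423),
  `lipid droplet` = c(1746, 1263, 1656, 3009, 1083),
  symbiont = c(930, 943, 1643, 1379, 1666, 484),
  cytoplasm = c(1006))

.classPalette <- c(nucleus = "red", `lipid droplet` = "yellow",
                   symbiont = "green", symbiont2 = "cyan",
                   cytoplasm = "blue")

.mkEntry <- function(centers, note, halfWidth = 8) {
  list(windows = lapply(centers, function(ctr)
    PeakWindow(ctr, halfWidth)), note = note)
}

#' The shipped metabolite band library
#'
#' Curated bands for bacteriocyte metabolite mapping.  Assignments are
#' deliberately tentative (vibrational bands overlap; several are noted
#' as "tentatively assigned") and the tool always reports candidates
#' rather than asserting identity.  The 980 cm^-1 region is excluded:
#' methanol fixation alters it, so it must not be used for attribution.
#'
#' Bands: deoxyribose 1423; nucleic-acid PO2- 1078; triglyceride C=O
#' 1746; palmitoleic acid 1263/1656/3009; cholesterol 1083;
#' phenylalanine 1006; lanosterol 930/943/1643; squalene 1379/1666;
#' glycogen 484; NADH 1114; glucose 1127; tryptophan 1557; threonine
#' (internal standard) 1341.  All half-widths default to 8 cm^-1.
#'
#' @return A \linkS4class{PeakLibrary}.
#' @examples
#' lib <- defaultLibrary()
#' libraryEntries(lib)$glycogen$windows[[1]]
#' @export
defaultLibrary <- function() {
  entries <- list(
    deoxyribose = .mkEntry(1423, "deoxyribose ring mode; DNA marker"),
    `nucleic acid` = .mkEntry(1078, "PO2- symmetric stretch; DNA backbone"),
    triglyceride = .mkEntry(1746, "ester C=O stretch; storage lipid"),
    `palmitoleic acid` = .mkEntry(c(1263, 1656, 3009),
      "=C-H / C=C modes of unsaturated fatty acid"),
    cholesterol = .mkEntry(1083, "sterol backbone mode"),
    phenylalanine = .mkEntry(1006,
      "ring breathing; tentatively assigned; protein marker"),
    lanosterol = .mkEntry(c(930, 943, 1643),
      "sterol precursor; tentatively assigned"),
    squalene = .mkEntry(c(1379, 1666),
      "triterpene precursor of sterols; methanotroph marker"),
    glycogen = .mkEntry(484, "glucosidic skeletal mode; storage glucan"),
    NADH = .mkEntry(1114, "reduced nicotinamide cofactor"),
    glucose = .mkEntry(1127, "C-O/C-C stretch region"),
    tryptophan = .mkEntry(1557, "indole ring mode"),
    threonine = .mkEntry(1341,
      "tentatively assigned; spatially uniform; internal standard"))
  new("PeakLibrary", entries = entries,
      exclusions = list(PeakWindow(980, 8, "fixation artifact")),
      matchTolerance = 8)
}

#' Assign an observed peak position to library metabolites
#'
#' Returns all library entries within \code{tolerance} of the position,
#' ranked by distance.  Positions inside an exclusion window (fixation
#' artifacts) are flagged excluded and get no assignments.  The result
#' set grows monotonically with tolerance.
#'
#' @param position observed peak position (cm^-1).
#' @param library a \linkS4class{PeakLibrary}.
#' @param tolerance match tolerance in cm^-1 (default: the library's).
#' @return list with \code{excluded} (logical) and \code{matches}
#'   (data.frame: metabolite, center, distance, note; ascending
#'   distance, possibly empty).
#' @export
assignPeak <- function(position, library = defaultLibrary(),
                       tolerance = NULL) {
  if (is.null(tolerance)) tolerance <- library@matchTolerance
  if (tolerance <= 0) stop("tolerance must be > 0")
  for (x in library@exclusions)
    if (abs(position - x@center) <= x@halfWidth)
      return(list(excluded = TRUE,
                  matches = data.frame(metabolite = character(0),
                                       center = numeric(0),
                                       distance = numeric(0),
                                       note = character(0))))
  rows <- list()
  for (nm in names(library@entries)) {
    e <- library@entries[[nm]]
    for (win in e$windows) {
      d <- abs(win@center - position)
      if (d <= tolerance)
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = nm, center = win@center, distance = d,
          note = e$note)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), center = numeric(0),
               distance = numeric(0), note = character(0))
  matches <- matches[order(matches$distance), , drop = FALSE]
  rownames(matches) <- NULL
  list(excluded = FALSE, matches = matches)
}

.bandClass <- function(center) {
  for (cl in names(.classMap))
    if (any(abs(.classMap[[cl]] - center) < 1e-9)) return(cl)
  NA_character_
}

#' Annotate clusters with metabolite classes
#'
#' Maps each cluster's candidate difference-peak bands through
#' \code{\link{assignPeak}} and labels the cluster by the majority
#' metabolite class (nucleus / lipid droplet / symbiont / cytoplasm);
#' ties resolve to the class of the highest-prominence band, clusters
#' with no assignable band become "unassigned".
#'
#' @param peaks output of \code{\link{differencePeaks}} (named list of
#'   data.frames with position and prominence).
#' @param library a \linkS4class{PeakLibrary}.
#' @param topN number of top-prominence bands considered per cluster.
#' @return data.frame: cluster, class, bands (semicolon-joined
#'   metabolite names of the matched bands).
#' @export
annotateClusters <- function(peaks, library = defaultLibrary(),
                             topN = 5L) {
  out <- list()
  for (nm in names(peaks)) {
    pk <- head(peaks[[nm]], topN)
    classes <- character(0)
    mets <- character(0)
    for (i in seq_len(nrow(pk))) {
      asg <- assignPeak(pk$position[i], library)
      if (asg$excluded || !nrow(asg$matches)) next
      mets <- c(mets, asg$matches$metabolite[1])
      cl <- .bandClass(asg$matches$center[1])
      if (!is.na(cl)) classes <- c(classes, cl)
    }
    cls <- if (!length(classes)) "unassigned" else {
      tab <- table(classes)
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) == 1L) winners else classes[1]  # top prominence
    }
    out[[length(out) + 1L]] <- data.frame(
      cluster = nm, class = cls,
      bands = paste(unique(mets), collapse = ";"))
  }
  do.call(rbind, out)
}

#' Compartment color palette for cluster composites
#'
#' Assigns the conventional compartment colors (nucleus red, lipid
#' droplets yellow, symbionts green then cyan, cytoplasm blue) to
#' clusters from their annotation; unannotated clusters take the
#' remaining palette colors in order.
#'
#' @param annotation data.frame from \code{\link{annotateClusters}}.
#' @return named character vector of colors, one per cluster.
#' @export
clusterPalette <- function(annotation) {
  base <- c("red", "yellow", "green", "cyan", "blue",
            "magenta", "orange", "gray")
  cols <- character(nrow(annotation))
  symbiontUsed <- 0L
  for (i in seq_len(nrow(annotation))) {
    cl <- annotation$class[i]
    cols[i] <- switch(cl,
      nucleus = "red", `lipid droplet` = "yellow",
      symbiont = { symbiontUsed <- symbiontUsed + 1L
                   if (symbiontUsed == 1L) "green" else "cyan" },
      cytoplasm = "blue", NA_character_)
  }
  left <- setdiff(base, cols[!is.na(cols)])
  cols[is.na(cols)] <- left[seq_len(sum(is.na(cols)))]
  names(cols) <- annotation$cluster
  cols
}

#' Write a peak library to YAML
#'
#' @param library a \linkS4class{PeakLibrary}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePeakLibrary <- function(library, path) {
  obj <- list(
    match_tolerance = library@matchTolerance,
    metabolites = lapply(library@entries, function(e) list(
      windows = lapply(e$windows, function(w)
        list(center = w@center, half_width = w@halfWidth)),
      note = e$note)),
    exclusions = lapply(library@exclusions, function(w)
      list(center = w@center, half_width = w@halfWidth)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a peak library from YAML
#'
#' @param path YAML file written by \code{\link{writePeakLibrary}} (or
#'   hand-authored in the same schema).
#' @return A \linkS4class{PeakLibrary}.
#' @export
readPeakLibrary <- function(path) {
  obj <- yaml::read_yaml(path)
  entries <- lapply(obj$metabolites, function(e) list(
    windows = lapply(e$windows, function(w)
      PeakWindow(w$center, w$half_width)),
    note = e$note))
  exclusions <- lapply(obj$exclusions, function(w)
    PeakWindow(w$center, w$half_width, "fixation artifact"))
  new("PeakLibrary", entries = entries, exclusions = exclusions,
      matchTolerance = obj$match_tolerance)
}
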