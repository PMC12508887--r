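.pcaScores <- function(X, nPcs) {
  nPcs <- min(nPcs, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nPcs)
  pc$x
}

#' K-means compartmentalization of a cube
#'
#' Clusters spectra with k-means++-style multiple restarts (10) on the
#' top \code{nPcs} PCA scores of vector-normalized spectra: spectra are
#' scaled to unit Euclidean norm first so segmentation reflects spectral
#' shape rather than brightness.  Deterministic given \code{seed}; the
#' best-inertia restart is returned.  Cluster mean spectra are the
#' arithmetic means of member-pixel spectra of the input cube
#' (unnormalized).
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param k cluster count (1 <= k <= valid pixel count).
#' @param seed integer seed.
#' @param nPcs number of PCA scores to cluster on (default 10).
#' @return A \linkS4class{ClusterResult}.
#' @export
kmeansCluster <- function(cube, k, seed = 1L, nPcs = 10L) {
  mask <- validMask(cube)
  if (k < 1L || k > sum(mask))
    stop("config error: k must lie in [1, valid pixel count]")
  X <- spectra(cube)[mask, , drop = FALSE]
  sc <- .pcaScores(.rowNormalize(X), nPcs)
  set.seed(childSeed(seed, "kmeans"))
  km <- if (k == 1L) {
    ctr <- colMeans(sc)
    list(cluster = rep(1L, nrow(sc)),
         tot.withinss = sum(sweep(sc, 2L, ctr)^2))
  } else {
    kmeans(sc, centers = k, nstart = 10L, iter.max = 200L)
  }
  labels <- rep(NA_integer_, length(mask))
  labels[mask] <- as.integer(km$cluster) - 1L
  ms <- matrix(0, k, ncol(X))
  for (i in seq_len(k)) {
    member <- which(labels == i - 1L)
    if (length(member))
      ms[i, ] <- colMeans(spectra(cube)[member, , drop = FALSE])
  }
  d <- cubeDim(cube)
  new("ClusterResult", k = as.integer(k), labels = labels,
      meanSpectra = ms, wavenumber = wavenumber(cube),
      inertia = km$tot.withinss, seed = as.integer(seed),
      width = as.integer(d["width"]), height = as.integer(d["height"]))
}

#' Choose the cluster count by mean silhouette
#'
#' Scans \code{kRange}, clustering as \code{\link{kmeansCluster}} does,
#' and returns the k maximizing the mean silhouette width on the PCA
#' scores.  Ties break toward smaller k; the full profile is always
#' reported so a manual override can be justified.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param kRange integer vector of candidate k (within [2, pixels - 1]).
#' @param seed integer seed.
#' @param nPcs PCA scores used for clustering and silhouette distances.
#' @return list with \code{k} (chosen), \code{profile} (data.frame of k
#'   and mean silhouette) and \code{results} (ClusterResult per k).
#' @export
selectK <- function(cube, kRange = 2:8, seed = 1L, nPcs = 10L) {
  mask <- validMask(cube)
  if (min(kRange) < 2L || max(kRange) > sum(mask) - 1L)
    stop("config error: kRange must lie within [2, valid pixels - 1]")
  X <- spectra(cube)[mask, , drop = FALSE]
  sc <- .pcaScores(.rowNormalize(X), nPcs)
  dd <- dist(sc)
  if (max(dd) == 0)
    stop("selection error: degenerate cube (all spectra identical)")
  results <- list()
  sil <- numeric(length(kRange))
  for (j in seq_along(kRange)) {
    res <- kmeansCluster(cube, kRange[j], seed = seed, nPcs = nPcs)
    results[[j]] <- res
    lab <- clusterLabels(res)[mask] + 1L
    if (length(unique(lab)) < 2L) {
      sil[j] <- NA_real_
    } else {
      sil[j] <- mean(cluster::silhouette(lab, dd)[, "sil_width"])
    }
  }
  profile <- data.frame(k = kRange, silhouette = sil)
  chosen <- kRange[which.max(sil)]   # first max: ties go to smaller k
  list(k = chosen, profile = profile, results = results)
}

# Successive-projection vertex search: greedily picks the pixel whose
# score vector has the largest residual norm after projecting out the
# span of the vertices found so far.  Greedy simplex-volume
# maximization; deterministic, and the vertex sequence is nested in the
# component count.
.spaVertices <- function(sc, k) {
  R <- sc
  picks <- integer(0)
  for (i in seq_len(k)) {
    nrm <- rowSums(R^2)
    pick <- which.max(nrm)
    if (nrm[pick] <= 0) break
    picks <- c(picks, pick)
    v <- R[pick, ] / sqrt(sum(R[pick, ]^2))
    R <- R - outer(as.numeric(R %*% v), v)
  }
  picks
}

#' Endmember extraction and non-negative unmixing
#'
#' Open reimplementation of linear-combination component imaging
#' ("true component analysis"): endmembers are sought among the observed
#' pixel spectra by greedy simplex-volume maximization (successive
#' projections on PCA-reduced scores, with the mean-offset direction
#' included so the first vertex is an extreme spectrum, not merely the
#' brightest); per-pixel abundances are then obtained by non-negative
#' least squares against the endmember matrix, on unnormalized spectra
#' so abundances track quantity.  This is an approximation of the
#' proprietary procedure it stands in for, not a clone.
#'
#' The vertex sequence is nested in the component count, so the
#' per-pixel residual is weakly decreasing as \code{nComponents} grows.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param nComponents number of endmembers
#'   (<= min(channels, valid pixels)).
#' @param seed integer seed, recorded for provenance (the search itself
#'   is deterministic).
#' @return An \linkS4class{UnmixResult}.
#' @export
trueComponentAnalysis <- function(cube, nComponents, seed = 1L) {
  mask <- validMask(cube)
  X <- spectra(cube)[mask, , drop = FALSE]
  if (nComponents > min(ncol(X), nrow(X)))
    stop("config error: nComponents exceeds min(channels, pixels)")
  # augment centered scores with a constant coordinate so the simplex
  # search sees affine (not just linear) extremes
  # fixed reduction rank, independent of nComponents, so the vertex
  # sequence (and hence nestedness of endmember sets) does not depend
  # on the requested component count
  sc <- .pcaScores(X, 30L)
  scale0 <- mean(sqrt(rowSums(sc^2)))
  if (scale0 == 0) scale0 <- 1
  Z <- cbind(sc, scale0)
  picks <- .spaVertices(Z, nComponents)
  E <- X[picks, , drop = FALSE]
  A <- t(E)                       # channels x components
  nval <- nrow(X)
  ab <- matrix(0, nval, nComponents)
  res <- numeric(nval)
  for (i in seq_len(nval)) {
    fit <- pracma::lsqnonneg(A, X[i, ])
    ab[i, ] <- fit$x
    res[i] <- sqrt(sum((X[i, ] - A %*% fit$x)^2) / ncol(X))
  }
  d <- cubeDim(cube)
  abundFull <- matrix(NA_real_, length(mask), nComponents)
  abundFull[mask, ] <- ab
  resFull <- rep(NA_real_, length(mask))
  resFull[mask] <- res
  new("UnmixResult", nComponents = as.integer(nComponents),
      endmembers = E, abundances = abundFull, residual = resFull,
      wavenumber = wavenumber(cube), width = as.integer(d["width"]),
      height = as.integer(d["height"]), seed = as.integer(seed))
}

#' Per-cluster mean spectra
#'
#' Arithmetic mean spectrum over the unmasked member pixels of each
#' label.  Empty clusters yield an NA spectrum with a warning.
#'
#' @param cube a \linkS4class{RamanCube}.
#' @param labels a \linkS4class{ClusterResult} or an integer per-pixel
#'   label vector (0-based, NA for masked pixels).
#' @return named list of \linkS4class{Spectrum} ("cluster0", ...).
#' @export
clusterMeanSpectra <- function(cube, labels) {
  if (is(labels, "ClusterResult")) labels <- clusterLabels(labels)
  stopifnot(length(labels) == nrow(spectra(cube)))
  labels[!validMask(cube)] <- NA_integer_
  lev <- sort(unique(labels[!is.na(labels)]))
  out <- vector("list", length(lev))
  names(out) <- paste0("cluster", lev)
  for (j in seq_along(lev)) {
    member <- which(labels == lev[j])
    if (!length(member)) {
      warning(sprintf("cluster %d is empty; mean undefined", lev[j]))
      out[[j]] <- NA
    } else {
      out[[j]] <- Spectrum(wavenumber(cube),
                           colMeans(spectra(cube)[member, , drop = FALSE]))
    }
  }
  out
}

#' Difference peaks between cluster mean spectra
#'
#' For each cluster, the contrast spectrum is the cluster mean minus the
#' mean of all other clusters' means; its local maxima above
#' \code{minProminence} are candidate assignment bands, returned with
#' positions and topographic prominences in descending prominence
#' order.  This is the "difference peak" step used to attribute clusters
#' to cell compartments.
#'
#' @param x a \linkS4class{ClusterResult}, or a k x channels matrix of
#'   mean spectra (then supply \code{wavenumbers}).
#' @param minProminence minimum prominence (same units as intensity).
#' @param wavenumbers axis when \code{x} is a matrix.
#' @return named list of data.frames (position, height, prominence).
#' @export
differencePeaks <- function(x, minProminence = 0,
                            wavenumbers = NULL) {
  if (is(x, "ClusterResult")) {
    M <- meanSpectra(x)
    w <- wavenumber(x)
  } else {
    M <- x
    w <- wavenumbers
  }
  if (nrow(M) < 2L)
    stop("at least 2 mean spectra are required")
  out <- vector("list", nrow(M))
  names(out) <- paste0("cluster", seq_len(nrow(M)) - 1L)
  for (i in seq_len(nrow(M))) {
    contrast <- M[i, ] - colMeans(M[-i, , drop = FALSE])
    pk <- peakProminence(contrast, w)
    out[[i]] <- pk[pk$prominence >= minProminence, , drop = FALSE]
  }
  out
}
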