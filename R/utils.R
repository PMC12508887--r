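#' Derive a child seed from a run seed and a stage tag
#'
#' One global seed fans out to per-stage seeds so each stage is
#' independently reproducible.  The derivation is a fixed integer hash of
#' (seed, tag) reduced modulo 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param tag character stage tag.
#' @return integer child seed in [1, 2^31 - 1].
#' @export
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483646) + 1L
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same pixels;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.  Pairs where either labeling is NA are dropped.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

# unit-L2-normalize matrix rows; zero rows left unchanged
.rowNormalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

#' Local maxima with topographic prominence
#'
#' Finds strict local maxima of a curve and computes each peak's
#' prominence: the drop from the peak to the higher of the two minima
#' separating it from higher ground (or from the curve end).
#'
#' @param y numeric curve.
#' @param x positions (same length); defaults to indices.
#' @return data.frame with columns \code{position}, \code{height},
#'   \code{prominence}, sorted by descending prominence.
#' @export
peakProminence <- function(y, x = seq_along(y)) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(idx))
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    lmin <- min(y[max(which(y[1:i] > y[i]), 1L):i])
    right <- y[i:n]
    higher <- which(right > y[i])
    rmin <- min(right[1:if (length(higher)) min(higher) else length(right)])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  out <- data.frame(position = x[idx], height = y[idx], prominence = prom)
  out[order(-out$prominence), , drop = FALSE]
}

# quadratic (parabolic) interpolation of an apex through three points
.quadApex <- function(xs, ys) {
  d <- (xs[3] - xs[1]) / 2
  denom <- ys[1] - 2 * ys[2] + ys[3]
  if (denom >= 0) return(xs[2])          # not concave: keep grid maximum
  xs[2] + 0.5 * d * (ys[1] - ys[3]) / denom
}
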