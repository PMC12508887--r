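test_that("k-means segmentation recovers the phantom compartments", {
  cl <- kmeansCluster(.phPre, 5, seed = 42)
  expect_gte(adjustedRand(clusterLabels(cl), clusterLabels(.ph$truth)),
             0.90)
  # deterministic under a fixed seed; labels partition the valid grid
  cl2 <- kmeansCluster(.phPre, 5, seed = 42)
  expect_identical(clusterLabels(cl), clusterLabels(cl2))
  lab <- clusterLabels(cl)
  expect_true(all(is.na(lab[!validMask(.phPre)])))
  expect_true(all(lab[validMask(.phPre)] %in% 0:4))
  # cross-check the in-package ARI against an independent implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    keep <- !is.na(lab)
    expect_equal(adjustedRand(lab, clusterLabels(.ph$truth)),
                 mclust::adjustedRandIndex(lab[keep],
                                           clusterLabels(.ph$truth)[keep]),
                 tolerance = 1e-12)
  }
})

test_that("k = 1 yields a single cluster with the cube mean spectrum", {
  cube <- .phClean$cube
  cl <- kmeansCluster(cube, 1, seed = 1)
  lab <- clusterLabels(cl)
  expect_true(all(lab[validMask(cube)] == 0L))
  expect_equal(meanSpectra(cl)[1, ],
               colMeans(spectra(cube)[validMask(cube), ]),
               tolerance = 1e-12)
  expect_error(kmeansCluster(cube, sum(validMask(cube)) + 1L, seed = 1),
               "config error")
})

test_that("cluster mean spectra equal member-pixel arithmetic means", {
  cube <- .phClean$cube
  cl <- kmeansCluster(cube, 4, seed = 9)
  lab <- clusterLabels(cl)
  for (k in 0:3) {
    member <- which(lab == k)
    expect_equal(meanSpectra(cl)[k + 1, ],
                 colMeans(spectra(cube)[member, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # two-pixel cluster: mean is (v + w) / 2
  ax <- seq(400, 430, by = 2)
  v <- runif(16); w <- runif(16)
  c2 <- RamanCube(rbind(v, w), ax, 2, 1)
  ms <- clusterMeanSpectra(c2, c(0L, 0L))
  expect_equal(intensity(ms$cluster0), (v + w) / 2)
  # constant-spectrum cluster reproduces that spectrum exactly
  c3 <- RamanCube(rbind(v, v, v), ax, 3, 1)
  expect_equal(intensity(clusterMeanSpectra(c3, c(0L, 0L, 0L))$cluster0),
               v)
  # phantom nucleus mean tracks the nucleus mixture at low noise
  nucMask <- compartmentMasks(.phClean$truth)$nucleus
  msn <- colMeans(spectra(.phClean$cube)[nucMask, ])
  C <- trueConcentrations(.phClean$truth)
  ref <- colMeans(C[nucMask, , drop = FALSE] %*%
                    .phClean$truth@referenceSpectra)
  expect_gte(cor(msn, ref), 0.99)
})

test_that("silhouette scan selects the right k on separable data", {
  # two well-separated blobs -> k = 2
  ax <- seq(400, 462, by = 2)
  set.seed(3)
  S <- rbind(matrix(rep(c(rep(1, 16), rep(0, 16)), 8), 8, byrow = TRUE),
             matrix(rep(c(rep(0, 16), rep(1, 16)), 8), 8, byrow = TRUE))
  S <- S + matrix(rnorm(length(S), sd = 0.01), nrow(S))
  cube <- RamanCube(S, ax, 4, 4)
  sel <- selectK(cube, 2:5, seed = 1)
  expect_equal(sel$k, 2L)
  # the profile reports every candidate k
  expect_equal(sel$profile$k, 2:5)
  expect_true(all(is.finite(sel$profile$silhouette)))
  # degenerate cube
  flat <- toyCube(width = 4, height = 4, value = 2)
  expect_error(selectK(flat, 2:3, seed = 1), "selection error")
  expect_error(selectK(cube, 2:40, seed = 1), "config error")
})

test_that("endmember extraction with NNLS recovers a noiseless mixture", {
  ax <- seq(400, 1800, by = 2)
  bands <- defaultReferenceBands()
  E <- rbind(intensity(makeReferenceSpectrum(bands$glycogen, ax)),
             intensity(makeReferenceSpectrum(bands$cholesterol, ax)),
             intensity(makeReferenceSpectrum(bands$tryptophan, ax)))
  set.seed(11)
  A <- matrix(runif(64 * 3), ncol = 3)
  A <- A / rowSums(A)
  A[1, ] <- c(1, 0, 0); A[2, ] <- c(0, 1, 0); A[3, ] <- c(0, 0, 1)
  cube <- RamanCube(A %*% E, ax, 8, 8)
  um <- trueComponentAnalysis(cube, 3, seed = 1)
  p <- bestPermutation(E, endmembers(um))
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (i in 1:3)
    expect_gte(cosv(E[i, ], endmembers(um)[p[i], ]), 0.99)
  expect_lte(sqrt(mean((A - abundances(um)[, p])^2)), 0.05)
})

test_that("unmixing invariants hold: non-negativity, residual bookkeeping, monotonicity", {
  cube <- .phClean$cube
  um <- trueComponentAnalysis(cube, 4, seed = 1)
  ab <- abundances(um)
  expect_true(all(ab[!is.na(ab)] >= 0))
  # reported residual equals the reconstruction RMS at every pixel
  m <- validMask(cube)
  rec <- ab[m, ] %*% endmembers(um)
  rms <- sqrt(rowMeans((spectra(cube)[m, ] - rec)^2))
  expect_equal(rms, unmixResiduals(um)[m], tolerance = 1e-10)
  # residual weakly decreasing in the component count
  med <- vapply(1:6, function(k)
    median(unmixResiduals(trueComponentAnalysis(cube, k, seed = 1)),
           na.rm = TRUE), numeric(1))
  expect_true(all(diff(med) <= 1e-10))
})

test_that("a single-component cube yields one proportional endmember", {
  ax <- seq(400, 700, by = 2)
  ref <- intensity(makeReferenceSpectrum(
    data.frame(center = 520, amplitude = 1, sigma = 6, eta = 0.3), ax))
  cube <- RamanCube(matrix(rep(3 * ref, 9), 9, byrow = TRUE), ax, 3, 3)
  um <- trueComponentAnalysis(cube, 1, seed = 1)
  cosv <- sum(endmembers(um)[1, ] * ref) /
    sqrt(sum(endmembers(um)[1, ]^2) * sum(ref^2))
  expect_gte(cosv, 1 - 1e-10)
  expect_lt(diff(range(abundances(um)[, 1])), 1e-9)
})

test_that("difference peaks surface the discriminating bands", {
  pre <- .phPre
  cl <- kmeansCluster(pre, 5, seed = 42)
  pk <- differencePeaks(cl)
  ann <- annotateClusters(pk)
  # the lipid-droplet cluster carries a triglyceride C=O candidate
  lip <- ann$cluster[ann$class == "lipid droplet"]
  expect_length(lip, 1L)
  top <- head(pk[[lip]], 5)
  expect_true(any(abs(top$position - 1746) <= 8))
  # ranking is strictly sorted by prominence
  for (p in pk)
    expect_true(all(diff(p$prominence) <= 0))
  # identical spectra give no difference peaks
  M <- rbind(rep(1, 32), rep(1, 32))
  expect_equal(nrow(differencePeaks(M, wavenumbers = seq(400, 462, 2))[[1]]),
               0L)
  expect_error(differencePeaks(M[1, , drop = FALSE],
                               wavenumbers = seq(400, 462, 2)),
               "at least 2")
})
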