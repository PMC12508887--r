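test_that("axis calibration maps the silicon apex onto the reference", {
  w <- seq(400, 700, by = 2)
  si <- Spectrum(w, exp(-(w - 522.5)^2 / (2 * 4^2)))
  cal <- calibrateAxis(si, si)
  # closed-form Gaussian apex is 522.5; quadratic interpolation must
  # recover it to better than 0.05 cm^-1, hence offset -2.5
  expect_equal(cal$apex, 522.5, tolerance = 0.05 / 522.5)
  expect_equal(cal$offset, -2.5, tolerance = 0.02)
  re <- calibrateAxis(cal$result, cal$result)
  expect_equal(re$apex, 520, tolerance = 0.05 / 520)

  # already-calibrated reference: offset 0
  si0 <- Spectrum(w, exp(-(w - 520)^2 / (2 * 4^2)))
  expect_equal(calibrateAxis(si0, si0)$offset, 0, tolerance = 1e-9)

  # shipped default reference position is 520 cm^-1
  expect_equal(formals(calibrateAxis)$referencePosition, 520)

  # no peak in the search window
  flat <- Spectrum(w, rep(1, length(w)))
  expect_error(calibrateAxis(flat, flat), "calibration error")
  # large offsets are applied but warned about
  far <- Spectrum(w, exp(-(w - 545)^2 / (2 * 4^2)))
  expect_warning(calibrateAxis(far, far, searchHalfWidth = 40),
                 "exceeds 15")
})

test_that("cosmic-ray removal flags injected spikes and repairs them", {
  ph <- makeCellPhantom(width = 24, height = 24, seed = 11, nSpikes = 0)
  clean <- makeCellPhantom(width = 24, height = 24, seed = 11,
                           nSpikes = 0)$cube
  cube <- ph$cube
  S <- spectra(cube)
  mask <- validMask(cube)
  target <- which(mask)[10]
  # one spike of 50x the local intensity
  ch <- 300L
  S[target, ch] <- S[target, ch] + 50 * max(abs(S[target, ]), 1)
  spiked <- RamanCube(S, wavenumber(cube), 24, 24, mask = mask)
  res <- removeCosmicRays(spiked, preprocessConfig())
  idx <- res$report$row * 24 + res$report$col + 1
  expect_true(any(idx == target & res$report$channel == ch))
  # corrected value back within the noise envelope of the clean truth
  noiseSD <- ph$truth@noise$s0 *
    sqrt(max(spectra(clean)[target, ch], 0) + ph$truth@noise$floorVar)
  expect_lt(abs(spectra(res$cube)[target, ch] -
                  spectra(clean)[target, ch]), 6 * noiseSD + 1e-9)
  # unflagged channels never altered
  flagged <- cbind(idx, res$report$channel)
  untouched <- spectra(res$cube)
  untouched[flagged] <- S[flagged]
  expect_identical(untouched, S)
})

test_that("two adjacent spiked channels are both repaired", {
  cube <- toyCube(width = 4, height = 4, nchan = 64, value = 5,
                  noise = 0.05, seed = 2)
  S <- spectra(cube)
  S[6, 30] <- S[6, 30] + 200
  S[6, 31] <- S[6, 31] + 150
  spiked <- RamanCube(S, wavenumber(cube), 4, 4)
  res <- removeCosmicRays(spiked, preprocessConfig())
  hit <- res$report$row * 4 + res$report$col + 1 == 6
  expect_setequal(intersect(res$report$channel[hit], 30:31), 30:31)
  expect_lt(abs(spectra(res$cube)[6, 30] - 5), 0.5)
})

test_that("a spike-free smooth cube passes through unchanged", {
  cube <- toyCube(width = 5, height = 5, nchan = 64, value = 3,
                  noise = 0.02, seed = 4)
  res <- removeCosmicRays(cube, preprocessConfig())
  expect_equal(nrow(res$report), 0L)
  expect_identical(spectra(res$cube), spectra(cube))
})

test_that("baseline correction recovers band area over a sloped background", {
  w <- seq(400, 1800, by = 2)
  amp <- 5; sig <- 6; ctr <- 1000
  y <- amp * exp(-(w - ctr)^2 / (2 * sig^2)) + 0.01 * (w - 400) + 2
  res <- correctBaseline(Spectrum(w, y), preprocessConfig())
  corr <- intensity(res$result)
  area <- sum(diff(w) * (head(corr, -1) + tail(corr, -1)) / 2)
  trueArea <- amp * sig * sqrt(2 * pi)           # erf over the full axis
  expect_lt(abs(area - trueArea) / trueArea, 0.05)
  # stored baseline reproduces the subtraction
  expect_equal(y - res$baseline, corr, tolerance = 1e-12)

  # pure peak on zero baseline: near identity (within 1% of peak height)
  y2 <- amp * exp(-(w - ctr)^2 / (2 * sig^2))
  res2 <- correctBaseline(Spectrum(w, y2), preprocessConfig())
  expect_lt(max(abs(intensity(res2$result) - y2)), 0.01 * amp)

  # peakless cubic polynomial: residual RMS < 1% of input RMS
  u <- (w - 400) / 1400
  y3 <- 2 + u + 0.5 * u^2 - 0.3 * u^3
  res3 <- correctBaseline(Spectrum(w, y3), preprocessConfig())
  expect_lt(sqrt(mean(intensity(res3$result)^2)) / sqrt(mean(y3^2)),
            0.01)

  # polynomial method also flattens a polynomial background
  res4 <- correctBaseline(Spectrum(w, y3),
                          preprocessConfig(baselineMethod = "poly"))
  expect_lt(sqrt(mean(intensity(res4$result)^2)) / sqrt(mean(y3^2)),
            0.01)
})

test_that("baseline correction is idempotent and scale-equivariant", {
  ph <- makeCellPhantom(width = 24, height = 24, seed = 4, nSpikes = 0,
                        snr = 50)
  cfg <- preprocessConfig()
  b1 <- correctBaseline(ph$cube, cfg)
  b2 <- correctBaseline(b1$result, cfg)
  m <- validMask(ph$cube)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(spectra(b2$result)[m, ] - spectra(b1$result)[m, ]) /
              rms(spectra(b1$result)[m, ]), 0.01)
  # f(c * S) = c * f(S): the asymmetric weights depend only on the
  # sign of the residual
  sc <- RamanCube(spectra(ph$cube) * 7.3, wavenumber(ph$cube), 24, 24,
                  mask = m)
  bs <- correctBaseline(sc, cfg)
  expect_equal(spectra(bs$result)[m, ], 7.3 * spectra(b1$result)[m, ],
               tolerance = 1e-9)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and shrinks noise", {
  w <- seq(400, 600, by = 2)
  u <- seq_along(w)
  cfg <- preprocessConfig(sgWindow = 9L, sgOrder = 3L)
  y <- 2 + 0.5 * u - 0.03 * u^2 + 1e-4 * u^3
  sm <- smoothSavitzkyGolay(Spectrum(w, y), cfg)
  expect_equal(intensity(sm), y, tolerance = 1e-9)

  set.seed(8)
  noise <- rnorm(length(w))
  smn <- smoothSavitzkyGolay(Spectrum(w, noise + 10), cfg)
  expect_lt(var(intensity(smn)), var(noise + 10))

  # broad Gaussian (sigma = 4 channel spacings): area change < 1%
  g <- exp(-(w - 500)^2 / (2 * 8^2))
  smg <- smoothSavitzkyGolay(Spectrum(w, g), cfg)
  a0 <- peakArea(Spectrum(w, g), PeakWindow(500, 40))
  a1 <- peakArea(smg, PeakWindow(500, 40))
  expect_lt(abs(a1 - a0) / a0, 0.01)
  # scale equivariance
  smc <- smoothSavitzkyGolay(Spectrum(w, 3 * g), cfg)
  expect_equal(intensity(smc), 3 * intensity(smg), tolerance = 1e-12)

  expect_error(preprocessConfig(sgWindow = 8L), "odd")
  expect_error(preprocessConfig(sgWindow = 3L, sgOrder = 3L), "exceed")
  expect_error(smoothSavitzkyGolay(Spectrum(w, g),
                                   preprocessConfig(sgWindow = 299L)),
               "channel count")
})

test_that("PCA denoising improves a low-rank cube and can be exact", {
  ax <- seq(400, 800, by = 2)
  set.seed(5)
  basis <- matrix(rnorm(3 * length(ax)), 3)
  A <- matrix(runif(100 * 3), ncol = 3)
  clean <- A %*% basis
  noisy <- clean + matrix(rnorm(length(clean), sd = 0.05), nrow(clean))
  cube <- RamanCube(noisy, ax, 10, 10)
  res <- pcaDenoise(cube, preprocessConfig(pcaComponents = 3L))
  rmse <- function(x) sqrt(mean(x^2))
  expect_lt(rmse(spectra(res$cube) - clean), rmse(noisy - clean))
  expect_equal(res$nComponents, 3L)
  # variance target on an (almost) rank-3 cube retains >= 3 components
  res2 <- pcaDenoise(cube, preprocessConfig(pcaVariance = 0.99))
  expect_gte(res2$nComponents, 3L)
  # per-channel mean preserved to machine precision
  expect_equal(colMeans(spectra(res$cube)), colMeans(noisy),
               tolerance = 1e-12)
  # full component count reproduces the input exactly
  res3 <- pcaDenoise(cube, preprocessConfig(pcaComponents = 99L))
  expect_equal(spectra(res3$cube), noisy, tolerance = 1e-9)
  expect_error(preprocessConfig(pcaVariance = 1.5), "pcaVariance")
})

test_that("the preprocessing pipeline honors stage order and logs provenance", {
  cube <- .phClean$cube
  idres <- runPreprocess(cube, preprocessConfig(stageOrder = character(0)))
  expect_identical(spectra(idres$cube), spectra(cube))
  expect_length(idres$provenance, 0L)

  ph <- makeCellPhantom(width = 24, height = 24, seed = 13)
  cfgA <- preprocessConfig()                                  # crr first
  cfgB <- preprocessConfig(stageOrder = c("baseline", "crr", "sg"))
  outA <- runPreprocess(ph$cube, cfgA)
  outB <- runPreprocess(ph$cube, cfgB)
  expect_equal(vapply(outA$provenance, `[[`, "", "stage"),
               c("crr", "baseline", "sg"))
  expect_equal(vapply(outB$provenance, `[[`, "", "stage"),
               c("baseline", "crr", "sg"))
  # spike channels end up repaired under either order
  sp <- ph$truth@spikes
  for (out in list(outA, outB)) {
    fixed <- spectra(out$cube)[cbind(sp$pixel, sp$channel)]
    raw <- spectra(ph$cube)[cbind(sp$pixel, sp$channel)]
    expect_true(all(fixed < raw - 0.5 * sp$amplitude))
  }
})
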