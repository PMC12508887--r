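test_that("band integration matches the closed-form Gaussian area", {
  ax <- seq(400, 600, by = 2)
  sig <- 3
  y <- exp(-(ax - 484)^2 / (2 * sig^2))
  s <- Spectrum(ax, y)
  a <- peakArea(s, PeakWindow(484, 8))
  analytic <- sig * sqrt(2 * pi) * (2 * pnorm(8 / sig) - 1)
  expect_lt(abs(a - analytic) / analytic, 0.01)
  # zero spectrum integrates to zero; linearity in intensity
  expect_equal(peakArea(Spectrum(ax, numeric(length(ax))),
                        PeakWindow(484, 8)), 0)
  expect_equal(peakArea(Spectrum(ax, 5 * y), PeakWindow(484, 8)), 5 * a,
               tolerance = 1e-12)
  # window outside the axis range
  expect_error(peakArea(s, PeakWindow(3000, 8)), "config error")
  expect_error(peakArea(s, PeakWindow(484, 0.5)), ">= 2 channels")
})

test_that("fractional window bounds are interpolated exactly", {
  # piecewise-linear spectrum: trapezoid with interpolated bounds is exact
  ax <- seq(400, 600, by = 2)
  y <- 0.1 * (ax - 400)
  win <- PeakWindow(487, 7.5)         # bounds fall between channels
  a <- peakArea(Spectrum(ax, y), win)
  analytic <- 0.1 * ((494.5 - 400)^2 - (479.5 - 400)^2) / 2
  expect_equal(a, analytic, tolerance = 1e-12)
  # local chord baseline removes a straight background completely
  expect_equal(peakArea(Spectrum(ax, y), win, localBaseline = TRUE), 0,
               tolerance = 1e-10)
})

test_that("the shipped metabolite windows integrate on the default axis", {
  wins <- libraryWindows()
  expected <- c(glycogen = 484, NADH = 1114, squalene = 1379,
                lanosterol = 930, cholesterol = 1083, glucose = 1127,
                tryptophan = 1557, threonine = 1341)
  for (nm in names(expected))
    expect_equal(windowCenter(wins[[nm]]), unname(expected[nm]))
  cube <- .phClean$cube
  for (nm in names(expected)) {
    am <- integratePeak(cube, wins[[nm]])
    expect_true(all(is.finite(mapValues(am)[validMask(am)])))
  }
})

test_that("ratio maps divide areas and cancel per-pixel gain", {
  cube <- .phClean$cube
  num <- integratePeak(cube, PeakWindow(484, 8))
  den <- integratePeak(cube, PeakWindow(1341, 8))
  # numerator = 2 x denominator -> ratio exactly 2
  num2 <- den
  num2@values <- den@values * 2
  r2 <- ratioMap(num2, den)
  expect_true(all(abs(mapValues(r2)[validMask(r2)] - 2) < 1e-12))
  # per-pixel gain cancels to machine precision
  g <- 0.5 + runif(length(validMask(cube)))
  gcube <- RamanCube(spectra(cube) * g, wavenumber(cube),
                     cubeDim(cube)["width"], cubeDim(cube)["height"],
                     mask = validMask(cube))
  r1 <- ratioMap(num, den)
  rg <- ratioMap(integratePeak(gcube, PeakWindow(484, 8)),
                 integratePeak(gcube, PeakWindow(1341, 8)))
  m <- validMask(r1) & validMask(rg)
  expect_equal(mapValues(rg)[m], mapValues(r1)[m], tolerance = 1e-12)
  # raw areas do NOT survive the gain (the point of normalization)
  expect_gt(max(abs(mapValues(integratePeak(gcube, PeakWindow(484, 8)))[m] -
                      mapValues(num)[m])), 1e-3)
  # zero denominator -> invalid pixel
  den0 <- den
  den0@values[den0@valid][1] <- 0
  rz <- ratioMap(num, den0)
  expect_false(validMask(rz)[which(den@valid)[1]])
  # negative areas flagged but retained
  numn <- num
  numn@values[num@valid][2] <- -1
  rn <- ratioMap(numn, den)
  idx <- which(num@valid)[2]
  expect_true(rn@flaggedNegative[idx])
  expect_true(validMask(rn)[idx])
  expect_lt(mapValues(rn)[idx], 0)
  # shape mismatch
  small <- integratePeak(toyCube(), PeakWindow(420, 8))
  expect_error(ratioMap(num, small), "grid error")
})

test_that("internal-standard ranking prefers the spatially uniform band", {
  sel <- selectInternalStandard(.phPre, libraryWindows())
  expect_equal(windowCenter(sel$chosen), 1341)
  expect_equal(sel$ranking$center[1], 1341)
  expect_true(all(diff(sel$ranking$cv) >= 0))
  expect_lte(nrow(sel$ranking), length(libraryWindows()))
  # exactly uniform candidates tie-break to the lowest center
  cube <- toyCube(width = 4, height = 4, nchan = 600, value = 1)
  cands <- list(PeakWindow(800, 8), PeakWindow(500, 8))
  sel2 <- selectInternalStandard(cube, cands)
  expect_equal(windowCenter(sel2$chosen), 500)
  # all-negative candidates are disqualified
  neg <- RamanCube(matrix(-1, 16, 600), wavenumber(cube), 4, 4)
  expect_error(selectInternalStandard(neg, cands), "selection error")
})

test_that("compartment statistics summarize valid pixels only", {
  d <- 40L
  vals <- rep(2.5, d * d)
  ok <- rep(TRUE, d * d)
  am <- new("AreaMap", values = vals, valid = ok, width = d, height = d,
            window = PeakWindow(484, 8))
  st <- compartmentStats(am, rep(0L, d * d), groupTag = "InS")
  expect_equal(st$mean, 2.5)
  expect_equal(st$sd, 0)
  expect_equal(st$n, d * d)
  expect_equal(st$group, "InS")
  # Gaussian field: sample mean within 3 sigma / sqrt(n) of mu
  set.seed(1)
  mu <- 4; sigma <- 0.5; n <- 1e4
  am2 <- new("AreaMap", values = rnorm(n, mu, sigma),
             valid = rep(TRUE, n), width = 100L, height = 100L,
             window = PeakWindow(484, 8))
  st2 <- compartmentStats(am2, rep(0L, n))
  expect_lt(abs(st2$mean - mu), 3 * sigma / sqrt(n))
  # invalid pixels reduce n and never contribute
  am3 <- am2
  am3@valid[1:100] <- FALSE
  am3@values[1:100] <- 1e6
  st3 <- compartmentStats(am3, rep(0L, n))
  expect_equal(st3$n, n - 100L)
  expect_lt(abs(st3$mean - mu), 0.1)
  # a label with zero valid pixels is omitted with a warning
  lab <- rep(0L, n); lab[1:100] <- 1L
  expect_warning(st4 <- compartmentStats(am3, lab), "no valid pixels")
  expect_equal(nrow(st4), 1L)
})

test_that("calibration fitting is exact on a line and rejects degenerate input", {
  cc <- 1:5
  fit <- fitCalibration(data.frame(concentration = cc,
                                   deltaA = 0.5 * cc + 0.1))
  expect_equal(calibrationSlope(fit), 0.5, tolerance = 1e-10)
  expect_equal(calibrationIntercept(fit), 0.1, tolerance = 1e-10)
  expect_equal(calibrationRSquared(fit), 1, tolerance = 1e-12)
  expect_error(fitCalibration(data.frame(concentration = c(2, 2, 2),
                                         deltaA = 1:3)), "fit error")
  expect_error(fitCalibration(data.frame(concentration = 1:2,
                                         deltaA = 1:2)), "fit error")
})

test_that("dA responds monotonically to true concentration", {
  # 5-point sweep of glycogen in strain A, everything else fixed
  sweep <- c(0.4, 0.7, 1.0, 1.3, 1.6)
  means <- vapply(sweep, function(g) {
    conc <- defaultPhantomConcentrations()
    conc$`symbiont A`["glycogen"] <- g
    ph <- makeCellPhantom(width = 24, height = 24, snr = 50, seed = 5,
                          nSpikes = 0, baseline = FALSE,
                          concentrations = conc)
    rmz <- ratioMap(integratePeak(ph$cube, PeakWindow(484, 8)),
                    integratePeak(ph$cube, PeakWindow(1341, 8)))
    st <- compartmentStats(rmz, ph$truth,
                           labelNames = ph$truth@compartments)
    st$mean[st$label == "symbiont A"]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # the response is proportional (semi-quantitative contract)
  fit <- fitCalibration(data.frame(concentration = sweep, deltaA = means))
  expect_gte(calibrationRSquared(fit), 0.99)
})

test_that("the end-to-end pipeline recovers concentration contrasts", {
  ph <- makeCellPhantom(seed = 21)
  lib <- libraryWindows()
  # windows whose bands are not spectrally confounded with another
  # compartment's marker in the phantom
  wins <- lib[c("glycogen", "triglyceride", "tryptophan",
                "phenylalanine", "squalene")]
  bundle <- runMQA(ph$cube, list(windows = wins, k = 5, seed = 42))
  expect_s4_class(bundle$clusters, "ClusterResult")
  expect_gte(adjustedRand(clusterLabels(bundle$clusters),
                          clusterLabels(ph$truth)), 0.9)
  C <- trueConcentrations(ph$truth)
  labs <- ph$truth@labels
  for (met in names(wins)) {
    st <- compartmentStats(bundle$ratios[[met]], ph$truth)
    truemean <- vapply(1:5, function(i)
      mean(C[!is.na(labs) & labs == i, met]), numeric(1))
    f <- sum(st$mean * truemean) / sum(truemean^2)
    expect_lt(max(abs(st$mean - f * truemean)), 0.10 * max(f * truemean))
  }
  expect_error(runMQA(ph$cube, list(k = 5)), "usage error")
})

test_that("group tags flow through to the cross-group table", {
  wins <- libraryWindows()["cholesterol"]
  cfg <- function(tag) list(windows = wins, k = 3, seed = 1,
                            groupTag = tag,
                            preprocess = preprocessConfig(
                              stageOrder = character(0)))
  b1 <- runMQA(.phClean$cube, cfg("InS"))
  b2 <- runMQA(.phClean$cube, cfg("D10w"))
  tab <- rbind(b1$stats, b2$stats)
  expect_setequal(unique(tab$group), c("InS", "D10w"))
})
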