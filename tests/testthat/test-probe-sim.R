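## Synthetic-data generator: ground-truth decays, wraparound, photon
## accounting, detector artifacts, spectral series and FLIM images.

test_that("wrapped ground-truth density has the geometric-series closed form", {
  mono <- constantProbe(tau = 2)
  ## T >> tau: wraparound negligible, pure exponential ratio
  r <- groundTruthDecay(mono, 510, t = 2, period = 50) /
    groundTruthDecay(mono, 510, t = 0, period = 50)
  expect_equal(r, exp(-1), tolerance = 1e-6)

  ## 80 MHz with tau = 5: wraparound boosts the density by 1/(1 - e^-2.5)
  mono5 <- constantProbe(tau = 5)
  boost <- groundTruthDecay(mono5, 510, t = 0, period = 12.5) /
    exp(0)                              # unwrapped density at 0 is a = 1
  expect_equal(boost, 1 / (1 - exp(-2.5)), tolerance = 1e-12)

  ## two components, T -> infinity: density at origin is the amplitude sum
  bi <- uniformProbe(c(0.5, 0.5), c(1, 3))
  expect_equal(groundTruthDecay(bi, 510, 0, period = 1e6), 1,
               tolerance = 1e-6)

  expect_error(groundTruthDecay(mono, 900, 0, 50), "window")
  expect_error(groundTruthDecay(mono, 510, 51, 50), "period")
})

test_that("probe models obey the spectral invariants", {
  for (nm in c("flipperLd", "flipperLo", "nr12Ld", "nr12Lo")) {
    p <- probePreset(nm)
    tm <- probeMeanLifetime(p)
    cen <- p@windows$center
    pre <- cen <= p@plateau
    expect_true(all(diff(tm[pre]) >= -1e-9), info = nm)
    if (any(!pre)) {
      post <- unname(tm[!pre])
      expect_equal(post, rep(post[1], length(post)), tolerance = 1e-9,
                   info = nm)                      # constant beyond plateau
      expect_gte(post[1], unname(tm[sum(pre)]) - 1e-9)
    }
    for (cmp in p@components) {
      expect_equal(sum(cmp$amplitudes), 1, tolerance = 1e-9)
      expect_true(all(cmp$lifetimes > 0))
    }
  }
  ## the anchor lifetimes are exact by construction
  expect_equal(probeMeanLifetime(probePreset("flipperLd"), 570), 4.0)
  expect_equal(probeMeanLifetime(probePreset("flipperLo"), 570), 5.6)
  ## invalid construction is rejected
  expect_error(relaxationProbe("bad", tauMin = 4, tauAnchor = 3))
})

test_that("photon accounting is exact and Poisson in the mean", {
  acq <- acq20(5)
  mono <- constantProbe(tau = 4)
  h <- simulateDecay(mono, 510, acq, nPhotons = 12345)
  expect_equal(totalPhotons(h), 12345)

  ## per-pulse mode: total ~ Poisson(nPulses * mu * efficiency)
  acqLow <- acquisitionConfig(mu = 0.01, efficiency = 0.8, seed = 2)
  hp <- simulateDecay(mono, 510, acqLow, nPulses = 2e5)
  lambda <- 2e5 * 0.01 * 0.8
  expect_lt(abs(totalPhotons(hp) - lambda), 3 * sqrt(lambda))

  expect_error(simulateDecay(mono, 510, acq), "nPulses or nPhotons")
  expect_error(acquisitionConfig(mu = -1), "positive")
})

test_that("pile-up over-represents early photons; the filter removes them", {
  mono <- constantProbe(tau = 4)
  meanArrival <- function(pileUp, filter, seed = 3) {
    acq <- acquisitionConfig(mu = 0.5, pileUp = pileUp,
                             singlePhotonFilter = filter, seed = seed)
    h <- simulateDecay(mono, 510, acq, nPulses = 1e5)
    sum(timeBins(h) * counts(h)) / totalPhotons(h)
  }
  tPile <- meanArrival(TRUE, FALSE)
  tFree <- meanArrival(FALSE, FALSE)
  tFilt <- meanArrival(TRUE, TRUE)
  expect_lt(tPile, tFree)                  # dead time biases arrivals early
  expect_lt(abs(tFilt - tFree), 0.1)       # filter restores the decay shape
  expect_lt(tFree - tPile, tFree - 0)      # sanity: effect is partial
})

test_that("spectral series conserves the photon budget across windows", {
  p <- probePreset("nr12Ld")
  acq <- acq20(7)
  ser <- simulateSpectralSeries(p, acq, photons = 54321)
  tot <- vapply(ser, totalPhotons, numeric(1))
  expect_equal(sum(tot), 54321)
  ## brightness ordering follows the emission-spectrum weights
  expect_identical(order(tot), order(p@weights))
  ## deterministic under the same seed
  ser2 <- simulateSpectralSeries(p, acq, photons = 54321)
  expect_identical(lapply(ser, counts), lapply(ser2, counts))
})

test_that("simulated wraparound matches the periodic model (chi2 ~ 1)", {
  mono <- constantProbe(tau = 5)
  acq <- acquisitionConfig(rateMHz = 80, seed = 9)
  h <- simulateDecay(mono, 510, acq, nPhotons = 2e5)
  fr <- fitDecay(h, gaussianIRF(acq), n = 1)
  expect_true(fr@converged)
  expect_gt(chiSqRed(fr), 0.8)
  expect_lt(chiSqRed(fr), 1.2)
  expect_equal(tauAvInt(fr), 5, tolerance = 0.02)
})

test_that("FLIM image simulation is deterministic and label-faithful", {
  map <- twoPhaseDisc(n = 16, photonsPerPixel = 400)
  acq <- acquisitionConfig(binWidth = 0.2, seed = 11)
  img1 <- simulateFlimImage(map, acq)
  img2 <- simulateFlimImage(map, acq)
  expect_identical(img1@channels, img2@channels)
  ## background pixels receive nothing by default
  bg <- img1@meta$labels == 0L
  expect_equal(sum(apply(img1@channels$green, c(1, 2), sum)[bg]), 0)
  ## Lo pixels live longer than Ld pixels in both channels
  irf <- gaussianIRF(acq)
  lab <- img1@meta$labels
  for (ch in c("green", "red")) {
    tLo <- tauAvInt(fitDecay(poolROI(img1, lab == 2L, ch), irf, n = 2,
                             qcOverride = TRUE))
    tLd <- tauAvInt(fitDecay(poolROI(img1, lab == 1L, ch), irf, n = 2,
                             qcOverride = TRUE))
    expect_gt(tLo, tLd)
  }
})

test_that("homogeneous image pools to the ground-truth lifetime", {
  lab <- matrix(1L, 12, 12)
  map <- phaseMap(lab, ld = probePreset("nr12Ld"), lo = probePreset("nr12Lo"),
                  photonsPerPixel = 1200)
  acq <- acquisitionConfig(binWidth = 0.1, seed = 13)
  img <- simulateFlimImage(map, acq)
  pooled <- poolWholeImage(img, "green")
  expect_gt(totalPhotons(pooled), 1e5 * 0.5)
  truth <- probeMeanLifetime(probeBroadband(probePreset("nr12Ld"),
                                            c(500, 600)), 1)
  fit <- tauAvInt(fitDecay(pooled, gaussianIRF(acq), n = 2,
                           estimator = "mle"))
  expect_equal(fit, truth, tolerance = 0.02)
})

test_that("substream seeds are stable and order-independent", {
  s1 <- substreamSeed(42, 1)
  expect_identical(s1, substreamSeed(42, 1))
  expect_false(substreamSeed(42, 2) == s1)
  expect_false(substreamSeed(43, 1) == s1)
  expect_true(all(vapply(1:100, function(i)
    substreamSeed(7, i) > 0 && substreamSeed(7, i) < 2^31, logical(1))))
})
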