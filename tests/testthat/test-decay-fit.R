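## Reconvolution fitting, intensity-weighted lifetime, QC, combining and
## the repetition-rate advisory.

test_that("intensity-weighted mean lifetime follows the component intensities", {
  expect_equal(intensityWeightedLifetime(decayModel(1, 4)), 4)
  ## a = (0.5, 0.5), tau = (1, 3): sum(a tau^2)/sum(a tau) = 5/2
  expect_equal(intensityWeightedLifetime(decayModel(c(0.5, 0.5), c(1, 3))),
               2.5)
  ## zero-amplitude components are ignored
  expect_equal(intensityWeightedLifetime(decayModel(c(1, 0), c(2, 7))), 2)
  expect_error(intensityWeightedLifetime(decayModel(c(0, 0), c(2, 7))),
               "undefined")
})

test_that("tauAvInt lies between the extreme component lifetimes", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:3, 1)
    m <- decayModel(runif(n, 0.1, 2), sort(runif(n, 0.2, 12)))
    tau <- intensityWeightedLifetime(m)
    expect_gte(tau, min(lifetimes(m)) - 1e-12)
    expect_lte(tau, max(lifetimes(m)) + 1e-12)
  }
})

test_that("photon-count QC uses the strict 10^4 exclusion threshold", {
  mk <- function(total) decayHistogram(c(total, numeric(9)), period = 50,
                                       binWidth = 5)
  expect_false(qcFilter(mk(9999)))
  expect_true(qcFilter(mk(10000)))
  expect_false(qcFilter(mk(0)))
  expect_equal(qcAdvisoryMinimum(1:3), c(1e2, 1e4, 1e6))
  expect_error(qcAdvisoryMinimum(4), "1, 2 or 3")
})

test_that("default fit ranges match the per-rate windows", {
  expect_equal(defaultFitRange(20), c(0.2, 45))
  expect_equal(defaultFitRange(40), c(0.2, 25))
  expect_equal(defaultFitRange(80), c(0.2, 12.5))
})

test_that("combining histograms is additive and axis-checked", {
  acq <- acq20(3)
  h1 <- simulateDecay(constantProbe(tau = 3), 510, acq, nPhotons = 1e5)
  h0 <- decayHistogram(numeric(length(counts(h1))), period = 50,
                       time = timeBins(h1))
  expect_identical(counts(combineHistograms(list(h1, h0))), counts(h1))

  h2 <- simulateDecay(constantProbe(tau = 5), 510, acq, nPhotons = 1e5,
                      seed = 8)
  comb <- combineHistograms(list(h1, h2))
  expect_equal(totalPhotons(comb), totalPhotons(h1) + totalPhotons(h2))
  ## equal-photon mixture of 3 and 5 ns fits strictly between
  tau <- tauAvInt(fitDecay(comb, gaussianIRF(acq), n = 2))
  expect_gt(tau, 3); expect_lt(tau, 5)

  hBad <- decayHistogram(numeric(10), period = 50, binWidth = 5)
  expect_error(combineHistograms(list(h1, hBad)), "axis mismatch")
})

test_that("repetition-rate advisory is ten lifetimes between pulses", {
  expect_equal(recommendRepetition(5), list(tRepeat = 50, rateMHz = 20))
  expect_equal(recommendRepetition(1), list(tRepeat = 10, rateMHz = 100))
  expect_equal(recommendRepetition(2.5), list(tRepeat = 25, rateMHz = 40))
  expect_error(recommendRepetition(0), "positive")
})

test_that("reconvolution matches continuous quadrature of IRF x decay", {
  ## fine bins so discretization is negligible against the oracle
  acq <- acquisitionConfig(binWidth = 0.01, seed = 1)
  irf <- gaussianIRF(acq)
  tau <- 3; period <- 50
  out <- reconvolve(decayModel(1, tau), irf)
  sigma <- acq@irfFwhm / (2 * sqrt(2 * log(2)))
  oracle <- function(t) {        # numeric quadrature, wraparound-summed
    stats::integrate(function(u)
      stats::dnorm(u, acq@irfCenter, sigma) *
        exp(-((t - u) %% period) / tau) / (1 - exp(-period / tau)),
      acq@irfCenter - 8 * sigma, acq@irfCenter + 8 * sigma,
      rel.tol = 1e-10)$value
  }
  probe <- c(1.5, 2.0, 2.1, 2.5, 5, 20, 45)   # spans rise, peak and tail
  idx <- round(probe / acq@binWidth + 0.5)
  exact <- vapply(timeBins(irf)[idx], oracle, numeric(1))
  expect_equal(out[idx], exact, tolerance = 1e-3)

  ## discretization error shrinks when bins shrink
  errAt <- function(bw) {
    a <- acquisitionConfig(binWidth = bw, seed = 1)
    o <- reconvolve(decayModel(1, tau), gaussianIRF(a))
    i <- round(2.1 / bw + 0.5)
    abs(o[i] - oracle(timeBins(gaussianIRF(a))[i]))
  }
  expect_lt(errAt(0.01), errAt(0.02))
})

test_that("the IRF shift is circularly equivariant", {
  acq <- acq20(1)
  irf <- gaussianIRF(acq)
  base <- reconvolve(decayModel(1, 4, shift = 0), irf)
  shifted <- reconvolve(decayModel(1, 4, shift = 3 * acq@binWidth), irf)
  rotated <- c(tail(base, 3), head(base, -3))
  expect_equal(shifted, rotated, tolerance = 1e-8)
})

test_that("noise-free fits recover the generating parameters", {
  acq <- acq20(1)
  irf <- gaussianIRF(acq)
  true <- decayModel(c(4e4, 2e4), c(1.8, 5.2), offset = 0.3, shift = 0.015)
  h <- noiseFreeHistogram(true, irf)
  fr <- fitDecay(h, irf, n = 2, qcOverride = TRUE)
  expect_true(fr@converged)
  expect_equal(lifetimes(fr), c(1.8, 5.2), tolerance = 1e-4)
  expect_equal(tauAvInt(fr), intensityWeightedLifetime(true),
               tolerance = 1e-4)
})

test_that("simulated monoexponentials are recovered within 2 percent", {
  mono <- constantProbe(tau = 4)
  acq <- acq20(1)
  irf <- gaussianIRF(acq)
  taus <- vapply(1:5, function(s)
    tauAvInt(fitDecay(simulateDecay(mono, 510, acq, nPhotons = 1e5,
                                    seed = s), irf, n = 1)),
    numeric(1))
  expect_equal(mean(taus), 4, tolerance = 0.02)
})

test_that("Neyman chi-square is calibrated when bins are well populated", {
  ## at 80 MHz the wrapped decay keeps every bin far from zero counts
  mono <- constantProbe(tau = 4)
  acq <- acquisitionConfig(rateMHz = 80, seed = 1)
  irf <- gaussianIRF(acq)
  ch <- vapply(1:100, function(s)
    chiSqRed(fitDecay(simulateDecay(mono, 510, acq, nPhotons = 1e5,
                                    seed = s), irf, n = 1)),
    numeric(1))
  expect_gt(mean(ch), 0.9)
  expect_lt(mean(ch), 1.1)
})

test_that("fit configuration errors are reported before fitting", {
  acq <- acq20(1)
  irf <- gaussianIRF(acq)
  h <- simulateDecay(constantProbe(tau = 4), 510, acq, nPhotons = 500)
  expect_error(fitDecay(h, irf, n = 4), "1, 2 or 3")
  expect_error(fitDecay(h, irf, n = 1), "QC")
  expect_s4_class(fitDecay(h, irf, n = 1, qcOverride = TRUE), "FitResult")
})
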