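## Spectral lifetime profiles, normalized spectra, GP and delta-tau.

## build a profile directly from intensities/lifetimes without simulation
mkProfile <- function(centers, tau, intensity, condition = "x") {
  new("SpectralLifetimeProfile",
      table = data.frame(center = centers, lower = centers - 10,
                         upper = centers + 10, tauAvInt = tau,
                         intensity = intensity, chiSqRed = 1,
                         nPhotons = intensity),
      condition = condition)
}

test_that("spectral profiles fit each window and drop QC failures", {
  acq <- acq20(2)
  irf <- gaussianIRF(acq)
  ser <- simulateSpectralSeries(probePreset("control"), acq,
                                photons = 3e5)
  expect_warning(prof <- spectralProfile(ser, irf, n = 1),
                 "dropped")
  tb <- as.data.frame(prof)
  expect_true(all(tb$nPhotons >= 1e4))
  expect_true(all(diff(tb$center) > 0))

  ## single surviving window equals a direct fit
  h <- ser[[which.max(vapply(ser, totalPhotons, numeric(1)))]]
  p1 <- spectralProfile(list(h), irf, n = 1)
  expect_equal(as.data.frame(p1)$tauAvInt,
               tauAvInt(fitDecay(h, irf, n = 1)))

  ## everything failing is an error
  tiny <- lapply(ser, function(x)
    decayHistogram(pmin(counts(x), 1), period = 50, time = timeBins(x),
                   window = spectralWindow(x)))
  expect_error(spectralProfile(tiny, irf), "empty profile")
})

test_that("noise-free flat and rising profiles are recovered as such", {
  acq <- acq20(1)
  irf <- gaussianIRF(acq)
  mk <- function(tau) {
    h <- noiseFreeHistogram(decayModel(3e4, tau), irf)
    h@counts <- round(h@counts)
    h
  }
  flat <- lapply(1:4, function(i) {
    h <- mk(4.1); h@window <- c(480 + 20 * i, 500 + 20 * i); h
  })
  pf <- spectralProfile(flat, irf, n = 1)
  expect_lt(diff(range(as.data.frame(pf)$tauAvInt)), 0.01)

  rising <- lapply(1:4, function(i) {
    h <- mk(3 + 0.3 * i); h@window <- c(480 + 20 * i, 500 + 20 * i); h
  })
  pr <- spectralProfile(rising, irf, n = 1)
  expect_true(all(diff(as.data.frame(pr)$tauAvInt) > 0.2))
})

test_that("normalized spectra scale to a unit maximum", {
  p <- mkProfile(c(510, 530, 550), c(3, 3, 3), c(2, 4, 8))
  expect_equal(unname(normalizedSpectrum(p)), c(0.25, 0.5, 1))
  ## scale invariance
  p10 <- mkProfile(c(510, 530, 550), c(3, 3, 3), 10 * c(2, 4, 8))
  expect_equal(normalizedSpectrum(p10), normalizedSpectrum(p))
  ## single window
  expect_equal(unname(normalizedSpectrum(mkProfile(510, 3, 7))), 1)
  ## all-zero undefined
  expect_error(normalizedSpectrum(mkProfile(510, 3, 0)), "undefined")
  ## the spline is for display only and leaves the values untouched
  both <- normalizedSpectrum(p, spline = TRUE)
  expect_equal(both$normalized, normalizedSpectrum(p))
  expect_true(is.data.frame(both$display))
})

test_that("GP is bounded, antisymmetric and scale-invariant", {
  expect_identical(gp(1, 0), 1)
  expect_identical(gp(0, 1), -1)
  expect_equal(gp(3, 3), 0)
  expect_equal(gp(1, 3), -0.5)
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    v <- gp(a, b)
    expect_gte(v, -1); expect_lte(v, 1)
    expect_equal(gp(b, a), -v)
    expect_equal(gp(13 * a, 13 * b), v)
  }
  expect_error(gp(0, 0), "undefined")
  expect_error(gp(-1, 2), "non-negative")
})

test_that("GP from a profile selects windows by containment", {
  cfg <- gpConfig(570, 650)
  ## blue-shifted (ordered-like) spectrum: positive GP
  lam <- seq(510, 690, by = 20)
  blue <- mkProfile(lam, rep(4, 10), exp(-(lam - 560)^2 / 5000) * 1e4)
  red <- mkProfile(lam, rep(4, 10), exp(-(lam - 660)^2 / 5000) * 1e4)
  expect_gt(gpFromProfile(blue, cfg), 0)
  expect_lt(gpFromProfile(red, cfg), 0)
  ## identical intensities give zero
  flat <- mkProfile(lam, rep(4, 10), rep(5, 10))
  expect_equal(gpFromProfile(flat, cfg), 0)
  expect_error(gpFromProfile(blue, gpConfig(400, 650)), "outside")
  expect_error(gpConfig(650, 570), "smaller")
})

test_that("delta tau is a signed per-window lifetime contrast", {
  lam <- seq(510, 690, by = 20)
  a <- mkProfile(lam, seq(4, 5.8, length.out = 10), rep(1e4, 10), "A")
  b <- mkProfile(lam, seq(3, 4.8, length.out = 10), rep(1e4, 10), "B")
  expect_equal(deltaTau(a, a, 570), 0)
  expect_equal(deltaTau(a, b, 570), -deltaTau(b, a, 570))
  expect_equal(deltaTau(a, b, 570), 1)
  expect_error(deltaTau(a, b, 480), "outside")
})
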