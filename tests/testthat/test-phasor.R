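## Phasor transform, calibration, semicircle geometry, lifetimes, maps.

test_that("phasor transform reproduces the closed forms", {
  ## all counts at the origin bin: (g, s) ~ (1, 0)
  h <- decayHistogram(c(1000, numeric(999)), period = 50, binWidth = 0.05)
  p <- phasorTransform(h)
  expect_equal(p@g, 1, tolerance = 1e-4)
  expect_equal(p@s, 0, tolerance = 1e-2)

  ## uniform counts: orthogonality sends both coordinates to zero
  hu <- decayHistogram(rep(5, 1000), period = 50, binWidth = 0.05)
  pu <- phasorTransform(hu)
  expect_lt(abs(pu@g), 1e-10)
  expect_lt(abs(pu@s), 1e-10)

  ## wrapped monoexponential at omega tau = 1: (0.5, 0.5)
  tau <- 50 / (2 * pi)
  hm <- decayHistogram(wrappedMonoCurve(tau, 50, 0.05), period = 50,
                       binWidth = 0.05)
  pm <- phasorTransform(hm)
  expect_equal(pm@g, 0.5, tolerance = 1e-3)
  expect_equal(pm@s, 0.5, tolerance = 1e-3)

  expect_error(phasorTransform(decayHistogram(numeric(10), period = 50,
                                              binWidth = 5)),
               "zero total")
})

test_that("discrete phasor converges to the continuous closed form", {
  tau <- 3; period <- 50
  err <- function(bw) {
    p <- phasorTransform(decayHistogram(wrappedMonoCurve(tau, period, bw),
                                        period = period, binWidth = bw))
    wt <- 2 * pi / period * tau
    sqrt((p@g - 1 / (1 + wt^2))^2 + (p@s - wt / (1 + wt^2))^2)
  }
  e <- vapply(c(0.2, 0.1, 0.05), err, numeric(1))
  expect_lt(e[2], 0.75 * e[1])
  expect_lt(e[3], 0.75 * e[2])
})

test_that("IRF calibration restores monoexponentials to the semicircle", {
  acq <- acq20(5)
  irf <- gaussianIRF(acq)
  irfPoint <- phasorTransform(irf)
  ## identity and self-calibration
  ident <- calibratePhasor(phasorPoint(0.3, 0.4, omega = 0.1),
                           phasorPoint(1, 0, omega = 0.1))
  expect_equal(c(ident@g, ident@s), c(0.3, 0.4))
  self <- calibratePhasor(irfPoint, irfPoint)
  expect_equal(c(self@g, self@s), c(1, 0))
  expect_error(calibratePhasor(irfPoint, phasorPoint(0, 0, omega = 0.1)),
               "zero modulus")

  ## simulated monoexponential through the Gaussian IRF
  h <- simulateDecay(constantProbe(tau = 4), 510, acq, nPhotons = 2e5)
  cal <- calibratePhasor(phasorTransform(h), irfPoint)
  expect_lt(abs(semicircleDistance(cal)), 1e-2)
})

test_that("semicircle distance is signed and mixtures lie inside", {
  expect_equal(semicircleDistance(phasorPoint(0.5, 0.5, omega = 1)), 0)
  expect_equal(semicircleDistance(phasorPoint(0.5, 0.25, omega = 1)), -0.25)
  ## any two-component mixture sits strictly inside
  mix <- phasorTransform(decayHistogram(
    0.5 * wrappedMonoCurve(1.5, 50, 0.05) +
      0.5 * wrappedMonoCurve(6, 50, 0.05), period = 50, binWidth = 0.05))
  expect_lt(semicircleDistance(mix), -1e-3)
})

test_that("phase and modulation lifetimes follow the phasor geometry", {
  omega <- 0.3
  lt <- phasorLifetimes(phasorPoint(0.5, 0.5, omega = omega))
  expect_equal(unname(lt), c(1 / omega, 1 / omega), tolerance = 1e-12)
  lt0 <- phasorLifetimes(phasorPoint(1, 0, omega = omega))
  expect_equal(unname(lt0), c(0, 0))
  expect_error(phasorLifetimes(phasorPoint(-0.1, 0.5, omega = omega)),
               "undefined")
  ## interior mixtures: phase lifetime < modulation lifetime, scanned
  ## over mixing fractions
  for (f in seq(0.1, 0.9, by = 0.2)) {
    mix <- phasorTransform(decayHistogram(
      f * wrappedMonoCurve(1.5, 50, 0.05) +
        (1 - f) * wrappedMonoCurve(6, 50, 0.05),
      period = 50, binWidth = 0.05))
    lt <- phasorLifetimes(mix)
    expect_lt(lt[["phase"]], lt[["modulation"]])
  }
})

test_that("phasors of mixtures lie on the chord between the endpoints", {
  w1 <- wrappedMonoCurve(2, 50, 0.05)
  w2 <- wrappedMonoCurve(6, 50, 0.05)
  pA <- phasorTransform(decayHistogram(w1, period = 50, binWidth = 0.05))
  pB <- phasorTransform(decayHistogram(w2, period = 50, binWidth = 0.05))
  v <- c(pB@g - pA@g, pB@s - pA@s)
  for (f in seq(0, 1, by = 0.1)) {
    pm <- phasorTransform(decayHistogram(f * w1 + (1 - f) * w2,
                                         period = 50, binWidth = 0.05))
    u <- c(pm@g - pA@g, pm@s - pA@s)
    dev <- abs(u[1] * v[2] - u[2] * v[1]) / sqrt(sum(v^2))
    expect_lt(dev, 1e-6)
  }
})

test_that("phasor maps pool to the single-decay phasor and denoise", {
  lab <- matrix(1L, 10, 10)
  mono <- constantProbe(tau = 4)
  map <- phaseMap(lab, ld = mono, lo = mono, photonsPerPixel = 800)
  acq <- acquisitionConfig(binWidth = 0.1, seed = 17)
  img <- simulateFlimImage(map, acq)
  pmRaw <- phasorMap(img, "green", filter = "none")
  pooled <- phasorTransform(poolWholeImage(img, "green"))
  ## photon-weighted centroid equals the pooled phasor
  gbar <- sum(pmRaw@g * pmRaw@photons) / sum(pmRaw@photons)
  expect_equal(gbar, pooled@g, tolerance = 1e-6)
  ## mean filtering tightens the cloud without moving its centroid
  pmMean <- phasorMap(img, "green", filter = "mean")
  expect_lt(var(as.vector(pmMean@g)), var(as.vector(pmRaw@g)))
  expect_equal(mean(pmMean@g), mean(pmRaw@g), tolerance = 0.01)
})

test_that("phasor ROI averaging recovers homogeneous lifetimes", {
  lab <- matrix(1L, 10, 10)
  mono <- constantProbe(tau = 4)
  map <- phaseMap(lab, ld = mono, lo = mono, photonsPerPixel = 1500)
  acq <- acquisitionConfig(binWidth = 0.1, seed = 19)
  img <- simulateFlimImage(map, acq)
  irf <- gaussianIRF(acq)
  pm <- phasorMap(img, "green", filter = "none", reference = irf)
  ctr <- c(mean(pm@g), mean(pm@s))
  tau <- roiAverageLifetime(pm, phasorROI(ctr[1], ctr[2], radius = 0.1))
  expect_equal(tau, 4, tolerance = 0.02)
  ## a single-pixel ROI returns that pixel's phase lifetime
  tiny <- phasorROI(pm@g[1, 1], pm@s[1, 1], radius = 1e-6)
  expect_equal(roiAverageLifetime(pm, tiny),
               (pm@s[1, 1] / pm@g[1, 1]) / pm@omega)
  expect_error(roiAverageLifetime(pm, phasorROI(-5, -5, 0.01)),
               "empty selection")
})
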