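## Shared fixtures: everything is generated in code at test time.

## standard 20 MHz acquisition with a given seed
acq20 <- function(seed = 1L, ...) acquisitionConfig(seed = seed, ...)

## noise-free expected-count histogram for a model through an IRF
noiseFreeHistogram <- function(model, irf, window = c(NA_real_, NA_real_)) {
  m <- pmax(reconvolve(model, irf), 0)
  decayHistogram(m, period = repetitionPeriod(irf), time = timeBins(irf),
                 window = window)
}

## flat-spectrum biexponential with intensity-weighted mean lifetime tauAv,
## components at tauShort/tauLong
biexpProbe <- function(tauAv = 5, tauShort = 1.5, tauLong = 5.8) {
  f <- (tauLong - tauAv) / (tauLong - tauShort)
  a <- c(f, 1 - f) / c(tauShort, tauLong)
  uniformProbe(a / sum(a), c(tauShort, tauLong))
}

## wrapped monoexponential density sampled at bin centers (analytic)
wrappedMonoCurve <- function(tau, period, binWidth) {
  t <- seq(binWidth / 2, period - binWidth / 2, by = binWidth)
  exp(-t / tau) / (1 - exp(-period / tau))
}
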