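## Constructors, accessors, show methods, and small numeric helpers.

## intensity-weighted mean lifetime of raw (amplitude, lifetime) vectors;
## shared by validity methods before the exported operation is defined
.tauAvIntOf <- function(a, tau) sum(a * tau^2) / sum(a * tau)

## wrapped (periodic) exponential density: sum_k exp(-(t + kT)/tau)
## = exp(-t/tau) / (1 - exp(-T/tau)); expm1 keeps tau >> T stable
.wrappedExp <- function(t, tau, period) {
  exp(-t / tau) / (-expm1(-period / tau))
}

## Deterministic substream seeds: two Lehmer rounds over the Mersenne
## prime 2^31 - 1 keep every product below 2^53, so the arithmetic is
## exact in doubles and stable across platforms and evaluation order.
.LEHMER_M <- 2147483647
.lehmerStep <- function(x) (48271 * x) %% .LEHMER_M

#' Derive a reproducible substream seed
#'
#' Hashes a base seed and a stream index (pixel, window, replicate) into an
#' independent seed so that per-stream simulation is reproducible no matter
#' in which order streams are evaluated.
#'
#' @param seed integer base seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substreamSeed <- function(seed, index) {
  x <- (abs(as.numeric(seed)) %% (.LEHMER_M - 1)) + 1
  x <- .lehmerStep(x)
  x <- .lehmerStep((x + as.numeric(index)) %% .LEHMER_M + 1)
  x <- .lehmerStep(x)
  as.integer(x)
}

## evaluate a function under a local RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## ---- constructors ---------------------------------------------------------

#' Construct a decay histogram
#'
#' @param counts photon counts per bin.
#' @param binWidth bin width in ns (bins are left-closed, labelled by
#'   center, time origin at the laser pulse). Give either `binWidth` or
#'   `time`.
#' @param period repetition period in ns.
#' @param time bin centers in ns (alternative to `binWidth`).
#' @param window spectral window edges `c(lower, upper)` in nm, or NA.
#' @param meta list of provenance fields.
#' @return A [DecayHistogram-class].
#' @export
decayHistogram <- function(counts, period, binWidth = NULL, time = NULL,
                           window = c(NA_real_, NA_real_), meta = list()) {
  if (is.null(time)) {
    if (is.null(binWidth))
      stop("either 'time' or 'binWidth' must be given")
    time <- (seq_along(counts) - 0.5) * binWidth
  }
  new("DecayHistogram", time = as.numeric(time), counts = as.numeric(counts),
      period = as.numeric(period), window = as.numeric(window),
      meta = meta)
}

#' Construct a spectral window ladder
#'
#' Half-open windows `[lower, upper)` tiling an emission range; the default
#' tiles 500-700 nm in 20 nm steps.
#'
#' @param from,to range edges in nm.
#' @param by window width in nm.
#' @return data.frame with columns `lower`, `upper`, `center`.
#' @export
spectralWindows <- function(from = 500, to = 700, by = 20) {
  lower <- seq(from, to - by, by = by)
  data.frame(lower = lower, upper = lower + by, center = lower + by / 2)
}

#' Construct an acquisition configuration
#'
#' Defaults mirror a single-photon counting confocal with a pulsed white
#' light laser: 20 MHz repetition rate, 50 ps bins, a Gaussian IRF of
#' 120 ps FWHM centered at 2 ns (leaving a pre-pulse baseline), and a mean
#' detected count rate well below the 0.5 photons-per-pulse operating cap.
#'
#' @param rateMHz repetition rate in MHz (period = 1000/rate ns).
#' @param binWidth histogram bin width in ns.
#' @param irfCenter,irfFwhm IRF center and FWHM in ns.
#' @param mu mean detected photons per pulse.
#' @param pileUp emulate dead-time pile-up (earliest photon per pulse).
#' @param singlePhotonFilter discard pulses with more than one photon.
#' @param efficiency per-window detector efficiency factors in (0, 1].
#' @param seed integer base seed.
#' @return An [AcquisitionConfig-class].
#' @export
acquisitionConfig <- function(rateMHz = 20, binWidth = 0.05,
                              irfCenter = 2, irfFwhm = 0.12, mu = 0.05,
                              pileUp = FALSE, singlePhotonFilter = FALSE,
                              efficiency = 1, seed = 1L) {
  period <- 1000 / rateMHz
  nBins <- round(period / binWidth)
  if (abs(nBins * binWidth - period) > 1e-6 * period)
    stop("binWidth must divide the repetition period ", period, " ns")
  new("AcquisitionConfig", rateMHz = as.numeric(rateMHz),
      binWidth = as.numeric(binWidth), nBins = as.integer(nBins),
      irfCenter = as.numeric(irfCenter), irfFwhm = as.numeric(irfFwhm),
      mu = as.numeric(mu), pileUp = isTRUE(pileUp),
      singlePhotonFilter = isTRUE(singlePhotonFilter),
      efficiency = as.numeric(efficiency), seed = as.integer(seed))
}

#' Construct an instrument response function
#'
#' `instrumentResponse()` wraps raw values (normalizing to unit sum);
#' `gaussianIRF()` builds the bin-integrated Gaussian IRF implied by an
#' acquisition configuration.
#'
#' @param values non-negative IRF values per bin.
#' @param period repetition period in ns.
#' @param binWidth bin width in ns (or give `time`).
#' @param time bin centers in ns.
#' @return An [InstrumentResponse-class].
#' @export
instrumentResponse <- function(values, period, binWidth = NULL, time = NULL) {
  if (is.null(time)) {
    if (is.null(binWidth)) stop("either 'time' or 'binWidth' must be given")
    time <- (seq_along(values) - 0.5) * binWidth
  }
  s <- sum(values)
  if (s <= 0) stop("IRF must contain positive mass")
  new("InstrumentResponse", time = as.numeric(time),
      values = as.numeric(values) / s, period = as.numeric(period))
}

#' @rdname instrumentResponse
#' @param acq an [AcquisitionConfig-class].
#' @export
gaussianIRF <- function(acq) {
  stopifnot(is(acq, "AcquisitionConfig"))
  sigma <- acq@irfFwhm / (2 * sqrt(2 * log(2)))
  edges <- (0:acq@nBins) * acq@binWidth
  v <- diff(stats::pnorm(edges, mean = acq@irfCenter, sd = sigma))
  instrumentResponse(v, period = acq@nBins * acq@binWidth,
                     binWidth = acq@binWidth)
}

#' Construct a decay model
#'
#' @param amplitudes non-negative pre-exponential amplitudes.
#' @param lifetimes positive lifetimes in ns (reordered ascending together
#'   with their amplitudes).
#' @param offset constant background per bin.
#' @param shift IRF time shift in ns.
#' @return A [DecayModel-class].
#' @export
decayModel <- function(amplitudes, lifetimes, offset = 0, shift = 0) {
  o <- order(lifetimes)
  new("DecayModel", amplitudes = as.numeric(amplitudes)[o],
      lifetimes = as.numeric(lifetimes)[o], offset = as.numeric(offset),
      shift = as.numeric(shift))
}

#' Construct a phasor point
#'
#' @param g,s phasor coordinates.
#' @param omega angular frequency in rad/ns.
#' @param harmonic harmonic index.
#' @param photons photon count backing the point.
#' @return A [PhasorPoint-class].
#' @export
phasorPoint <- function(g, s, omega, harmonic = 1L, photons = NA_real_) {
  new("PhasorPoint", g = as.numeric(g), s = as.numeric(s),
      harmonic = as.integer(harmonic), omega = as.numeric(omega),
      photons = as.numeric(photons))
}

## ---- accessors ------------------------------------------------------------

#' @describeIn DecayHistogram-class photon counts per bin.
#' @param object,... object and ignored extras.
#' @export
setMethod("counts", "DecayHistogram", function(object, ...) object@counts)

#' @describeIn DecayHistogram-class bin centers in ns.
#' @export
setMethod("timeBins", "DecayHistogram", function(object, ...) object@time)

#' @describeIn DecayHistogram-class repetition period in ns.
#' @export
setMethod("repetitionPeriod", "DecayHistogram",
          function(object, ...) object@period)

#' @describeIn DecayHistogram-class total photons in the histogram.
#' @export
setMethod("totalPhotons", "DecayHistogram",
          function(object, ...) sum(object@counts))

#' @describeIn DecayHistogram-class spectral window edges in nm.
#' @export
setMethod("spectralWindow", "DecayHistogram",
          function(object, ...) object@window)

#' @export
setMethod("timeBins", "InstrumentResponse", function(object, ...) object@time)

#' @export
setMethod("repetitionPeriod", "InstrumentResponse",
          function(object, ...) object@period)

#' @describeIn DecayModel-class lifetimes in ns, ascending.
#' @param object,... object and ignored extras.
#' @export
setMethod("lifetimes", "DecayModel", function(object, ...) object@lifetimes)

#' @describeIn DecayModel-class pre-exponential amplitudes.
#' @export
setMethod("amplitudes", "DecayModel", function(object, ...) object@amplitudes)

#' @describeIn FitResult-class the fitted model's lifetimes.
#' @param object,... object and ignored extras.
#' @export
setMethod("lifetimes", "FitResult",
          function(object, ...) object@model@lifetimes)

#' @describeIn FitResult-class the fitted model's amplitudes.
#' @export
setMethod("amplitudes", "FitResult",
          function(object, ...) object@model@amplitudes)

#' @describeIn FitResult-class intensity-weighted mean lifetime in ns.
#' @export
setMethod("tauAvInt", "FitResult", function(object, ...) object@tauAvInt)

#' @describeIn FitResult-class reduced chi-square.
#' @export
setMethod("chiSqRed", "FitResult", function(object, ...) object@chiSqRed)

#' @describeIn FLIMImage-class names of the spectral channels.
#' @param object,... object and ignored extras.
#' @export
setMethod("channelNames", "FLIMImage",
          function(object, ...) names(object@channels))

#' @describeIn FLIMImage-class shared bin centers in ns.
#' @export
setMethod("timeBins", "FLIMImage", function(object, ...) object@time)

#' @describeIn FLIMImage-class repetition period in ns.
#' @export
setMethod("repetitionPeriod", "FLIMImage", function(object, ...)
  object@period)

#' @describeIn SpectralLifetimeProfile-class per-window table as a
#'   data.frame.
#' @param x a SpectralLifetimeProfile.
#' @param ... ignored.
#' @export
as.data.frame.SpectralLifetimeProfile <- function(x, ...) x@table

#' @export
setMethod("tauAvInt", "SpectralLifetimeProfile",
          function(object, ...) stats::setNames(object@table$tauAvInt,
                                                object@table$center))

## ---- show methods ---------------------------------------------------------

setMethod("show", "DecayHistogram", function(object) {
  w <- object@window
  wtxt <- if (all(is.na(w))) "unresolved" else
    sprintf("[%g, %g) nm", w[1], w[2])
  cat(sprintf(
    "DecayHistogram: %d bins x %.3g ns | period %.4g ns | window %s\n",
    length(object@counts),
    if (length(object@time) > 1) diff(object@time[1:2]) else NA_real_,
    object@period, wtxt))
  cat(sprintf("  total photons: %.0f\n", sum(object@counts)))
})

setMethod("show", "InstrumentResponse", function(object) {
  pk <- object@time[which.max(object@values)]
  cat(sprintf("InstrumentResponse: %d bins | period %.4g ns | peak %.3g ns\n",
              length(object@values), object@period, pk))
})

setMethod("show", "DecayModel", function(object) {
  cat(sprintf("DecayModel: %d component(s)\n", length(object@lifetimes)))
  cat(sprintf("  tau (ns): %s | a: %s | offset %.3g | shift %.3g ns\n",
              paste(signif(object@lifetimes, 4), collapse = ", "),
              paste(signif(object@amplitudes, 4), collapse = ", "),
              object@offset, object@shift))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: tauAvInt %.4g ns | chi2_red %.3g | %s%s\n",
    object@tauAvInt, object@chiSqRed,
    if (object@converged) "converged" else "NOT converged",
    if (object@outlier) " | flagged outlier" else ""))
  show(object@model)
})

setMethod("show", "ProbeModel", function(object) {
  cat(sprintf("ProbeModel '%s': %d windows | plateau %g nm\n",
              object@name, nrow(object@windows), object@plateau))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig: %g MHz (period %.4g ns) | %d bins x %g ns\n",
    object@rateMHz, 1000 / object@rateMHz, object@nBins, object@binWidth))
  cat(sprintf(
    "  IRF %g ps FWHM @ %g ns | mu %g/pulse | pile-up %s | 1-photon filter %s\n",
    object@irfFwhm * 1000, object@irfCenter, object@mu,
    object@pileUp, object@singlePhotonFilter))
})

setMethod("show", "FLIMImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("FLIMImage: %d x %d pixels | %d bins | channels: %s\n",
              d[1], d[2], d[3],
              paste(names(object@channels), collapse = ", ")))
})

setMethod("show", "PhasorPoint", function(object) {
  cat(sprintf("PhasorPoint: g = %.4f, s = %.4f (harmonic %d, omega %.4g rad/ns)\n",
              object@g, object@s, object@harmonic, object@omega))
})

setMethod("show", "PhasorMap", function(object) {
  cat(sprintf("PhasorMap: %d x %d pixels | channel '%s' | filter %s\n",
              nrow(object@g), ncol(object@g), object@channel, object@filter))
})

setMethod("show", "SpectralLifetimeProfile", function(object) {
  cat(sprintf("SpectralLifetimeProfile '%s': %d windows\n",
              object@condition, nrow(object@table)))
  print(object@table, digits = 4)
})
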