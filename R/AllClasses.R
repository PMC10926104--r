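## Core S4 containers. Validity methods enforce the physical invariants
## (non-negative counts, unit-sum IRF, label alphabets, axis agreement).

#' DecayHistogram: a TCSPC decay histogram
#'
#' Photon counts per arrival-time bin for one spectral window / ROI /
#' pooled selection, together with the laser repetition period. Bins are
#' uniform, left-closed, and labelled by their centers; the time origin is
#' the laser pulse.
#'
#' @slot time numeric, bin centers in ns (uniform spacing).
#' @slot counts numeric, non-negative photon counts per bin.
#' @slot period numeric(1), repetition period in ns; all bins lie below it.
#' @slot window numeric(2), spectral window edges in nm (`c(lower, upper)`,
#'   half-open), or `c(NA, NA)` when not spectrally resolved.
#' @slot meta list of provenance fields (seed, label, ROI id, ...).
#' @exportClass DecayHistogram
setClass("DecayHistogram",
  representation(time = "numeric", counts = "numeric", period = "numeric",
                 window = "numeric", meta = "list"),
  prototype(window = c(NA_real_, NA_real_), meta = list()))

setValidity("DecayHistogram", function(object) {
  msg <- character()
  if (length(object@time) != length(object@counts))
    msg <- c(msg, "time and counts must have equal length")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@period) != 1L || !is.finite(object@period) ||
      object@period <= 0)
    msg <- c(msg, "period must be a single positive number")
  if (length(object@time) > 1L) {
    dt <- diff(object@time)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      msg <- c(msg, "time bins must be uniform")
  }
  if (length(object@time) && max(object@time) >= object@period)
    msg <- c(msg, "all bin centers must lie below the repetition period")
  if (length(object@window) != 2L)
    msg <- c(msg, "window must be length 2 (lower, upper)")
  if (length(msg)) msg else TRUE
})

#' InstrumentResponse: a normalized IRF histogram
#'
#' The temporal instrument response sampled on the same bin axis as the
#' decay histograms it will be reconvolved with; values are non-negative
#' and normalized to unit sum.
#'
#' @slot time numeric, bin centers in ns.
#' @slot values numeric, non-negative, summing to 1.
#' @slot period numeric(1), repetition period in ns.
#' @exportClass InstrumentResponse
setClass("InstrumentResponse",
  representation(time = "numeric", values = "numeric", period = "numeric"))

setValidity("InstrumentResponse", function(object) {
  msg <- character()
  if (length(object@time) != length(object@values))
    msg <- c(msg, "time and values must have equal length")
  if (any(object@values < 0)) msg <- c(msg, "IRF values must be non-negative")
  if (abs(sum(object@values) - 1) > 1e-8)
    msg <- c(msg, "IRF values must sum to 1")
  if (length(msg)) msg else TRUE
})

#' DecayModel: an n-exponential decay model
#'
#' Pre-exponential amplitudes and lifetimes of a 1-3 component decay, plus
#' a constant background offset and an IRF time shift. Lifetimes are kept
#' in ascending order for identifiability.
#'
#' @slot amplitudes numeric, non-negative pre-exponential factors.
#' @slot lifetimes numeric, strictly positive lifetimes in ns, ascending.
#' @slot offset numeric(1), constant background counts per bin, >= 0.
#' @slot shift numeric(1), IRF time shift in ns.
#' @exportClass DecayModel
setClass("DecayModel",
  representation(amplitudes = "numeric", lifetimes = "numeric",
                 offset = "numeric", shift = "numeric"),
  prototype(offset = 0, shift = 0))

setValidity("DecayModel", function(object) {
  msg <- character()
  n <- length(object@lifetimes)
  if (n < 1L || n > 3L) msg <- c(msg, "1 to 3 components are supported")
  if (length(object@amplitudes) != n)
    msg <- c(msg, "amplitudes and lifetimes must have equal length")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@lifetimes <= 0)) msg <- c(msg, "lifetimes must be > 0")
  if (is.unsorted(object@lifetimes))
    msg <- c(msg, "lifetimes must be in ascending order")
  if (object@offset < 0) msg <- c(msg, "offset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FitResult: the outcome of a reconvolution fit
#'
#' @slot model the fitted [DecayModel-class].
#' @slot tauAvInt numeric(1), intensity-weighted mean lifetime in ns.
#' @slot chiSqRed numeric(1), reduced chi-square of the weighted fit.
#' @slot residuals numeric, weighted residuals (NA outside the fit range).
#' @slot fitRange numeric(2), fitted time range in ns.
#' @slot niter integer(1), optimizer iterations.
#' @slot converged logical(1).
#' @slot outlier logical(1), TRUE when the result fails the plausibility
#'   screen (lifetime outside 0.1-20 ns or chi-square red > 5).
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "DecayModel", tauAvInt = "numeric",
                 chiSqRed = "numeric", residuals = "numeric",
                 fitRange = "numeric", niter = "integer",
                 converged = "logical", outlier = "logical"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (length(object@tauAvInt) != 1L) msg <- c(msg, "tauAvInt must be scalar")
  if (length(object@chiSqRed) == 1L && is.finite(object@chiSqRed) &&
      object@chiSqRed <= 0)
    msg <- c(msg, "chiSqRed must be positive")
  if (length(msg)) msg else TRUE
})

#' ProbeModel: ground-truth photophysics of a simulated probe
#'
#' Per spectral window: a multi-exponential decay (amplitude fractions
#' summing to 1, lifetimes in ns) and a relative emission brightness
#' weight. The intensity-weighted mean lifetime is non-decreasing with the
#' window center up to `plateau` nm and flat beyond, emulating solvent
#' relaxation.
#'
#' @slot name character(1) probe identifier.
#' @slot windows data.frame with columns `lower`, `upper`, `center` (nm).
#' @slot components list, one element per window, each a list with
#'   `amplitudes` (fractions summing to 1) and `lifetimes` (ns).
#' @slot weights numeric, relative emission brightness per window.
#' @slot plateau numeric(1), wavelength (nm) beyond which the mean
#'   lifetime is constant.
#' @exportClass ProbeModel
setClass("ProbeModel",
  representation(name = "character", windows = "data.frame",
                 components = "list", weights = "numeric",
                 plateau = "numeric"))

setValidity("ProbeModel", function(object) {
  msg <- character()
  w <- object@windows
  nw <- nrow(w)
  if (!all(c("lower", "upper", "center") %in% names(w)))
    msg <- c(msg, "windows needs columns lower, upper, center")
  else {
    if (any(w$upper <= w$lower)) msg <- c(msg, "window upper must exceed lower")
    if (is.unsorted(w$center, strictly = TRUE))
      msg <- c(msg, "windows must be strictly ordered by center")
  }
  if (length(object@components) != nw)
    msg <- c(msg, "one component set per window required")
  if (length(object@weights) != nw)
    msg <- c(msg, "one brightness weight per window required")
  if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
  for (cmp in object@components) {
    if (abs(sum(cmp$amplitudes) - 1) > 1e-8) {
      msg <- c(msg, "amplitude fractions must sum to 1 in every window")
      break
    }
    if (any(cmp$lifetimes <= 0)) {
      msg <- c(msg, "lifetimes must be strictly positive")
      break
    }
  }
  if (!length(msg) && nw > 1L) {
    tm <- vapply(object@components, function(cmp)
      .tauAvIntOf(cmp$amplitudes, cmp$lifetimes), numeric(1))
    pre <- w$center <= object@plateau + 1e-9
    if (sum(pre) > 1L && any(diff(tm[pre]) < -1e-6))
      msg <- c(msg, "mean lifetime must be non-decreasing up to the plateau")
    post <- w$center > object@plateau
    if (sum(post) > 0L) {
      ref <- tm[which(!post)[sum(!post)]]
      if (length(ref) && any(abs(tm[post] - ref) > 0.05 * ref))
        msg <- c(msg, "mean lifetime must be flat beyond the plateau")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AcquisitionConfig: TCSPC acquisition settings
#'
#' @slot rateMHz numeric(1), laser repetition rate in MHz (20/40/80 usual).
#' @slot binWidth numeric(1), histogram bin width in ns.
#' @slot nBins integer(1); `nBins * binWidth` equals the repetition period
#'   `1000 / rateMHz` ns.
#' @slot irfCenter numeric(1), IRF center in ns (pre-pulse baseline before
#'   it).
#' @slot irfFwhm numeric(1), IRF full width at half maximum in ns.
#' @slot mu numeric(1), mean detected photons per laser pulse.
#' @slot pileUp logical(1), emulate detector dead time (earliest photon per
#'   pulse only).
#' @slot singlePhotonFilter logical(1), discard pulses carrying more than
#'   one photon before detection.
#' @slot efficiency numeric, per-window detector efficiency factors in
#'   (0, 1] (recycled over windows).
#' @slot seed integer(1), base random seed.
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(rateMHz = "numeric", binWidth = "numeric", nBins = "integer",
                 irfCenter = "numeric", irfFwhm = "numeric", mu = "numeric",
                 pileUp = "logical", singlePhotonFilter = "logical",
                 efficiency = "numeric", seed = "integer"))

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (object@rateMHz <= 0) msg <- c(msg, "repetition rate must be positive")
  if (object@mu <= 0) msg <- c(msg, "mean photons per pulse must be positive")
  if (any(object@efficiency <= 0) || any(object@efficiency > 1))
    msg <- c(msg, "efficiency factors must lie in (0, 1]")
  period <- 1000 / object@rateMHz
  if (abs(object@nBins * object@binWidth - period) > 1e-6 * period)
    msg <- c(msg, "nBins * binWidth must equal the repetition period")
  if (object@irfFwhm <= 0) msg <- c(msg, "IRF FWHM must be positive")
  if (length(msg)) msg else TRUE
})

#' PhaseMap: ground-truth phase labels for a simulated two-phase image
#'
#' @slot labels integer matrix; 0 = background, 1 = Ld, 2 = Lo.
#' @slot models list with elements `ld` and `lo`, each a
#'   [ProbeModel-class].
#' @slot photonsPerPixel numeric(1), expected photons per labelled pixel.
#' @slot darkRate numeric(1), expected dark counts per background pixel.
#' @exportClass PhaseMap
setClass("PhaseMap",
  representation(labels = "matrix", models = "list",
                 photonsPerPixel = "numeric", darkRate = "numeric"),
  prototype(darkRate = 0))

setValidity("PhaseMap", function(object) {
  msg <- character()
  if (!all(object@labels %in% c(0L, 1L, 2L)))
    msg <- c(msg, "labels must be 0 (background), 1 (Ld) or 2 (Lo)")
  if (!all(c("ld", "lo") %in% names(object@models)))
    msg <- c(msg, "models must contain elements 'ld' and 'lo'")
  if (object@photonsPerPixel <= 0)
    msg <- c(msg, "photonsPerPixel must be positive")
  if (object@darkRate < 0) msg <- c(msg, "darkRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FLIMImage: per-pixel decay histograms, one stack per spectral channel
#'
#' @slot channels named list of 3-D arrays `[rows, cols, bins]` of counts.
#' @slot time numeric, shared bin centers in ns.
#' @slot period numeric(1), repetition period in ns.
#' @slot channelWindows named list of numeric(2) spectral edges per channel.
#' @slot meta list of acquisition metadata (seed, pixel size, ...).
#' @exportClass FLIMImage
setClass("FLIMImage",
  representation(channels = "list", time = "numeric", period = "numeric",
                 channelWindows = "list", meta = "list"),
  prototype(meta = list(), channelWindows = list()))

setValidity("FLIMImage", function(object) {
  msg <- character()
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  nb <- length(object@time)
  dims <- lapply(object@channels, dim)
  for (d in dims) {
    if (length(d) != 3L) { msg <- c(msg, "channels must be 3-D arrays"); break }
    if (d[3] != nb) { msg <- c(msg, "bin axis must match time"); break }
  }
  if (length(dims) > 1L &&
      !all(vapply(dims, function(d) identical(d[1:2], dims[[1]][1:2]),
                  logical(1))))
    msg <- c(msg, "all channels must share pixel dimensions")
  if (any(vapply(object@channels, function(a) any(a < 0), logical(1))))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PhasorPoint: first-harmonic (or higher) Fourier coordinates of a decay
#'
#' @slot g numeric(1), cosine coordinate.
#' @slot s numeric(1), sine coordinate.
#' @slot harmonic integer(1), harmonic index (1 = fundamental).
#' @slot omega numeric(1), angular frequency `harmonic * 2 * pi / period`
#'   in rad/ns.
#' @slot photons numeric(1), photon count backing the point.
#' @exportClass PhasorPoint
setClass("PhasorPoint",
  representation(g = "numeric", s = "numeric", harmonic = "integer",
                 omega = "numeric", photons = "numeric"))

#' PhasorMap: per-pixel phasor coordinates of a FLIM channel
#'
#' @slot g,s numeric matrices of phasor coordinates (NA for empty pixels).
#' @slot photons numeric matrix of per-pixel photon counts.
#' @slot harmonic integer(1), omega numeric(1): as in
#'   [PhasorPoint-class].
#' @slot channel character(1), source channel name.
#' @slot filter character(1), spatial filter that was applied.
#' @exportClass PhasorMap
setClass("PhasorMap",
  representation(g = "matrix", s = "matrix", photons = "matrix",
                 harmonic = "integer", omega = "numeric",
                 channel = "character", filter = "character"))

setValidity("PhasorMap", function(object) {
  if (!identical(dim(object@g), dim(object@s)) ||
      !identical(dim(object@g), dim(object@photons)))
    "g, s and photons must share dimensions" else TRUE
})

#' SpectralLifetimeProfile: per-window lifetimes and intensities
#'
#' @slot table data.frame with one row per spectral window: `center`,
#'   `lower`, `upper` (nm), `tauAvInt` (ns), `intensity` (summed photons),
#'   `chiSqRed`, `nPhotons`.
#' @slot condition character(1) label for the measured condition.
#' @exportClass SpectralLifetimeProfile
setClass("SpectralLifetimeProfile",
  representation(table = "data.frame", condition = "character"))

setValidity("SpectralLifetimeProfile", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("center", "lower", "upper", "tauAvInt", "intensity")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(tb) > 1L && is.unsorted(tb$center, strictly = TRUE))
      msg <- c(msg, "windows must be strictly ordered by center")
    if (any(tb$intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
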