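## Synthetic probe photophysics: solvatochromic membrane dyes whose
## intensity-weighted mean lifetime rises with emission wavelength to a
## probe-specific plateau (a phenomenological stand-in for solvent
## relaxation), plus liquid-ordered / liquid-disordered (Lo/Ld) variants
## and a wavelength-independent control dye.

## saturating mean-lifetime curve; clipped flat above the plateau
.relaxCurve <- function(lambda, tauMin, tauMax, lambdaScale, plateau) {
  lam <- pmin(lambda, plateau)
  tauMax - (tauMax - tauMin) * exp(-(lam - 500) / lambdaScale)
}

## biexponential with a prescribed intensity-weighted mean: components at
## fixed spread factors around tauMean, intensity fractions solved so the
## intensity-weighted mean equals tauMean exactly
.componentsForMean <- function(tauMean, n = 2L, spread = c(0.55, 1.35)) {
  if (n == 1L)
    return(list(amplitudes = 1, lifetimes = tauMean))
  tau <- spread * tauMean
  f2 <- (tauMean - tau[1]) / (tau[2] - tau[1])
  f <- c(1 - f2, f2)                       # intensity fractions
  a <- f / tau                             # pre-exponential amplitudes
  list(amplitudes = a / sum(a), lifetimes = tau)
}

#' Build a solvent-relaxation probe model
#'
#' Constructs a [ProbeModel-class] whose per-window intensity-weighted
#' mean lifetime follows the saturating curve
#' `tauMax - (tauMax - tauMin) * exp(-(lambda - 500)/lambdaScale)`,
#' clipped flat above `plateau` nm. `tauMax` is solved so that the mean
#' lifetime at `anchorLambda` equals `tauAnchor` exactly, which makes
#' ground-truth lifetime contrasts between two probes at the anchor
#' wavelength exact by construction. Each window carries a biexponential
#' (or monoexponential) decay with that mean, and an emission-spectrum
#' brightness weight that is Gaussian in the window center.
#'
#' @param name probe identifier.
#' @param tauMin mean lifetime at 500 nm, ns.
#' @param tauAnchor mean lifetime at `anchorLambda`, ns.
#' @param anchorLambda anchor wavelength, nm.
#' @param lambdaScale e-folding scale of the rise, nm.
#' @param plateau wavelength beyond which the mean lifetime is flat, nm.
#' @param emissionPeak,emissionSigma Gaussian emission-spectrum peak and
#'   width, nm.
#' @param nComponents decay components per window (1 or 2).
#' @param windows window ladder (see [spectralWindows()]).
#' @return A [ProbeModel-class].
#' @export
relaxationProbe <- function(name, tauMin, tauAnchor, anchorLambda = 570,
                            lambdaScale = 60, plateau = 600,
                            emissionPeak = 580, emissionSigma = 50,
                            nComponents = 2L,
                            windows = spectralWindows()) {
  if (tauAnchor <= tauMin)
    stop("tauAnchor must exceed tauMin")
  E <- exp(-(min(anchorLambda, plateau) - 500) / lambdaScale)
  tauMax <- (tauAnchor - tauMin * E) / (1 - E)
  tm <- .relaxCurve(windows$center, tauMin, tauMax, lambdaScale, plateau)
  comps <- lapply(tm, .componentsForMean, n = nComponents)
  w <- exp(-(windows$center - emissionPeak)^2 / (2 * emissionSigma^2))
  new("ProbeModel", name = name, windows = windows, components = comps,
      weights = w, plateau = plateau)
}

#' Build a wavelength-independent control probe
#'
#' Monoexponential with the same lifetime in every window (the behaviour
#' of a simple water-soluble control dye), used to verify that flat
#' spectral lifetime profiles are recovered as flat.
#'
#' @param name probe identifier.
#' @param tau lifetime in ns.
#' @param emissionPeak,emissionSigma emission-spectrum shape, nm.
#' @param windows window ladder.
#' @return A [ProbeModel-class].
#' @export
constantProbe <- function(name = "control", tau = 4.1, emissionPeak = 520,
                          emissionSigma = 40,
                          windows = spectralWindows()) {
  comps <- rep(list(list(amplitudes = 1, lifetimes = tau)),
               nrow(windows))
  w <- exp(-(windows$center - emissionPeak)^2 / (2 * emissionSigma^2))
  new("ProbeModel", name = name, windows = windows, components = comps,
      weights = w, plateau = windows$center[1])
}

#' Build a wavelength-independent multi-exponential probe
#'
#' The same decay components in every window: the workhorse for artifact
#' studies (wraparound, pile-up) where spectral structure is irrelevant
#' but a multi-exponential decay is essential -- a wrapped
#' monoexponential keeps a purely exponential shape, so repetition-rate
#' wraparound only distorts the intensity weighting of decays with two or
#' more components.
#'
#' @param amplitudes amplitude fractions (normalized to sum 1).
#' @param lifetimes component lifetimes in ns.
#' @param name probe identifier.
#' @param emissionPeak,emissionSigma emission-spectrum shape, nm.
#' @param windows window ladder.
#' @return A [ProbeModel-class].
#' @export
uniformProbe <- function(amplitudes, lifetimes, name = "uniform",
                         emissionPeak = 580, emissionSigma = 60,
                         windows = spectralWindows()) {
  o <- order(lifetimes)
  cmp <- list(amplitudes = amplitudes[o] / sum(amplitudes),
              lifetimes = lifetimes[o])
  w <- exp(-(windows$center - emissionPeak)^2 / (2 * emissionSigma^2))
  new("ProbeModel", name = name, windows = windows,
      components = rep(list(cmp), nrow(windows)), weights = w,
      plateau = windows$center[1])
}

#' Bundled probe presets
#'
#' Ground-truth simulator presets, not measurements of any real dye:
#' \describe{
#'   \item{flipperLd / flipperLo}{biexponential, lifetime plateau at
#'     600 nm, small spectral shift between phases; mean lifetimes at the
#'     570 nm anchor are 4.0 (Ld) and 5.6 ns (Lo), a 1.6 ns contrast.}
#'   \item{nr12Ld / nr12Lo}{biexponential, plateau at 650 nm, large
#'     solvatochromic shift; the Lo-Ld lifetime gap is largest below
#'     600 nm, so pooled green-channel contrast exceeds red-channel
#'     contrast.}
#'   \item{control}{wavelength-independent 4.1 ns monoexponential.}
#' }
#'
#' @param name one of `"flipperLd"`, `"flipperLo"`, `"nr12Ld"`,
#'   `"nr12Lo"`, `"control"`.
#' @return A [ProbeModel-class].
#' @export
probePreset <- function(name = c("flipperLd", "flipperLo", "nr12Ld",
                                 "nr12Lo", "control")) {
  name <- match.arg(name)
  switch(name,
    flipperLd = relaxationProbe("flipperLd", tauMin = 3.2, tauAnchor = 4.0,
                                lambdaScale = 60, plateau = 600,
                                emissionPeak = 585, emissionSigma = 45),
    flipperLo = relaxationProbe("flipperLo", tauMin = 4.6, tauAnchor = 5.6,
                                lambdaScale = 60, plateau = 600,
                                emissionPeak = 575, emissionSigma = 45),
    nr12Ld = relaxationProbe("nr12Ld", tauMin = 1.0, tauAnchor = 3.0,
                             lambdaScale = 80, plateau = 650,
                             emissionPeak = 620, emissionSigma = 50),
    nr12Lo = relaxationProbe("nr12Lo", tauMin = 4.2, tauAnchor = 5.2,
                             lambdaScale = 80, plateau = 650,
                             emissionPeak = 560, emissionSigma = 50),
    control = constantProbe())
}

## resolve a window argument (center wavelength, c(lower, upper), or row
## index) to a window row index; error if the probe does not define it
.windowIndex <- function(probe, window) {
  w <- probe@windows
  if (length(window) == 2L && !anyNA(window)) {
    i <- which(abs(w$lower - window[1]) < 1e-9 &
               abs(w$upper - window[2]) < 1e-9)
  } else if (length(window) == 1L) {
    if (window >= 1 && window <= nrow(w) && window == round(window) &&
        window < min(w$lower)) {
      i <- as.integer(window)
    } else {
      i <- which(w$lower <= window & window < w$upper)
    }
  } else stop("invalid window specification")
  if (length(i) != 1L)
    stop("window not defined for probe '", probe@name, "': ",
         paste(window, collapse = "-"), " nm")
  i
}

#' Ground-truth decay components of a probe window
#'
#' @param probe a [ProbeModel-class].
#' @param window window center (nm), `c(lower, upper)` edges, or index.
#' @return list with `amplitudes` (fractions summing to 1) and
#'   `lifetimes` (ns).
#' @export
probeComponents <- function(probe, window) {
  probe@components[[.windowIndex(probe, window)]]
}

#' Ground-truth intensity-weighted mean lifetime per window
#'
#' @param probe a [ProbeModel-class].
#' @param window optional single window (as in [probeComponents()]); when
#'   missing, all windows are returned named by center.
#' @return numeric, ns.
#' @export
probeMeanLifetime <- function(probe, window) {
  if (!missing(window)) {
    cmp <- probeComponents(probe, window)
    return(.tauAvIntOf(cmp$amplitudes, cmp$lifetimes))
  }
  stats::setNames(
    vapply(probe@components,
           function(cmp) .tauAvIntOf(cmp$amplitudes, cmp$lifetimes),
           numeric(1)),
    probe@windows$center)
}

#' Pool a probe's windows into one broadband channel
#'
#' Combines the decay components of all ladder windows falling inside
#' `span` into a single mixture, weighting each window's photon
#' contribution by its emission-spectrum brightness. The pooled
#' intensity-weighted mean lifetime is the brightness-weighted mean of the
#' member windows' means. Used to emulate broad 100 nm detection channels
#' (e.g. green 500-600 nm vs red 600-700 nm).
#'
#' @param probe a [ProbeModel-class].
#' @param span `c(lower, upper)` nm; member windows must tile it exactly.
#' @return A [ProbeModel-class] with a single window covering `span`.
#' @export
probeBroadband <- function(probe, span) {
  w <- probe@windows
  sel <- which(w$lower >= span[1] - 1e-9 & w$upper <= span[2] + 1e-9)
  if (!length(sel))
    stop("no probe windows inside [", span[1], ", ", span[2], ") nm")
  amp <- numeric(0); tau <- numeric(0)
  for (i in sel) {
    cmp <- probe@components[[i]]
    ## scale so each window's photon share is proportional to its weight
    sc <- probe@weights[i] / sum(cmp$amplitudes * cmp$lifetimes)
    amp <- c(amp, sc * cmp$amplitudes)
    tau <- c(tau, cmp$lifetimes)
  }
  o <- order(tau)
  amp <- amp[o] / sum(amp)
  tau <- tau[o]
  win <- data.frame(lower = span[1], upper = span[2],
                    center = mean(span))
  new("ProbeModel", name = paste0(probe@name, "[", span[1], "-", span[2], "]"),
      windows = win, components = list(list(amplitudes = amp,
                                            lifetimes = tau)),
      weights = sum(probe@weights[sel]), plateau = probe@plateau)
}

#' Periodic (wraparound-summed) ground-truth decay density
#'
#' Evaluates the wrapped multi-exponential density of a probe window at
#' times within one repetition period: each component contributes
#' `a * exp(-t/tau) / (1 - exp(-period/tau))`, the closed form of the
#' geometric wraparound series over all preceding pulses. At repetition
#' periods much longer than the lifetime this reduces to the plain
#' exponential; at short periods the incomplete decay from earlier pulses
#' raises the apparent baseline.
#'
#' @param probe a [ProbeModel-class].
#' @param window window selector (see [probeComponents()]).
#' @param t times in ns, all in `[0, period)`.
#' @param period repetition period in ns.
#' @return Intensity density (arbitrary units) at `t`.
#' @export
groundTruthDecay <- function(probe, window, t, period) {
  if (any(t < 0 | t >= period))
    stop("times must lie in [0, period)")
  cmp <- probeComponents(probe, window)
  v <- numeric(length(t))
  for (i in seq_along(cmp$lifetimes))
    v <- v + cmp$amplitudes[i] * .wrappedExp(t, cmp$lifetimes[i], period)
  v
}
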