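## TCSPC simulation: photon arrival times are drawn as (exponential decay
## time + Gaussian IRF jitter) modulo the repetition period, which
## produces wraparound naturally; detector dead time (pile-up) and the
## single-photon filter act per pulse.

## sample n photon arrival times (ns, within one period) for a component
## mixture; a photon's component is chosen with probability proportional
## to its steady-state intensity a_i * tau_i
.samplePhotonTimes <- function(cmp, n, acq) {
  if (n == 0L) return(numeric(0))
  I <- cmp$amplitudes * cmp$lifetimes
  pick <- sample.int(length(I), n, replace = TRUE, prob = I)
  sigma <- acq@irfFwhm / (2 * sqrt(2 * log(2)))
  t <- stats::rexp(n, rate = 1) * cmp$lifetimes[pick] +
    stats::rnorm(n, mean = acq@irfCenter, sd = sigma)
  t %% (acq@nBins * acq@binWidth)
}

## bin arrival times into left-closed uniform bins
.binPhotons <- function(t, acq) {
  b <- pmin(floor(t / acq@binWidth) + 1L, acq@nBins)
  tabulate(b, nbins = acq@nBins)
}

## largest-remainder integer allocation of a total over weights
.allocate <- function(total, w) {
  q <- total * w / sum(w)
  base <- floor(q)
  short <- round(total - sum(base))
  if (short > 0) {
    add <- order(q - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

.effFor <- function(acq, windowIdx) {
  acq@efficiency[(windowIdx - 1L) %% length(acq@efficiency) + 1L]
}

#' Simulate a TCSPC decay histogram
#'
#' Draws photons from a probe window's ground-truth decay observed
#' through the Gaussian IRF of `acq`, with wraparound across pulses
#' (arrival times are taken modulo the repetition period).
#'
#' Two modes:
#' \itemize{
#'   \item `nPulses`: per-pulse simulation. Each pulse emits
#'     `Poisson(mu * efficiency)` photons. If the single-photon filter is
#'     enabled, pulses carrying more than one photon are discarded before
#'     detection (the filter inspects the pulse, so it sees the true
#'     photon multiplicity). If pile-up is enabled, only the earliest
#'     photon of each surviving pulse is detected (dead time spanning the
#'     rest of the period), over-representing early photons and biasing
#'     lifetimes downward.
#'   \item `nPhotons`: draws exactly that many photons directly from the
#'     decay; requires pile-up and the filter to be off. Used for
#'     photon-budget studies where per-pulse structure is irrelevant.
#' }
#'
#' @param probe a [ProbeModel-class].
#' @param window window selector (see [probeComponents()]).
#' @param acq an [AcquisitionConfig-class].
#' @param nPulses number of laser pulses (per-pulse mode).
#' @param nPhotons exact photon budget (direct mode).
#' @param seed random seed (default from `acq`).
#' @return A [DecayHistogram-class]; `meta` records the seed, probe name,
#'   ground-truth mean lifetime and pulse/photon budget.
#' @export
simulateDecay <- function(probe, window, acq, nPulses = NULL,
                          nPhotons = NULL, seed = acq@seed) {
  wi <- .windowIndex(probe, window)
  cmp <- probe@components[[wi]]
  win <- unlist(probe@windows[wi, c("lower", "upper")])
  if (is.null(nPulses) == is.null(nPhotons))
    stop("give exactly one of nPulses or nPhotons")
  cts <- .withSeed(seed, {
    if (!is.null(nPulses)) {
      stopifnot(nPulses >= 1)
      k <- stats::rpois(nPulses, acq@mu * .effFor(acq, wi))
      if (acq@singlePhotonFilter) k[k > 1L] <- 0L
      t <- .samplePhotonTimes(cmp, sum(k), acq)
      if (acq@pileUp && any(k > 1L)) {
        pulse <- rep.int(which(k > 0L), k[k > 0L])
        o <- order(pulse, t)
        t <- t[o][!duplicated(pulse[o])]
      }
      t
    } else {
      if (acq@pileUp || acq@singlePhotonFilter)
        stop("nPhotons mode requires pile-up and the single-photon filter off")
      .samplePhotonTimes(cmp, as.integer(nPhotons), acq)
    }
  })
  decayHistogram(.binPhotons(cts, acq), period = acq@nBins * acq@binWidth,
                 binWidth = acq@binWidth, window = win,
                 meta = list(seed = seed, probe = probe@name,
                             truthTau = .tauAvIntOf(cmp$amplitudes,
                                                    cmp$lifetimes),
                             nPulses = nPulses, nPhotons = nPhotons))
}

#' Simulate a spectrally resolved decay series
#'
#' One decay histogram per probe window. The total photon budget is
#' distributed over windows proportionally to the probe's emission-
#' spectrum weights times the per-window detector efficiency, using
#' largest-remainder rounding so the per-window totals sum exactly to the
#' requested budget. Each window draws from its own reproducible
#' substream (see [substreamSeed()]).
#'
#' @param probe a [ProbeModel-class].
#' @param acq an [AcquisitionConfig-class].
#' @param photons total photon budget across all windows.
#' @param seed base seed (default from `acq`).
#' @return Named list of [DecayHistogram-class], names = window centers.
#' @export
simulateSpectralSeries <- function(probe, acq, photons, seed = acq@seed) {
  nw <- nrow(probe@windows)
  eff <- vapply(seq_len(nw), function(i) .effFor(acq, i), numeric(1))
  alloc <- .allocate(photons, probe@weights * eff)
  out <- vector("list", nw)
  for (i in seq_len(nw)) {
    out[[i]] <- simulateDecay(probe, i, acq, nPhotons = alloc[i],
                              seed = substreamSeed(seed, i))
  }
  names(out) <- probe@windows$center
  out
}

#' Construct a phase map
#'
#' @param labels integer matrix of phase labels (0 background, 1 Ld,
#'   2 Lo).
#' @param ld,lo [ProbeModel-class] ground truth for each phase.
#' @param photonsPerPixel expected photons per labelled pixel.
#' @param darkRate expected dark counts per background pixel.
#' @return A [PhaseMap-class].
#' @export
phaseMap <- function(labels, ld, lo, photonsPerPixel = 1000,
                     darkRate = 0) {
  storage.mode(labels) <- "integer"
  new("PhaseMap", labels = labels, models = list(ld = ld, lo = lo),
      photonsPerPixel = photonsPerPixel, darkRate = darkRate)
}

#' Build a two-phase vesicle-like label image
#'
#' A filled disc on a dark background, split into a Ld half (label 1) and
#' a Lo half (label 2) -- a minimal stand-in for an equatorial image of a
#' phase-separated giant vesicle.
#'
#' @param n image side in pixels.
#' @param ld,lo [ProbeModel-class] per phase.
#' @param photonsPerPixel expected photons per labelled pixel.
#' @param radius disc radius as a fraction of the image side.
#' @param darkRate expected background dark counts per pixel.
#' @return A [PhaseMap-class].
#' @export
twoPhaseDisc <- function(n = 32, ld = probePreset("nr12Ld"),
                         lo = probePreset("nr12Lo"),
                         photonsPerPixel = 1000, radius = 0.45,
                         darkRate = 0) {
  ctr <- (n + 1) / 2
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  inside <- (xy$row - ctr)^2 + (xy$col - ctr)^2 <= (radius * n)^2
  lab <- matrix(0L, n, n)
  lab[cbind(xy$row, xy$col)[inside, , drop = FALSE]] <-
    ifelse(xy$col[inside] <= ctr, 1L, 2L)
  phaseMap(lab, ld, lo, photonsPerPixel, darkRate)
}

#' Simulate a two-channel FLIM image from a phase map
#'
#' Each labelled pixel emits `Poisson(photonsPerPixel)` photons, split
#' between the spectral channels according to the emission-spectrum
#' weight its phase's probe carries inside each channel span; arrival
#' times are drawn from the phase's pooled broadband decay (see
#' [probeBroadband()]). Background pixels receive only dark counts
#' (uniform arrival times; none by default). Every pixel uses a
#' substream derived from the seed and the pixel index, so the result is
#' bit-identical for a given seed regardless of evaluation order.
#'
#' @param map a [PhaseMap-class].
#' @param acq an [AcquisitionConfig-class].
#' @param windows named list of channel spans in nm.
#' @param seed base seed (default from `acq`).
#' @return A [FLIMImage-class]; `meta$labels` keeps the ground-truth
#'   label image.
#' @export
simulateFlimImage <- function(map, acq,
                              windows = list(green = c(500, 600),
                                             red = c(600, 700)),
                              seed = acq@seed) {
  lab <- map@labels
  nr <- nrow(lab); nc <- ncol(lab); nb <- acq@nBins
  ## pooled broadband decay + channel weight per phase and channel
  broad <- lapply(map@models, function(m)
    lapply(windows, function(sp) probeBroadband(m, sp)))
  chw <- lapply(broad, function(bl)
    vapply(bl, function(b) b@weights, numeric(1)))
  arrs <- lapply(windows, function(.) array(0, dim = c(nr, nc, nb)))
  period <- nb * acq@binWidth
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    pix <- (j - 1L) * nr + i
    l <- lab[i, j]
    res <- .withSeed(substreamSeed(seed, pix), {
      if (l == 0L) {
        n0 <- if (map@darkRate > 0) stats::rpois(1, map@darkRate) else 0L
        lapply(windows, function(.)
          if (n0 > 0) stats::runif(n0, 0, period) else numeric(0))
      } else {
        key <- if (l == 1L) "ld" else "lo"
        n <- stats::rpois(1, map@photonsPerPixel)
        split <- if (n > 0)
          as.vector(stats::rmultinom(1, n, chw[[key]])) else
          integer(length(windows))
        lapply(seq_along(windows), function(k)
          .samplePhotonTimes(broad[[key]][[k]]@components[[1]],
                             split[k], acq))
      }
    })
    for (k in seq_along(windows))
      arrs[[k]][i, j, ] <- .binPhotons(res[[k]], acq)
  }
  new("FLIMImage", channels = arrs,
      time = (seq_len(nb) - 0.5) * acq@binWidth, period = period,
      channelWindows = windows,
      meta = list(seed = seed, labels = lab,
                  photonsPerPixel = map@photonsPerPixel))
}
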