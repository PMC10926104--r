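## Fit-free phasor analysis: decays are represented by the normalized
## Fourier coordinates g = <cos(n w0 t)>, s = <sin(n w0 t)> at harmonic n
## of the repetition frequency. Monoexponential decays lie on the
## universal semicircle (center (0.5, 0), radius 0.5); mixtures lie on
## chords strictly inside.

.phasorOf <- function(time, weights, period, harmonic) {
  tot <- sum(weights)
  if (tot <= 0) stop("undefined phasor: zero total counts")
  omega <- harmonic * 2 * pi / period
  phasorPoint(sum(weights * cos(omega * time)) / tot,
              sum(weights * sin(omega * time)) / tot,
              omega = omega, harmonic = harmonic, photons = tot)
}

#' @describeIn phasorTransform phasor of a decay histogram, evaluated as
#'   count-weighted cosine/sine sums at the bin centers.
#' @param object a decay histogram or instrument response.
#' @param harmonic harmonic index (1 = fundamental).
#' @param ... ignored.
#' @export
setMethod("phasorTransform", "DecayHistogram",
  function(object, harmonic = 1L, ...)
    .phasorOf(object@time, object@counts, object@period,
              as.integer(harmonic)))

#' Phasor transform
#'
#' Fourier coordinates `(g, s)` of a decay at a harmonic of the
#' repetition frequency (`omega0 = 2 * pi / period`). For a wrapped
#' monoexponential the continuous transform is
#' `g = 1 / (1 + (omega tau)^2)`, `s = omega tau / (1 + (omega tau)^2)`.
#'
#' @describeIn phasorTransform phasor of an instrument response (used as
#'   the calibration reference).
#' @export
setMethod("phasorTransform", "InstrumentResponse",
  function(object, harmonic = 1L, ...)
    .phasorOf(object@time, object@values, object@period,
              as.integer(harmonic)))

#' Calibrate a phasor point against an instrument-response phasor
#'
#' The measured decay is the IRF convolved with the physical decay, so in
#' phasor space the measured point is the complex product of the two;
#' dividing by the IRF phasor removes the instrument contribution and
#' places monoexponential decays back on the universal semicircle.
#'
#' @param sample a [PhasorPoint-class] of the measured decay.
#' @param reference a [PhasorPoint-class] of the IRF (same harmonic).
#' @return The calibrated [PhasorPoint-class].
#' @export
calibratePhasor <- function(sample, reference) {
  zr <- complex(real = reference@g, imaginary = reference@s)
  if (Mod(zr) <= 0)
    stop("calibration error: reference phasor has zero modulus")
  z <- complex(real = sample@g, imaginary = sample@s) / zr
  phasorPoint(Re(z), Im(z), omega = sample@omega,
              harmonic = sample@harmonic, photons = sample@photons)
}

#' Signed distance to the universal semicircle
#'
#' Distance from a phasor point to the circle centered at (0.5, 0) with
#' radius 0.5; negative inside. Monoexponential decays sit on the circle
#' (distance ~ 0); multi-exponential mixtures sit strictly inside
#' (negative).
#'
#' @param p a [PhasorPoint-class].
#' @return Signed distance (dimensionless).
#' @export
semicircleDistance <- function(p) {
  sqrt((p@g - 0.5)^2 + p@s^2) - 0.5
}

#' Phase and modulation lifetimes of a phasor point
#'
#' `tau_phase = (s/g) / omega` and
#' `tau_mod = sqrt(1/(g^2 + s^2) - 1) / omega`. The two agree for
#' monoexponential decays; for mixtures the phase lifetime is strictly
#' smaller than the modulation lifetime.
#'
#' @param p a [PhasorPoint-class].
#' @return Named numeric: `phase`, `modulation` (ns).
#' @export
phasorLifetimes <- function(p) {
  if (p@g <= 0)
    stop("phase lifetime undefined for g <= 0")
  mod2 <- p@g^2 + p@s^2
  if (mod2 <= 0 || mod2 > 1 + 1e-9)
    stop("modulation lifetime undefined: modulus outside (0, 1]")
  c(phase = tan(atan2(p@s, p@g)) / p@omega,
    modulation = sqrt(max(1 / mod2 - 1, 0)) / p@omega)
}

## 3x3 neighbourhood filters with edge replication, applied per time bin
.neighbourStack <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  vapply(1:3, function(i) vapply(1:3, function(j)
    pad[i:(i + nr - 1), j:(j + nc - 1)], m), array(0, c(nr, nc, 3)))
}
.mean3x3 <- function(m) apply(.neighbourStack(m), c(1, 2), mean)
.median3x3 <- function(m) apply(.neighbourStack(m), c(1, 2), stats::median)

#' Per-pixel phasor map of a FLIM channel
#'
#' Transforms every pixel's decay histogram to phasor coordinates,
#' optionally after a 3x3 spatial filter applied to each time bin's count
#' image -- a denoiser that tightens the phasor photon clouds for better
#' cloud differentiation. The default mean (boxcar) filter is linear in
#' the counts, so it leaves cloud centroids in place; a median variant is
#' available but biases sparse (low counts per bin) histograms, since the
#' median of a skewed count distribution falls below its mean. Pixels
#' with no photons yield NA coordinates and are excluded downstream.
#'
#' @param image a [FLIMImage-class].
#' @param channel channel name or index.
#' @param harmonic harmonic index.
#' @param filter `"mean"` (3x3, per time bin), `"median"` or `"none"`.
#' @param reference optional [PhasorPoint-class] or
#'   [InstrumentResponse-class] for IRF calibration of every pixel.
#' @return A [PhasorMap-class].
#' @export
phasorMap <- function(image, channel = 1L, harmonic = 1L,
                      filter = c("mean", "median", "none"),
                      reference = NULL) {
  filter <- match.arg(filter)
  arr <- image@channels[[channel]]
  nb <- dim(arr)[3]
  if (filter != "none") {
    f <- if (filter == "mean") .mean3x3 else .median3x3
    for (b in seq_len(nb)) arr[, , b] <- f(arr[, , b])
  }
  omega <- harmonic * 2 * pi / image@period
  cosv <- cos(omega * image@time)
  sinv <- sin(omega * image@time)
  tot <- apply(arr, c(1, 2), sum)
  gnum <- apply(sweep(arr, 3, cosv, "*"), c(1, 2), sum)
  snum <- apply(sweep(arr, 3, sinv, "*"), c(1, 2), sum)
  g <- ifelse(tot > 0, gnum / tot, NA_real_)
  s <- ifelse(tot > 0, snum / tot, NA_real_)
  if (!is.null(reference)) {
    if (is(reference, "InstrumentResponse"))
      reference <- phasorTransform(reference, harmonic = harmonic)
    zr <- complex(real = reference@g, imaginary = reference@s)
    if (Mod(zr) <= 0) stop("calibration error: zero-modulus reference")
    z <- complex(real = g, imaginary = s) / zr
    g <- matrix(Re(z), nrow(g)); s <- matrix(Im(z), nrow(g))
  }
  chName <- if (is.character(channel)) channel else
    names(image@channels)[channel]
  new("PhasorMap", g = g, s = s, photons = tot,
      harmonic = as.integer(harmonic), omega = omega,
      channel = if (is.null(chName)) as.character(channel) else chName,
      filter = filter)
}

#' Circular phasor-space ROI
#'
#' @param g,s center coordinates in phasor units.
#' @param radius selection radius in phasor units (default 0.05).
#' @return list with class `"PhasorROI"`.
#' @export
phasorROI <- function(g, s, radius = 0.05) {
  if (radius <= 0) stop("radius must be positive")
  structure(list(g = g, s = s, radius = radius), class = "PhasorROI")
}

#' Photon-weighted average lifetime inside a phasor ROI
#'
#' Selects the pixels whose phasor coordinates fall inside a circular
#' phasor-space ROI (the programmatic analogue of circling a photon
#' cloud) and returns the photon-weighted mean of their phase lifetimes.
#'
#' @param map a [PhasorMap-class].
#' @param roi a [phasorROI()].
#' @return Average lifetime in ns.
#' @export
roiAverageLifetime <- function(map, roi) {
  stopifnot(inherits(roi, "PhasorROI"))
  inside <- !is.na(map@g) &
    (map@g - roi$g)^2 + (map@s - roi$s)^2 <= roi$radius^2
  if (!any(inside))
    stop("empty selection: no pixels inside the phasor ROI")
  g <- map@g[inside]; s <- map@s[inside]; w <- map@photons[inside]
  tauPhi <- (s / g) / map@omega
  sum(w * tauPhi) / sum(w)
}
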