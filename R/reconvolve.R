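## Periodic IRF reconvolution: the forward model of a TCSPC measurement.
## The measured histogram is the excitation-chain IRF convolved with the
## (wraparound-summed) multi-exponential decay, so fitting convolves the
## model with the IRF rather than deconvolving the data.

## conjugate-symmetric frequency indices for an FFT of length n
.fftFreqIdx <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

## circular sub-bin shift of a sampled curve via a Fourier phase ramp
.circShift <- function(v, shift, period) {
  n <- length(v)
  if (shift == 0) return(v)
  ramp <- exp(-2i * pi * .fftFreqIdx(n) * shift / period)
  Re(stats::fft(stats::fft(v) * ramp, inverse = TRUE)) / n
}

#' Expected decay histogram of a model through an instrument response
#'
#' Computes the expected (noise-free) counts per bin for a multi-
#' exponential [DecayModel-class] observed through an
#' [InstrumentResponse-class] at a given repetition period. With
#' `periodic = TRUE` (the default) the multi-exponential is wraparound-
#' summed over all preceding pulses and convolved circularly with the
#' shifted IRF -- the correct model when the decay is not complete within
#' one repetition period. With `periodic = FALSE` a plain (single-pulse)
#' exponential is convolved linearly, the model that overestimates
#' lifetimes at high repetition rates.
#'
#' The IRF time shift is applied as a circular sub-bin translation, so
#' shifting by `s` and evaluating equals evaluating and then translating
#' by `s`.
#'
#' The convolution is carried out on an internally oversampled grid
#' (default 8 sub-bins per histogram bin): the decay is integrated
#' analytically over each sub-bin and the IRF is distributed over the
#' fine grid by monotone-spline interpolation of its cumulative. This
#' resolves the sub-bin alignment between the IRF arrival and the
#' emission delay, whose neglect otherwise overweights the rising-edge
#' bins (the emission-delay density jumps at zero, so same-bin emission
#' must count for roughly half a bin, not a full one).
#'
#' @param model a [DecayModel-class].
#' @param irf an [InstrumentResponse-class] on the histogram's bin axis.
#' @param period repetition period in ns; must match the IRF's.
#' @param periodic logical, use the wraparound-summed periodic model.
#' @param oversample integer sub-bins per histogram bin.
#' @return numeric expected counts per bin (offset included).
#' @export
reconvolve <- function(model, irf, period = repetitionPeriod(irf),
                       periodic = TRUE, oversample = 8L) {
  stopifnot(is(model, "DecayModel"), is(irf, "InstrumentResponse"))
  if (abs(period - irf@period) > 1e-6 * period)
    stop("axis mismatch: IRF period ", irf@period,
         " ns differs from requested period ", period, " ns")
  n <- length(irf@time)
  os <- as.integer(oversample)
  nf <- n * os
  delta <- period / nf                     # fine-grid width
  a <- model@amplitudes
  tau <- model@lifetimes
  edges <- (0:nf) * delta
  ## decay integrated analytically over each fine bin (density scale)
  decay <- numeric(nf)
  for (i in seq_along(tau)) {
    seg <- tau[i] * (exp(-edges[-(nf + 1)] / tau[i]) -
                     exp(-edges[-1] / tau[i])) / delta
    if (periodic) seg <- seg / (-expm1(-period / tau[i]))
    decay <- decay + a[i] * seg
  }
  coarseEdges <- seq(0, period, length.out = n + 1L)
  cdfFun <- stats::splinefun(coarseEdges, c(0, cumsum(irf@values)),
                             method = "monoH.FC")
  irfFine <- diff(cdfFun(edges))
  ## summing two bin-integrated sequences centers their masses at
  ## (j + m + 1) * delta, half a fine bin late of index j + m: realign
  shift <- model@shift + delta / 2
  if (periodic) {
    ramp <- exp(-2i * pi * .fftFreqIdx(nf) * shift / period)
    conv <- Re(stats::fft(stats::fft(irfFine) * ramp *
                          stats::fft(decay), inverse = TRUE)) / nf
  } else {
    m <- 2L * nf                           # zero-pad: linear convolution
    pad <- function(v) c(v, numeric(m - nf))
    ramp <- exp(-2i * pi * .fftFreqIdx(m) * shift / (2 * period))
    conv <- Re(stats::fft(stats::fft(pad(irfFine)) * ramp *
                          stats::fft(pad(decay)), inverse = TRUE))[1:nf] / m
  }
  ## aggregate fine grid back to histogram bins
  colSums(matrix(conv, nrow = os)) / os + model@offset
}
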