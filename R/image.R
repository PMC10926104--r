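## Pooling strategies for FLIM images: whole-image decay pooling,
## mask-based ROI pooling, and a fast per-pixel lifetime map for display.
## Full multi-exponential fits always run on pooled histograms -- at
## realistic photon budgets a per-pixel fit is not statistically
## meaningful, so the per-pixel read-out is phasor-based.

.channelArray <- function(image, channel) {
  arr <- image@channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  arr
}

.channelSpan <- function(image, channel) {
  chName <- if (is.character(channel)) channel else
    names(image@channels)[channel]
  w <- image@channelWindows[[chName]]
  if (is.null(w)) c(NA_real_, NA_real_) else as.numeric(w)
}

#' Pool all pixels of a FLIM channel into one decay histogram
#'
#' Bin-wise sum over every pixel; photon conservation is exact. The
#' pooled histogram is what whole-image lifetime analysis fits.
#'
#' @param image a [FLIMImage-class].
#' @param channel channel name or index.
#' @return A [DecayHistogram-class].
#' @export
poolWholeImage <- function(image, channel = 1L) {
  arr <- .channelArray(image, channel)
  decayHistogram(apply(arr, 3, sum), period = image@period,
                 time = image@time, window = .channelSpan(image, channel),
                 meta = list(pooled = "whole-image",
                             nPixels = prod(dim(arr)[1:2])))
}

#' Pool a masked region of a FLIM channel into one decay histogram
#'
#' Bin-wise sum over the pixels where `mask` is TRUE, e.g. a manually or
#' programmatically selected Lo or Ld region. A full-TRUE mask is
#' equivalent to [poolWholeImage()]; disjoint masks give additive totals.
#'
#' @param image a [FLIMImage-class].
#' @param mask logical matrix matching the pixel dimensions.
#' @param channel channel name or index.
#' @param label optional region label stored in the result's metadata.
#' @return A [DecayHistogram-class].
#' @export
poolROI <- function(image, mask, channel = 1L, label = "") {
  arr <- .channelArray(image, channel)
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(arr)[1:2]))
    stop("mask dimensions must match the image")
  if (!any(mask))
    stop("empty selection: mask contains no pixels")
  flat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3])
  cts <- colSums(flat[as.vector(mask), , drop = FALSE])
  decayHistogram(cts, period = image@period, time = image@time,
                 window = .channelSpan(image, channel),
                 meta = list(pooled = "roi", label = label,
                             nPixels = sum(mask)))
}

#' Fast per-pixel lifetime map for display
#'
#' Phasor phase lifetime per pixel (no fitting), with pixels below a
#' photon-count threshold rendered missing. Intended for lifetime
#' colour-coded images only; quantitative comparisons should use pooled
#' fits or phasor cloud averages.
#'
#' @param image a [FLIMImage-class].
#' @param channel channel name or index.
#' @param minPhotons pixels with fewer photons become NA (default 100,
#'   the advisory minimum for a monoexponential estimate).
#' @param reference optional IRF (or its phasor) for calibration.
#' @param filter spatial filter passed to [phasorMap()].
#' @return Numeric matrix of lifetimes in ns (NA where below threshold).
#' @export
lifetimeDisplayMap <- function(image, channel = 1L, minPhotons = 100,
                               reference = NULL, filter = "none") {
  pm <- phasorMap(image, channel = channel, filter = filter,
                  reference = reference)
  tau <- (pm@s / pm@g) / pm@omega
  tau[is.na(pm@g) | pm@photons < minPhotons] <- NA_real_
  tau
}
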