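## Generics shared across the package. Accessor generics follow the
## Bioconductor convention of short camelCase verbs.

#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @export
setGeneric("timeBins", function(object, ...) standardGeneric("timeBins"))

#' @export
setGeneric("repetitionPeriod", function(object, ...)
  standardGeneric("repetitionPeriod"))

#' @export
setGeneric("totalPhotons", function(object, ...)
  standardGeneric("totalPhotons"))

#' @export
setGeneric("spectralWindow", function(object, ...)
  standardGeneric("spectralWindow"))

#' @export
setGeneric("tauAvInt", function(object, ...) standardGeneric("tauAvInt"))

#' @export
setGeneric("chiSqRed", function(object, ...) standardGeneric("chiSqRed"))

#' @export
setGeneric("lifetimes", function(object, ...) standardGeneric("lifetimes"))

#' @export
setGeneric("amplitudes", function(object, ...) standardGeneric("amplitudes"))

#' @export
setGeneric("phasorTransform", function(object, harmonic = 1L, ...)
  standardGeneric("phasorTransform"))

#' @export
setGeneric("channelNames", function(object, ...)
  standardGeneric("channelNames"))
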