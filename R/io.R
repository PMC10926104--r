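## Plain-text interchange: decay histograms as TSV (time_ns, counts) with
## a JSON sidecar carrying the metadata that the TSV cannot (window,
## period, seed, totals); FLIM images as multi-page TIFF (one page per
## time bin, one file per channel) plus a JSON sidecar and a label-mask
## TIFF. Vendor formats are deliberately out of scope.

.sidecarPath <- function(path) {
  if (grepl("\\.tsv$", path)) sub("\\.tsv$", ".json", path)
  else paste0(path, ".json")
}

#' Write / read a decay histogram as TSV + JSON sidecar
#'
#' The TSV has columns `time_ns` (bin centers) and `counts`; the sidecar
#' (same path with extension `.json`) records the repetition period, bin
#' width, spectral window, total photons and seed. Round trips are
#' lossless, and on read the recomputed total is checked against the
#' sidecar.
#'
#' @param hist a [DecayHistogram-class].
#' @param path TSV file path (`.tsv`).
#' @return `writeDecayHistogram`: the path, invisibly.
#' @export
writeDecayHistogram <- function(hist, path) {
  utils::write.table(
    data.frame(time_ns = hist@time, counts = hist@counts),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(period_ns = hist@period,
               bin_width_ns = if (length(hist@time) > 1)
                 diff(hist@time[1:2]) else NA,
               window_nm = as.numeric(hist@window),
               total_photons = sum(hist@counts),
               meta = hist@meta)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeDecayHistogram
#' @param sidecar sidecar path; defaults to `path` with `.json`.
#' @param period repetition period in ns, required when the sidecar is
#'   missing.
#' @return `readDecayHistogram`: a [DecayHistogram-class].
#' @export
readDecayHistogram <- function(path, sidecar = .sidecarPath(path),
                               period = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_ns", "counts") %in% names(tb)))
    stop("malformed histogram file ", path,
         ": expected columns time_ns and counts")
  bad <- which(tb$counts < 0)
  if (length(bad))
    stop("malformed histogram file ", path, ": negative counts at line ",
         bad[1] + 1L)
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$total_photons) &&
        abs(sum(tb$counts) - side$total_photons) > 1e-6)
      stop("sidecar total (", side$total_photons,
           ") does not match histogram counts (", sum(tb$counts),
           ") for ", path)
    period <- side$period_ns
    window <- if (is.null(side$window_nm)) c(NA_real_, NA_real_) else
      as.numeric(side$window_nm)
    meta <- if (is.null(side$meta)) list() else as.list(side$meta)
  } else {
    if (is.null(period))
      stop("sidecar ", sidecar, " is missing; 'period' must be supplied")
    warning("sidecar missing for ", path,
            ": window and provenance default to NA")
    window <- c(NA_real_, NA_real_)
    meta <- list()
  }
  decayHistogram(tb$counts, period = period, time = tb$time_ns,
                 window = window, meta = meta)
}

## 16-bit dynamic range of the TIFF pages; counts above this cannot be
## stored losslessly
.TIFF_MAX <- 65535

#' Write / read a FLIM image as multi-page TIFF stacks + JSON sidecar
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_<channel>.tiff`, one
#' page per time bin), a label-mask TIFF when ground-truth labels are
#' present, and a sidecar `<prefix>.json` with the period, bin width,
#' dimensions and channel windows. Per-pixel per-bin counts must stay
#' below 65536 for a lossless round trip (they do at any realistic
#' photon budget).
#'
#' @param image a [FLIMImage-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `writeFlimImage`: the sidecar path, invisibly.
#' @export
writeFlimImage <- function(image, dir, prefix = "flim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(image@channels)) {
    arr <- image@channels[[ch]]
    if (max(arr) > .TIFF_MAX)
      stop("counts exceed the 16-bit TIFF range")
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(b) arr[, , b] / .TIFF_MAX)
    tiff::writeTIFF(pages, file.path(dir, paste0(prefix, "_", ch, ".tiff")),
                    bits.per.sample = 16L)
  }
  labels <- image@meta$labels
  if (!is.null(labels))
    tiff::writeTIFF(labels / 255,
                    file.path(dir, paste0(prefix, "_labels.tiff")),
                    bits.per.sample = 8L)
  side <- list(period_ns = image@period,
               bin_width_ns = diff(image@time[1:2]),
               n_bins = length(image@time),
               dim = dim(image@channels[[1]])[1:2],
               channels = names(image@channels),
               channel_windows_nm = image@channelWindows,
               seed = image@meta$seed)
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(sidecar)
}

#' @rdname writeFlimImage
#' @param sidecar path to the JSON sidecar written by `writeFlimImage`.
#' @return `readFlimImage`: a [FLIMImage-class].
#' @export
readFlimImage <- function(sidecar) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  prefix <- sub("\\.json$", "", basename(sidecar))
  nb <- side$n_bins
  arrs <- list()
  for (ch in side$channels) {
    pages <- tiff::readTIFF(file.path(dir, paste0(prefix, "_", ch, ".tiff")),
                            all = TRUE)
    if (length(pages) != nb)
      stop("truncated stack for channel '", ch, "': expected ", nb,
           " pages (period ", side$period_ns, " ns / bin ",
           side$bin_width_ns, " ns), found ", length(pages))
    arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), nb))
    for (b in seq_len(nb)) arr[, , b] <- round(pages[[b]] * .TIFF_MAX)
    arrs[[ch]] <- arr
  }
  labFile <- file.path(dir, paste0(prefix, "_labels.tiff"))
  meta <- list(seed = side$seed)
  if (file.exists(labFile))
    meta$labels <- round(tiff::readTIFF(labFile) * 255)
  cw <- side$channel_windows_nm
  if (!is.null(cw)) cw <- lapply(cw, as.numeric)
  new("FLIMImage", channels = arrs,
      time = (seq_len(nb) - 0.5) * side$bin_width_ns,
      period = side$period_ns,
      channelWindows = if (is.null(cw)) list() else cw, meta = meta)
}
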