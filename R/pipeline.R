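## Reproducible end-to-end runs: a single config (list or YAML file)
## drives simulation, fitting, spectral analysis, phasor analysis or
## condition comparison, writing CSV tables, PNG figures and a JSON
## provenance record. Identical config + seed gives byte-identical CSVs.

.requireFields <- function(config, fields, where) {
  missing <- setdiff(fields, names(config))
  if (length(missing))
    stop("validation error: config block '", where, "' is missing field(s) ",
         paste(missing, collapse = ", "))
}

.resolveProbe <- function(spec) {
  if (is(spec, "ProbeModel")) return(spec)
  if (is.character(spec) && length(spec) == 1L) return(probePreset(spec))
  if (is.list(spec)) return(do.call(relaxationProbe, spec))
  stop("validation error: cannot interpret probe specification")
}

.resolveAcq <- function(spec, seed = NULL) {
  if (is(spec, "AcquisitionConfig")) return(spec)
  if (is.null(spec)) spec <- list()
  if (!is.null(seed)) spec$seed <- seed
  do.call(acquisitionConfig, spec)
}

.writeCSV <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

.readInputs <- function(paths) {
  files <- unlist(lapply(paths, function(p)
    if (dir.exists(p)) list.files(p, pattern = "\\.tsv$",
                                  full.names = TRUE) else p))
  files <- sort(files)
  if (!length(files)) stop("no input histogram files found")
  stats::setNames(lapply(files, readDecayHistogram), basename(files))
}

.fitTables <- function(hists, irf, nComp, fitArgs = list()) {
  rows <- list(); rejects <- list()
  for (nm in names(hists)) {
    h <- hists[[nm]]
    if (!qcFilter(h)) {
      rejects[[nm]] <- data.frame(input = nm, photons = totalPhotons(h),
                                  reason = "below 10^4 photon QC threshold")
      next
    }
    fr <- do.call(fitDecay, c(list(h, irf, n = nComp), fitArgs))
    w <- spectralWindow(h)
    rows[[nm]] <- data.frame(
      input = nm, window_lower_nm = w[1], window_upper_nm = w[2],
      tau_av_int_ns = tauAvInt(fr), chi2_red = chiSqRed(fr),
      total_photons = totalPhotons(h), converged = fr@converged,
      outlier = fr@outlier)
    if (fr@outlier)
      rejects[[paste0(nm, ".outlier")]] <-
        data.frame(input = nm, photons = totalPhotons(h),
                   reason = "fit flagged as outlier")
  }
  list(fits = do.call(rbind, c(rows, list(NULL))),
       rejects = if (length(rejects)) do.call(rbind, rejects) else
         data.frame(input = character(), photons = numeric(),
                    reason = character()))
}

.phasorPlot <- function(path, g, s, photons = NULL) {
  grDevices::png(path, width = 720, height = 560)
  on.exit(grDevices::dev.off())
  th <- seq(0, pi, length.out = 200)
  plot(0.5 + 0.5 * cos(th), 0.5 * sin(th), type = "l", lty = 2,
       xlim = c(0, 1), ylim = c(0, 0.62), xlab = "g", ylab = "s",
       main = "Phasor plot")
  graphics::points(g, s, pch = 16, col = grDevices::rgb(0, 0, 0, 0.3),
                   cex = 0.6)
}

#' Run a configured analysis pipeline
#'
#' Modes: `simulate` (spectral decay series and optionally a two-phase
#' FLIM image, written as TSV/TIFF), `fit` (reconvolution fits of input
#' histograms), `spectral` (fits plus lifetime profile, normalized
#' spectrum and GP), `phasor` (per-decay phasor coordinates and
#' lifetimes, with a phasor plot), and `compare` (lifetime contrast
#' between two input sets). Every run writes `provenance.json` (config,
#' seed, package version); QC rejections and outlier flags go to
#' `rejects.csv` and the run continues.
#'
#' @param config list or path to a YAML file. Required fields: `mode`;
#'   per-mode blocks as documented in the package vignette.
#' @param outDir output directory (default `config$outDir`).
#' @param seed optional seed overriding `config$seed`.
#' @return Named list of written file paths, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .requireFields(config, "mode", "top level")
  mode <- match.arg(config$mode,
                    c("simulate", "fit", "spectral", "phasor", "compare"))
  if (is.null(outDir)) outDir <- config$outDir
  if (is.null(outDir)) stop("validation error: no output directory given")
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- list()

  if (mode == "simulate") {
    .requireFields(config, c("probe", "photons"), "simulate")
    probe <- .resolveProbe(config$probe)
    acq <- .resolveAcq(config$acquisition, seed)
    series <- simulateSpectralSeries(probe, acq, photons = config$photons,
                                     seed = seed)
    for (nm in names(series)) {
      p <- file.path(outDir, paste0("decay_", nm, "nm.tsv"))
      writeDecayHistogram(series[[nm]], p)
      written[[paste0("decay_", nm)]] <- p
    }
    if (!is.null(config$image)) {
      im <- config$image
      map <- twoPhaseDisc(
        n = if (is.null(im$size)) 32 else im$size,
        ld = .resolveProbe(if (is.null(im$ld)) "nr12Ld" else im$ld),
        lo = .resolveProbe(if (is.null(im$lo)) "nr12Lo" else im$lo),
        photonsPerPixel = if (is.null(im$photonsPerPixel)) 1000 else
          im$photonsPerPixel)
      img <- simulateFlimImage(map, acq, seed = seed)
      written$image <- writeFlimImage(img, outDir, "flim")
    }
  } else if (mode %in% c("fit", "spectral")) {
    .requireFields(config, "inputs", mode)
    hists <- .readInputs(config$inputs)
    acq <- .resolveAcq(config$acquisition, seed)
    irf <- gaussianIRF(acq)
    nComp <- if (is.null(config$fit$n)) 2L else config$fit$n
    ft <- .fitTables(hists, irf, nComp)
    written$fits <- .writeCSV(ft$fits, outDir, "fits.csv")
    written$rejects <- .writeCSV(ft$rejects, outDir, "rejects.csv")
    if (mode == "spectral") {
      keep <- vapply(hists, qcFilter, logical(1))
      prof <- spectralProfile(hists[keep], irf, n = nComp,
                              condition = if (is.null(config$condition))
                                "" else config$condition)
      written$profile <- .writeCSV(as.data.frame(prof), outDir,
                                   "spectral_profile.csv")
      ns <- normalizedSpectrum(prof)
      written$spectrum <- .writeCSV(
        data.frame(center_nm = as.numeric(names(ns)), normalized = ns),
        outDir, "normalized_spectrum.csv")
      if (!is.null(config$gp)) {
        cfg <- gpConfig(config$gp$lambdaLo, config$gp$lambdaLd)
        written$gp <- .writeCSV(
          data.frame(lambda_lo_nm = cfg$lambdaLo,
                     lambda_ld_nm = cfg$lambdaLd,
                     gp = gpFromProfile(prof, cfg)),
          outDir, "gp.csv")
      }
    }
  } else if (mode == "phasor") {
    .requireFields(config, "inputs", "phasor")
    hists <- .readInputs(config$inputs)
    acq <- .resolveAcq(config$acquisition, seed)
    irfPoint <- phasorTransform(gaussianIRF(acq))
    rows <- lapply(names(hists), function(nm) {
      p <- calibratePhasor(phasorTransform(hists[[nm]]), irfPoint)
      lt <- tryCatch(phasorLifetimes(p), error = function(e)
        c(phase = NA_real_, modulation = NA_real_))
      data.frame(input = nm, g = p@g, s = p@s,
                 tau_phase_ns = lt[["phase"]],
                 tau_mod_ns = lt[["modulation"]],
                 photons = p@photons)
    })
    tb <- do.call(rbind, rows)
    written$phasor <- .writeCSV(tb, outDir, "phasor.csv")
    fig <- file.path(outDir, "phasor.png")
    .phasorPlot(fig, tb$g, tb$s)
    written$figure <- fig
  } else { # compare
    .requireFields(config, "compare", "compare")
    .requireFields(config$compare, c("a", "b", "lambda"), "compare")
    acq <- .resolveAcq(config$acquisition, seed)
    irf <- gaussianIRF(acq)
    nComp <- if (is.null(config$fit$n)) 2L else config$fit$n
    profA <- spectralProfile(.readInputs(config$compare$a), irf, n = nComp,
                             condition = "A")
    profB <- spectralProfile(.readInputs(config$compare$b), irf, n = nComp,
                             condition = "B")
    lam <- config$compare$lambda
    written$compare <- .writeCSV(
      data.frame(lambda_nm = lam,
                 tau_a_ns = profA@table$tauAvInt[.profileRowAt(profA, lam)],
                 tau_b_ns = profB@table$tauAvInt[.profileRowAt(profB, lam)],
                 delta_tau_ns = deltaTau(profA, profB, lam)),
      outDir, "delta_tau.csv")
  }

  prov <- list(config = config, seed = seed,
               package = as.character(utils::packageVersion("flimkit")))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  written$provenance <- file.path(outDir, "provenance.json")
  invisible(written)
}
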