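# flimkit

Simulation and analysis of spectrally resolved fluorescence-lifetime
(FLIM/TCSPC) data in R.

Solvatochromic membrane probes report lipid order through two coupled
read-outs: the position of their emission spectrum and their
fluorescence lifetime, which for such dyes *rises with the emission
wavelength* up to a probe-specific plateau (a signature of solvent
relaxation). Quantifying membrane order from such data means fitting
photon-arrival histograms per spectral window, summarising each fit by
one number, and comparing conditions — while keeping two instrumental
artifacts under control: **wraparound** (incomplete decays at high laser
repetition rates inflate lifetimes) and **pile-up** (detector dead time
at high count rates deflates them).

`flimkit` provides that full chain for microscopists and method
developers:

* **Simulation** — multi-exponential TCSPC decays through a Gaussian
  IRF, with Poisson statistics, per-pulse pile-up and single-photon
  filtering, repetition-rate wraparound, wavelength-dependent probe
  presets (liquid-ordered / liquid-disordered variants and a flat
  control), and two-phase vesicle images; all reproducible from a
  single seed.
* **Fitting** — periodic (wraparound-correct) n-exponential
  IRF-reconvolution by Levenberg–Marquardt, reporting the
  intensity-weighted mean lifetime
  `tau_AvInt = sum(a_i tau_i^2) / sum(a_i tau_i)`, reduced chi-square,
  photon-count QC (10^4-photon exclusion; 10^2/10^4/10^6 advisory
  minima for 1/2/3 components) and outlier flags.
* **Spectral analysis** — per-window lifetime profiles, normalized
  intensity spectra, generalized polarization
  `GP = (I_B − I_R)/(I_B + I_R)`, and signed lifetime contrasts
  (`deltaTau`) between conditions.
* **Phasor analysis** — fit-free `(g, s)` coordinates, IRF calibration,
  universal-semicircle geometry, phase/modulation lifetimes, per-pixel
  phasor maps with cloud selection.
* **Image pooling** — whole-image and mask-based ROI pooling of
  per-pixel histograms, and a phasor-based per-pixel lifetime map for
  display.
* **I/O and pipeline** — TSV + JSON-sidecar decay histograms,
  multi-page TIFF image stacks, YAML-configured `runPipeline()` runs
  writing CSV tables, figures and provenance, plus a thin CLI
  (`inst/exec/flimkit`).

## Worked example

```r
library(flimkit)

## acquisition: 20 MHz, 50 ps bins, Gaussian IRF (120 ps FWHM at 2 ns)
acq <- acquisitionConfig(rateMHz = 20, seed = 42)
irf <- gaussianIRF(acq)

## simulate a spectral decay series of an Ld-phase membrane probe
ld <- probePreset("nr12Ld")
series <- simulateSpectralSeries(ld, acq, photons = 1e6)

## per-window reconvolution fits -> spectral lifetime profile
prof <- spectralProfile(series, irf, n = 2, condition = "nr12Ld")
prof
#> SpectralLifetimeProfile 'nr12Ld': 10 windows
#>    center lower upper tauAvInt intensity chiSqRed nPhotons outlier
#> 1     510   500   520    1.347     15119   0.3077    15119   FALSE
#> 2     530   520   540    2.010     33648   0.3946    33648   FALSE
#> 3     550   540   560    2.553     63813   0.4653    63813   FALSE
#> 4     570   560   580    2.955    103126   0.6030   103126   FALSE
#> 5     590   580   600    3.281    142018   0.8018   142018   FALSE
#> 6     610   600   620    3.522    166660   0.7946   166660   FALSE
#> 7     630   620   640    3.708    166659   0.9026   166659   FALSE
#> 8     650   640   660    3.855    142018   0.7299   142018   FALSE
#> 9     670   660   680    3.841    103126   0.8424   103126   FALSE
#> 10    690   680   700    3.776     63813   0.7394    63813   FALSE
```

The fitted lifetime climbs from 1.35 ns at 510 nm towards its plateau
near 650 nm — the wavelength dependence the simulator builds in (its
ground truth rises 1.40 → 3.90 ns). Intensities peak at 620 nm, the
preset's red-shifted (disordered-phase) emission maximum.

```r
## generalized polarization from the same summed intensities
gpFromProfile(prof, gpConfig(lambdaLo = 550, lambdaLd = 670))
#> [1] -0.2354932
```

A negative GP: the spectrum is red-shifted, as expected for a
disordered-phase environment.

```r
## lifetime contrast against the Lo-phase preset at 570 nm
lo <- probePreset("nr12Lo")
profLo <- spectralProfile(
  simulateSpectralSeries(lo, acq, photons = 1e6, seed = 43),
  irf, n = 2, condition = "nr12Lo")
deltaTau(profLo, prof, 570)
#> [1] 2.152893
```

The recovered Lo−Ld contrast at 570 nm (2.15 ns) matches the presets'
ground-truth gap of 2.2 ns within statistical error.

```r
## fit-free phasor read-out of the pooled (500-700 nm) decay
h <- combineHistograms(series)
pt <- calibratePhasor(phasorTransform(h), phasorTransform(irf))
pt
#> PhasorPoint: g = 0.8307, s = 0.3420 (harmonic 1, omega 0.1257 rad/ns)
phasorLifetimes(pt)
#>      phase modulation
#>   3.276052   3.892535
```

Phase lifetime below modulation lifetime: the pooled decay is a
multi-exponential mixture, sitting inside the universal semicircle.

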