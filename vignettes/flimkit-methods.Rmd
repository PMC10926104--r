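---
title: "Methods: simulating and analysing spectrally resolved FLIM data"
author: "flimkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing spectrally resolved FLIM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimkit)
```

# The measurement model

A time-correlated single photon counting (TCSPC) instrument records, for
each detected photon, the delay between a laser pulse and the photon's
arrival, binned into a histogram over one repetition period
$T = 1000/f$ ns (rate $f$ in MHz). Three physical ingredients shape that
histogram:

1. **The decay.** A fluorophore population decays as a sum of up to three
   exponentials with pre-exponential amplitudes $a_i$ and lifetimes
   $\tau_i$. Because excitation is periodic, emission from *earlier*
   pulses wraps into the current period; summing the geometric series
   gives the wrapped density per component,
   $a_i\, e^{-t/\tau_i} / (1 - e^{-T/\tau_i})$ for $t \in [0, T)$. When
   $T \gg \tau$ the correction is negligible; at 80 MHz
   ($T = 12.5$ ns) it is not.
2. **The instrument response.** The measured histogram is the wrapped
   decay convolved (circularly, because both are periodic) with the
   instrument response function (IRF). The simulator uses a Gaussian IRF
   of 120 ps FWHM, inside the 100--150 ps pulse width of a white-light
   laser source, centered by default at 2 ns to leave a pre-pulse
   baseline in view.
3. **Detection.** Photon counts are Poisson. At high count rates the
   detector dead time keeps only the earliest photon of a multi-photon
   pulse ("pile-up"), over-representing early arrivals and biasing
   lifetimes downward; a single-photon filter that discards multi-photon
   pulses outright removes that bias at the cost of throughput.

## Fitting

`fitDecay()` performs n-exponential *reconvolution*: the model --
amplitudes, lifetimes, a constant offset and an IRF time shift -- is
convolved with the IRF by `reconvolve()` and compared with the data, so
the data are never deconvolved. The default objective is weighted least
squares with Neyman weights $1/\max(c_k, 1)$; a Poisson maximum-likelihood
deviance objective is available (`estimator = "mle"`). Optimization uses
Levenberg--Marquardt with box constraints (non-negative amplitudes and
offset, positive lifetimes, bounded shift); lifetimes are reported in
ascending order. Default fit ranges are 0.2--45 ns at 20 MHz, 0.2--25 ns
at 40 MHz and 0.2--12.5 ns at 80 MHz, configurable.

The headline quantity is the intensity-weighted mean lifetime
$$\tau_{\mathrm{AvInt}} \;=\; \frac{\sum_i I_i\,\tau_i}{\sum_i I_i},
\qquad I_i = a_i\,\tau_i,$$
the mean of the component lifetimes weighted by their steady-state
intensities.

Quality control excludes histograms with fewer than $10^4$ photons;
advisory minima of $10^2$, $10^4$ and $10^6$ photons apply to mono-, bi-
and triexponential fits. Fits with $\tau_{\mathrm{AvInt}}$ outside
0.1--20 ns or reduced $\chi^2 > 5$ are flagged as outliers rather than
silently dropped.

### Numerical choices in the forward model

The discrete convolution is evaluated on an internally oversampled grid
(8 sub-bins per histogram bin): the wrapped decay is integrated
analytically over each sub-bin, the IRF is redistributed onto the fine
grid by monotone-spline interpolation of its cumulative, and the product
is realigned by half a sub-bin (summing two bin-integrated sequences
otherwise centres their mass half a bin late). Without these steps the
rising-edge bins of the model are overweighted -- the emission-delay
density jumps at zero, so same-bin emission must count for roughly half a
bin -- which visibly biases high-repetition-rate fits. With them, the
model matches continuous quadrature of the IRF-decay integral to about
$10^{-6}$ relative in smooth regions and $2\times10^{-4}$ at the rising
edge, where the accuracy of reconstructing a continuous IRF from its
binned histogram is the limit.

Two identifiability switches matter in special situations and are
otherwise left on. `fitShift = FALSE` pins the IRF shift when the fit
range excludes the rising edge (nothing else constrains it).
`fitOffset = FALSE` pins the background offset; at 80 MHz the offset is
nearly collinear with the wrap-around baseline of a slow component, and
freeing both lets noise wander the fit along a flat valley.

### Estimator bias

Neyman weighting is the package default because it mirrors common
commercial practice, but it is known to deflate lifetimes by 1--2 % when
many fitted bins hold only a few counts (observed counts in the
denominator underweight upward fluctuations). The reduced $\chi^2$ is
correspondingly calibrated (mean within 0.9--1.1 over replicates) only
when bins are well populated, e.g. at 80 MHz where the wrapped decay
keeps all bins high. Tests that assert *unbiased* recovery therefore use
the Poisson MLE objective; tests of contrasts (differences of lifetimes)
use the default, whose bias largely cancels between conditions.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests.

**Wavelength dependence.** Solvatochromic membrane probes emit at longer
wavelengths the longer the excited state has relaxed, so their apparent
lifetime rises with the emission window. The generator emulates this
phenomenologically: the per-window mean lifetime follows the saturating
curve
$\tau(\lambda) = \tau_{\max} - (\tau_{\max} - \tau_{\min})
e^{-(\lambda - 500)/\lambda_{s}}$, clipped flat above a probe-specific
plateau wavelength. No time-resolved emission spectrum is modelled; only
window-level lifetimes are needed downstream. `relaxationProbe()` solves
$\tau_{\max}$ so the curve passes exactly through an anchor value at
570 nm, making preset lifetime contrasts exact by construction.

**Presets.** Two preset families are bundled, with liquid-ordered (Lo)
and liquid-disordered (Ld) variants: a Flipper-like pair (biexponential,
plateau 600 nm, small spectral shift, anchors 4.0/5.6 ns giving a 1.6 ns
Lo-Ld contrast) and an NR12-like pair (plateau 650 nm, large spectral
shift, Lo-Ld lifetime gap largest below 600 nm). A constant 4.1 ns
monoexponential `control` probe emulates a wavelength-independent
reference dye. All preset numbers are simulator ground truth -- declared
here, not inferred from any measurement of the real dyes.

**Spectral windows** tile 500--700 nm in 20 nm half-open intervals
labelled by centre; broad 100 nm channels (green 500--600, red 600--700)
are built by pooling member windows weighted by the probe's
emission-spectrum brightness (`probeBroadband()`).

**Photon sampling.** An arrival time is an exponential draw (component
chosen proportionally to its intensity $a_i \tau_i$) plus Gaussian IRF
jitter, taken modulo $T$ -- wraparound arises naturally. Per-pulse mode
draws Poisson($\mu$) photons per pulse and applies, in order, the
single-photon filter (discarding multi-photon pulses: the filter
inspects the pulse before the detector loses photons to dead time; in
the reverse order the detector would only ever present single photons
and the filter could do nothing) and then pile-up (keeping the earliest
photon). Direct mode draws an exact photon budget when neither artifact
is enabled. Images derive one substream seed per pixel by exact integer
hashing (`substreamSeed()`), so results are bit-identical for a given
seed regardless of evaluation order.

**What is *not* emulated:** detector afterpulsing and dark-count
structure, vendor file formats, excitation spectra, continuous
time-resolved emission, and the photophysics behind the lifetime changes
(solvent relaxation is reproduced as a curve, not a mechanism). Passing
tests therefore validate the analysis chain against these idealized
conditions, not against every property of real data.

# Spectral analysis and GP

`spectralProfile()` fits each window's histogram and collects
$\tau_{\mathrm{AvInt}}$ and summed intensity per window, dropping
QC-failing windows with a warning. `normalizedSpectrum()` divides window
intensities by their maximum; its optional cubic-spline curve is
display-only and never feeds any statistic. Generalized polarization is
$$\mathrm{GP} = \frac{I_B - I_R}{I_B + I_R} \in [-1, +1],$$
with $I_B$ and $I_R$ the summed intensities in the windows *containing*
the configured blue and red wavelengths (containment, not
nearest-centre: the analysis windows are 20 nm wide, so exact-wavelength
lookup is ill-posed). `deltaTau()` reports the signed lifetime contrast
between two conditions at a wavelength.

# Phasor analysis

`phasorTransform()` maps a decay to
$g = \langle\cos n\omega_0 t\rangle$, $s = \langle\sin n\omega_0
t\rangle$ ($\omega_0 = 2\pi/T$, first harmonic by default -- the
conventional choice), evaluated at bin centres. Monoexponentials satisfy
$g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau/(1+(\omega\tau)^2)$ -- the
universal semicircle -- and mixtures lie on chords strictly inside.
Because the measured decay is IRF $\circledast$ decay, the measured
phasor is the complex product of the two; `calibratePhasor()` divides by
the IRF phasor to undo it. Phase and modulation lifetimes are
$\tau_\phi = (s/g)/\omega$ and
$\tau_m = \sqrt{1/(g^2+s^2) - 1}/\omega$.

`phasorMap()` transforms each pixel, optionally after a per-time-bin 3x3
spatial filter. The default filter is a *mean* (boxcar): the phasor
transform is linear in counts, so a linear filter tightens photon clouds
without displacing their centroids. A median variant is provided for
robustness to bright outlier pixels, with a caveat: on sparse histograms
(order one count per bin) the median of a skewed count distribution sits
below its mean, which measurably displaces the cloud -- use it only on
well-filled histograms. Cloud read-out uses a circular ROI in $(g, s)$
units (`phasorROI()`, default radius 0.05 -- a GUI's pixel-radius
selection has no physical analogue here) and returns the photon-weighted
mean phase lifetime of the pixels inside.

# Image pooling

Whole-image and mask-based ROI pooling sum per-pixel histograms bin-wise
(photon conservation is exact) and fit the pooled decay; per-pixel
*fitting* is deliberately not offered, since realistic per-pixel budgets
(about $10^3$ photons) cannot support a multi-exponential fit. The
per-pixel read-out for display, `lifetimeDisplayMap()`, is the phasor
phase lifetime with pixels under 100 photons (the monoexponential
advisory minimum) rendered missing. Pooling a whole image whose phases
differ only slightly averages the contrast away; mask-based pooling of
each phase resolves it -- both behaviours are exercised in the tests.

# Artifact studies

**Repetition rate.** The recommended operating point keeps the
inter-pulse interval near ten times the mean lifetime
(`recommendRepetition()`; 5 ns lifetime, 50 ns interval, at most
20 MHz). Fitting with a *non-periodic* model (plain exponential, linear
convolution) inflates lifetimes at high rates: each component's wrapped
amplitude is boosted by $1/(1-e^{-T/\tau_i})$, which favours slow
components, so the recovered intensity weighting -- and with it
$\tau_{\mathrm{AvInt}}$ -- rises with rate. The effect needs at least
two components: a wrapped monoexponential keeps a purely exponential
shape. For a 5 ns biexponential (1.5/5.8 ns) the systematic inflation is
about +0.0001/+0.009/+0.088 ns at 20/40/80 MHz; at 20 MHz it is far
below any realistic photon noise, so the monotonicity of the bias is
assessed on noise-free expected-count histograms, while the 80 MHz
bias-removal check (periodic reconvolution eliminates $\ge 90\%$ of it)
runs on Poisson-simulated photons. This study places the IRF at 0.15 ns,
as on instruments whose record starts at the pulse, so the standard fit
windows contain no pre-pulse region.

**Pile-up.** At $\mu = 0.5$ photons per pulse with first-photon
detection, fitted lifetimes fall well below truth; enabling the
single-photon filter restores them to within 1 % at $10^6$ photons.

# Problem sizes and runtime

Test and acceptance runs use decays of $10^5$--$10^7$ photons, spectral
series of $1$--$2\times10^6$ photons over ten windows, and images of
$10^2$--$10^3$ pixels at $10^2$--$10^3$ photons per pixel with 0.1--0.2 ns
bins -- sizes chosen so the full suite completes in a few minutes on one
CPU while keeping every statistical margin at three standard errors or
better. Larger runs scale linearly in photons and pixels.

# Known limitations

* The IRF must be supplied (the simulator's Gaussian IRF is exact);
  estimating an IRF from scattering measurements is out of scope.
* Neyman-weighted fits inherit the low-count deflation discussed above;
  prefer `estimator = "mle"` for absolute lifetimes from sparse data.
* The 16-bit TIFF interchange holds per-pixel per-bin counts up to
  65535.
* Phasor ROI selection is programmatic; there is no interactive tool.
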