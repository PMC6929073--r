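---
title: "Methods: simulating and analysing pulsed-QCL infrared spectroscopy"
author: "qclspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pulsed-QCL infrared spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qclspec)
```

## Scope and model

`qclspec` is a synthetic end-to-end study of multianalyte quantification by
tuneable pulsed quantum cascade laser (QCL) absorption spectroscopy in the
1200--925 cm^-1^ fingerprint region, in two sensing configurations:

* **transmission** through a 165 µm liquid gap between two fibers, and
* **attenuated total reflection (ATR)** at the top facet of a trapezoidal
  ZnS prism (24 × 6 × 2.4 mm, 45° coupling facets), where the evanescent
  field of the totally internally reflected beam samples the liquid.

The analyte system is aqueous glucose (0--800 mg/dL) and albumin
(0--6000 mg/dL) with urea (0--200 mg/dL) and lactate (0--90 mg/dL) as
interferents -- a deliberately overlapping-band mixture relevant to
biomedical sensing. The pipeline chains five stages, each usable on its
own: prism ray optics, A-optimal mixture design, pulse-resolved instrument
simulation, signal processing, and PLS chemometrics with cross-validation.

## Prism optics

The central ray enters at the midpoint of the 45° entry facet at normal
incidence, so it propagates unrefracted at 45° and bounces specularly
between the top (sampling) and bottom facets until it leaves through the
exit facet. For the standard geometry this gives 9 reflections, 5 of them
on the sampling facet, and a 30.5 mm in-prism path. A useful property of
the 45° entry facet is that every normally incident entry ray strikes the
top facet at the same abscissa, so the reflection pattern is independent of
the entry offset; only the short entry and exit segments of the path
depend on it.

One design question deserves a note. Halving the prism height is often
described as doubling the number of internal reflections at constant path.
Exact 2-D geometry gives 19 (not 18) reflections for the 1.2 mm prism and
a path 5.5% longer, because the bounce count is the smallest odd $k$
exceeding $L/h - 2$ (the entry and exit half-segments make it odd). The
package returns the exact counts; the "doubling" statement holds to within
one reflection and the path to within ten percent, and the tests assert it
at that fidelity.

Divergent delivery (fiber NA 0.30, 400 µm core) is modelled by eight
marginal rays -- entry offsets $\{-r, 0, +r\}$ crossed with internal
divergence angles $\pm\arcsin(\mathrm{NA}/n_1)$ -- reporting the
worst-case path difference versus the central ray. With water at
$n_2 = 1.33$ the steepest marginal ray falls below the critical angle
($45° - 7.8° < 37.2°$); the trace reports this as a loss of total internal
reflection rather than guessing. The dispersionless defaults are
$n_1 = 2.2$ (ZnS near 10 µm) and $n_2 = 1.3$ (water in the mid-infrared),
under which all marginal rays stay confined.

The evanescent penetration depth follows the Harrick expression
$d_p = \lambda / (2\pi n_1 \sqrt{\sin^2\theta - (n_2/n_1)^2})$, about
1.55--2.01 µm across the scan. The literature convention for the
*effective sampling depth* is a small multiple of $d_p$ (material beyond
one decay length still attenuates the reflection); we use
`effectiveDepthFactor = 2.62`, chosen so the sampling depth spans
4.07--5.28 µm across 1200--925 cm^-1^ -- inside the conventional
4--5.4 µm window at both ends -- giving per-reflection-count interaction
lengths of 20.3--26.4 µm with 5 sampling reflections. A factor of 2.9,
sometimes quoted as "≈3 d_p", would overshoot the upper end (5.84 µm);
2.62 is the value that satisfies the window at both edges for this
geometry. The factor is exposed as a configuration argument.

## Experiment design

The 25 calibration mixtures come from a quadratic Scheffé mixture model
with A-optimality. Each analyte is scaled by its range maximum to a
pseudo-component $x_i \in [0,1]$ and a fifth closing component (the
aqueous diluent) completes the simplex -- the Scheffé canonical form (no
intercept, no pure quadratics) requires simplex-constrained compositions.
With $q = 5$ components the model has $5 + 10 = 15$ terms. The optimiser
is a plain Fedorov single-point exchange over a degree-4 simplex-lattice
candidate grid (70 points), minimising $\mathrm{tr}[(X^\top X)^{-1}]$ from
random full-rank starts with 20 restarts. Exchanges only accept strict
improvements, so the criterion descends monotonically, and the whole
search is deterministic given its seed. Candidates are kept in canonical
lexicographic order so the result does not depend on how the grid was
generated. Concentrations are mapped back to mg/dL and are exact grid
multiples.

## Instrument simulation

The simulated laser scans 1200 → 925 cm^-1^ at 275 cm^-1^/s with 500 ns
pulses at 100 kHz: a 5% duty cycle, 1 s and 100,000 pulses per scan. One
intensity value is stored per pulse (the digitiser's intra-pulse waveform
is out of scope). Per pulse,

$$ I = E(\tilde\nu)\, T(\tilde\nu)\,(1+\epsilon_\mathrm{pulse})
       (1+\delta_\mathrm{scan}) + \eta_\mathrm{det}, $$

with $E$ a unit-normalised Gaussian gain envelope (centre 1060 cm^-1^,
width 120 cm^-1^, above 0.5 at both scan edges) and $T$ the Beer--Lambert
transmittance

$$ T = 10^{-\left(\sum_a \varepsilon_a(\tilde\nu)\, c_a +
        a_w(\tilde\nu)\right) L(\tilde\nu)}. $$

$L$ is 165 µm in transmission and the wavelength-dependent evanescent
interaction length (≈20--26 µm) in ATR -- the origin of the ≈7× lower ATR
analyte absorbance. The water term $a_w$ is a flat baseline plus a
logistic rise below a 960 cm^-1^ edge; it cancels between sample and
background but suppresses the transmitted intensity at long paths, which
is what amplifies relative noise below ~970 cm^-1^ in transmission (and
much less in ATR).

Band library: lactate at 1040/1124 cm^-1^ and urea at ~1160 cm^-1^;
glucose is modelled with bands at 1036/1080/1110/1152 cm^-1^ and albumin
as two broad weak bands across 1050--1170 cm^-1^, positions from standard
mid-infrared solution spectra. All shapes are Gaussian (a configurable
simplification) and the amplitudes are synthetic, calibrated only so that
800 mg/dL glucose over 165 µm peaks near 0.1 AU; they are not fits to any
measured spectrum.

Noise parameters and their calibration:

* `perPulseRsd = 3.54%` -- back-derived so that 255-pulse × 10-scan
  averaging leaves $0.0354/\sqrt{2550} = 0.07\%$, the documented
  post-averaging RSD (equivalently 0.0003 AU).
* `scanOffsetSd = 0.1%` -- multiplicative per-scan offset; exercised by the
  scan-to-scan alignment.
* `scanShiftSd = 1` spectral bin -- integer wavenumber-registration jitter
  per scan; exercised by the chi-squared alignment.
* `detectorNoiseSd = 2e-4` (additive, envelope units) and
  `seriesDriftSd = 5e-4` (slow sample-vs-background drift within a series)
  are free parameters with no documented counterpart; they are set small
  enough that the cross-validated prediction quality of the synthetic
  study matches the instrument-class performance reported for such
  systems (glucose R² ≈ 0.99+ in both configurations), while keeping the
  water-edge noise amplification and the series-level generalisation gap
  qualitatively visible.

What the generator deliberately does not emulate: ATR band distortions
(anomalous dispersion), detector nonlinearity, fiber dispersion, etalon
fringes, atmospheric lines, or intra-pulse chirp. Passing tests therefore
demonstrate the correctness of the processing and regression chain under
the stated noise model, not robustness to those real-world artefacts.

## Signal processing

Each scan is reduced by averaging 255 consecutive pulses per spectral bin.
`floor(100000/255) = 392` complete bins are possible; the chain keeps the
first 390 (two edge bins dropped) to work on a 390-point spectrum at
0.705 cm^-1^ nominal spacing -- the point count is configurable. Axes are
stored ascending; the descending scan direction lives in metadata.

Scans 2..n of a measurement are aligned to its first scan by a chi-squared
grid search over integer bin shifts with a closed-form additive intensity
offset per shift (ties break toward the smaller |shift|), then averaged.
The sample average is aligned to the background average the same way but
with two differences, both consequences of the sample genuinely absorbing:

* the fit runs on **log10 intensities over an analyte-free window**
  (default 925--1000 cm^-1^, where none of the four analytes absorb and
  the steep water edge provides the registration feature). A full-range
  intensity-domain fit is biased: it can trade a spurious 1--2 bin shift
  against its free offset and imprint a large water-edge artefact on the
  absorbance.
* only the recovered shift is applied. The fitted offset (a multiplicative
  gain in the log domain) is left in place -- subtracting it would remove
  genuine absorbance signal.

Two further registration details matter once many measurements are
combined into one dataset:

* **a study-wide anchor.** Aligning each sample only to its own
  background leaves every pair on the (jittered) registration of its
  first background scan, so band positions wander ±1 bin *between*
  measurements -- a band-position noise that multivariate regression
  cannot average away and that dominated ATR prediction error before
  anchoring. The pipeline therefore registers every background average
  onto the first background of the study (shift only; two backgrounds
  share their structure, so a full-range fit is unbiased) and lets each
  sample follow its background. This is the "offset between measurements"
  half of the alignment procedure.
* **edge exclusion.** Applying a shift of up to `maxShift` bins pads the
  spectrum ends with their nearest values; those bins are corrupted in a
  measurement-dependent way and, once standardised to unit variance,
  would be amplified into the regression. The pipeline excludes
  `maxShift + 1` points at each end of the feature matrix (the stored
  spectra keep all 390 points).

Absorbance is $A = -\log_{10}(I/I_0)$ (base-10; "absorbance units"
throughout). Noise characterisation uses the across-replicate sd/mean per
point, averaged over 1200--1000 cm^-1^ where laser noise dominates.

Numerical fidelity: in the noiseless limit the chain reproduces the
injected Beer--Lambert profile up to the within-bin quadrature of the
exponential -- averaging intensities over a 0.7 cm^-1^ bin is not exactly
the intensity at the bin-centre wavenumber. This residual is ~1e-6 AU
(≈0.01 mg/dL of glucose), far below every noise scale; the tests assert
linearity of the chain at 1e-5 AU and zero-noise cross-validation errors
below 0.05 mg/dL rather than a literal machine-precision identity.

## Chemometrics

Preprocessing is Savitzky--Golay smoothing (width 9, polynomial order 2 --
the order is our choice; only the width is conventional for this kind of
data) followed by per-feature centring and unit-variance scaling.
Scaling statistics are always refit on the training fold and applied to
held-out spectra, never the reverse. Near-constant features are centred
but not scaled.

Regression is NIPALS partial least squares, deterministic, with one PLS1
model per analyte (whether the original analysis used PLS1 or PLS2 is not
documented; PLS2 is available through the multi-response fit). Extraction
stops early with a warning when the deflated X is exhausted. Prediction
uses $B = W (P^\top W)^{-1} Q^\top$ truncated to any latent-variable
count, so one fit serves all counts in a scan of 1--8.

Cross-validation schemes:

* **LOOCV** -- one measurement per fold;
* **L5OCV** -- blocks of five consecutive samples in design order *within
  each series* (the grouping convention is ours; the literature rarely
  states one);
* **LDOCV** -- one fold per measurement series, which probes day-to-day
  and series-to-series generalisation and is therefore expected to sit at
  or above LOOCV error whenever a series-level offset exists.

RMSECV is the root-mean-square error over pooled held-out predictions;
R² is computed about the reference mean on the same pool. RMSE values are
scale-dependent -- they scale exactly with the concentration range -- so
R² is reported alongside.

## Study layout and problem sizes

The default study (`runStudy()`) measures the 25 designed samples in 4
series (2 per day on 2 days) in both configurations: 200 background +
200 sample measurements of 10 scans × 100,000 pulses each, processed to
two 390 × 100 absorbance matrices and cross-validated per scheme and
analyte. This runs in roughly two minutes on one core. The unit-test
suite exercises the identical chain at a reduced instrument scale
(2000 pulses/scan, 5-pulse bins) chosen so every stage -- including
alignment and binning edge cases -- is still fully active; the acceptance
suite runs the full-scale study.

## Known limitations

* Band amplitudes and the water edge are plausible but synthetic;
  RMSECV magnitudes from the simulator characterise the chain, not any
  physical instrument.
* The 2-D trace ignores polarisation-resolved Fresnel coefficients and
  3-D skew rays; the marginal-ray path spread is convention-dependent
  (it depends on which rays one calls "most of the beam").
* The effective-depth factor is a calibration, not a derivation; the
  underlying reference values for the 4--5.4 µm depth do not come with a
  stated formula.
* ATR band distortion physics is out of scope, so ATR and transmission
  spectra differ here only by the interaction length.
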