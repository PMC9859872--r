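---
title: "Methods: strip quantification, 4PL calibration and detection limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strip quantification, 4PL calibration and detection limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The assay and its model

`lfaquant` targets competitive (binding-inhibition) lateral flow assays
for small molecules. The labelled detection antibody is pre-incubated
with the sample as it migrates; free analyte occupies its paratopes, and
only the *free fraction* of antibody can still bind the antigen
immobilized on the test line. The test-line colour therefore decreases
with analyte concentration, while a secondary-antibody control line
captures conjugate regardless of analyte.

Two model layers appear in the package:

* **Mechanistic (generator only).** At equilibrium with analyte in
  excess, the free fraction of antibody sites is `f(C) = Kd / (Kd + C)`
  with `C` the molar analyte concentration and `Kd = kd/ka`
  (`free_fraction()`). With the default antibody kinetics
  (ka = 2.4·10⁴ M⁻¹s⁻¹, kd = 1.3·10⁻³ s⁻¹, so Kd ≈ 54 nM ≈ 15 µg l⁻¹
  for a 277.4 g mol⁻¹ analyte) this is a one-site isotherm — a 4PL with
  slope 1. It motivates the shape of the simulated response; nothing in
  the analysis chain assumes it.
* **Empirical (analysis).** Calibration fits the four-parameter
  logistic `y = A2 + (A1 − A2)/(1 + (x/x0)^p)` to blank-normalized
  responses. `A1` is the blank response (1 after normalization), `A2`
  the residual response at saturation, `x0` the inflection = EC50, and
  `p` a free slope that absorbs everything the one-site picture ignores
  (transport, drying, avidity). Fitting uses raw concentrations; the
  blank enters through the model's own limit `y(0) = A1`, valid for
  `p > 0`, which is enforced as a bound.

## Signal evaluation chain

Given an image and a nominal layout, `strip_signals()` applies:

1. **Zone localization** (`detect_zones()`). The ablated channel
   barriers are permanent high-contrast landmarks, so a global
   translation is estimated by exhaustively scanning a ±8 px window for
   the offset minimizing the mean green intensity under the layout's
   barrier mask. A deterministic matcher was chosen over a learned
   detector deliberately: there is no public training corpus for this
   strip format, and an exhaustive scan is reproducible and testable
   (the error path — fiducials absent — is detected by a minimum
   contrast of 15 intensity units against the median background).
   Rotation and perspective are out of scope.
2. **Green plane** (`green_plane()`): the red spot absorbs green light,
   so the green channel carries the depletion signal.
3. **Illumination correction** (`correct_illumination()`). A first-order
   (planar) surface is fitted to ≥ 3 non-collinear background reference
   points and divided out, preserving the mean reference intensity.
   Planar is the minimal model that captures one-sided lighting; it is
   exact for the generator's gradient and idempotent in general. The
   default reference points sit at the channel centres in the blank
   bands between zones (16 points on a 4-channel strip).
4. **Segmentation and signal** (`quantify_zone()`). An Otsu threshold is
   computed on the 256-bin histogram *of the zone box only* (a global
   threshold would be dominated by the barriers), spot = the low-green
   class, and `signal = mean(reference band) − mean(spot pixels)`, so a
   stronger spot gives a larger positive signal and any constant offset
   cancels. Ties in the between-class variance are broken towards the
   lowest level, and the signal is computed from the corrected plane
   (order configurable via `correct = FALSE`). An undeveloped (blank)
   zone raises an error by default or returns a flagged zero
   (`on_blank = "zero"`).
5. **Ratio and strip statistics**: per channel
   `ratio = test / control`; per strip the mean and sample SD over the
   four channels. The test/control ratio is the preferred response — it
   cancels batch-to-batch intensity variation — but the plain
   normalized test signal is retained (`mode = "test"` in
   `run_pipeline()`).

## Calibration, bands and detection limits

`normalize_signals()` divides by the blank mean, so the blank's
normalized mean is exactly 1. `fit_4pl()` is Levenberg–Marquardt least
squares (unweighted by default, `1/SD²` weights accepted), with the
covariance `σ̂²(JᵀJ)⁻¹` from the analytic Jacobian at the optimum.

`confidence_band()` is the delta method,
`ŷ(x) ± t₁₋α/₂(n−4) · √(g(x)ᵀ V g(x))` with `g` the parameter gradient
of the curve. The t-quantile reflects that `σ²` is estimated from few
points. A parametric bootstrap (refit Gaussian resamples of the fitted
curve, take pointwise quantiles) is provided as an independent
cross-check; the two agree to well under 10% of the band half-width on
a moderately sized calibration, and the tests assert exactly that.

`detection_limits()` encodes the band-intersection construction for a
*decreasing* curve: the critical response `y_crit` is the lower band
limit at concentration 0 (the lowest response still consistent with a
blank); MDC solves `ŷ(x) = y_crit` and RDL solves
`upper(x) = y_crit`. Because the upper band lies above the curve,
MDC ≤ RDL always. Both roots are found by bracketing bisection on the
log-concentration scale in [10⁻³, 10⁵] µg l⁻¹ to a relative tolerance of
10⁻⁶ — robust and derivative-free; a collapsed band (zero residual
variance) puts the crossing below the bracket and is reported as the
bracket floor. The defining sentence of this construction admits a
second reading in which the MDC is located on the lower band limit
itself; that variant is exposed as `rule = "lower-upper"` rather than
silently guessed.

## What the generator emulates — and what it does not

`render_strip()` draws 8-bit-range RGB rasters of a four-channel strip:
dark ablated barriers (the fiducials), circular test/control spots with
Gaussian edge softening (sub-pixel antialiasing, σ = 0.3 px — the value
at which the rendered spot reproduces its declared core mean to
< 0.2 intensity units through the full pipeline), a configurable planar
multiplicative illumination gradient, and i.i.d. additive Gaussian pixel
noise. The true response enters as green-channel depletion: the control
spot at a fixed amplitude (60 units by default; optionally mildly
increasing with concentration, as unbound conjugate accumulates on the
control line), the test spot at `control_amplitude × y(c)` with `y` the
configured 4PL. Ground truth (noise- and gradient-free zone means and
ratios) is returned with every render, which is what makes closed-loop
testing possible: at zero noise the raster pipeline returns the
configured (A1, A2, x0, p) to machine precision, and with noise the
empirical zone-mean scatter matches the closed-form `σ/√n` of a mean.

Defaults are the study conditions used throughout: calibrators 0, 1, 10,
30, 100, 300, 1000, 10 000 µg l⁻¹; triplicate strips; four channels;
true curve (1, 0.1, 50, 1.2); pixel noise SD 2 (a plausible shot/readout
level for an 8-bit consumer camera — no measured value exists for this
setup, so it is a documented choice, not an inference); signal-level
Monte-Carlo studies use σ = 0.03 on the normalized scale.

Not emulated: optics of plasmonic colour (spectra are Lorentzian
profiles by construction), DLS autocorrelation physics (distributions
are consumed, not inverted), membrane fluidics, rotation/perspective,
camera colour response, or serum-matrix effects. Passing tests therefore
demonstrate the correctness of the *evaluation chain*, not the
performance of any physical assay; real MDCs depend on chemistry and
imaging hardware that synthetic data cannot certify.

## Conjugate characterization choices

* Particle number concentration at OD 1 is a built-in nominal table
  (20 nm → 7.0·10¹¹ ml⁻¹, 40 nm → 9.0·10¹⁰ ml⁻¹), overridable per
  recipe; with it, the default recipe gives 34 antibodies per particle
  (29 at 4.2 µl, 110 at 16 µl).
* Monolayer capacity uses `floor(πd²/A)` on the bare core diameter with
  the 14.5 × 8.5 nm² IgG footprint — a fractional antibody cannot bind,
  and the hydrodynamic diameter would double-count the protein shell.
  This yields 10 (20 nm) and 40 (40 nm).
* FWHM is read off by linear interpolation between 1-nm grid points;
  layer thickness is half the hydrodynamic diameter increase; the DLS
  number mean averages only the main peak (the contiguous bin run above
  5% of the modal weight with the largest total weight), so small
  agglomerate shoulders do not bias the diameter.
* Streptavidin-mediated recipes are characterized but excluded from
  stoichiometry golden values: their printed antibody-per-particle
  figures fold in biotinylation and filtration losses that the naive
  mass balance cannot reproduce.

## Numerical and testing notes

* Monte-Carlo problem sizes: 500 calibration fits for CI coverage,
  3 batches × 8 concentrations × 4 replicates for recovery, 1000 random
  histograms for the Otsu oracle, 10⁶ grid points for the
  detection-limit oracle, 2000 bootstrap draws for the band comparison.
  The whole suite runs in well under a minute.
* The noise-ladder monotonicity study (σ ∈ {0.01, 0.02, 0.05, 0.1})
  shares one standard-normal draw across the ladder (common random
  numbers), so it compares noise levels rather than seeds.
* All generators save and restore the global RNG state and are
  bit-reproducible under a fixed seed; `run_pipeline()` derives one
  sub-seed per strip from the configuration seed and records it in the
  manifest together with per-file checksums, so a fixed configuration
  reproduces its signal tables byte for byte.
* Known limitations: translation-only registration; a single Otsu
  threshold per zone (no multi-level segmentation); unweighted fits by
  default; no 5PL or variance-function modelling; detection-limit roots
  outside [10⁻³, 10⁵] µg l⁻¹ are reported as errors ("limit beyond
  calibrated range") rather than extrapolated.
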