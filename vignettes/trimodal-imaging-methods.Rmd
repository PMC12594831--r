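---
title: "Models and methods behind the trimodal imaging pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the trimodal imaging pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripai)
```

`tripai` models the computational chain of a coaxial trimodal probe: a
transparent 64-element linear ultrasound array (300 µm pitch, 7 MHz,
45% fractional bandwidth) that passes the excitation laser through its own
aperture, with a near-infrared camera viewing the same field en face. This
vignette explains each model, the tunable parameters, the numerical
choices, and what the synthetic tests can and cannot say about real data.

## Digital phantoms

A `digital_phantom` holds per-species concentration grids (Hb, HbO2, ICG;
mol/L), an acoustic scatterer-amplitude grid, and homogeneous optical
background properties. Coordinates are x lateral (element axis, zero at
the array center), y elevational, z axial depth from the transducer face;
voxels are half-open and isotropic (default 0.1 mm, which keeps tube
boundaries within half a voxel of their analytic position).

Vessels are capsules around polyline centerlines. For blood the Hb/HbO2
split encodes the ground-truth saturation exactly
(`C_HbO2 = sO2 · C_total`), with total hemoglobin defaulting to 2.3 mmol/L
(whole blood). ICG concentration inside lymphatics is a free parameter of
the scene — intradermally injected dye is diluted by an unknown factor on
uptake — and defaults to 0.1 mmol/L, a tenth of a typical 1 mM injectate.

Speckle is the standard fully-developed model: scatterers at uniform
random sub-voxel positions (default 2 per mm³) with folded-Gaussian
amplitudes, accumulated per voxel; vessel lumina are hypoechoic (default
10% amplitude). All placement randomness flows through one seed, so a
phantom is bit-reproducible.

Arterial pulsation multiplies radius and concentration of vessels flagged
pulsatile by `1 + m·s(2π f₀ t)`. The waveform `s` is a zero-mean
raised-cosine pulse train (systole occupying 35% of the cycle) rather
than a sinusoid: a real arterial waveform is pulse-like, and its spectrum
carries the harmonic stack that the pulsation analysis should detect. The
default modulation depth 0.15 keeps the period-averaged cross-section
within 1% of the static value. Heart rates at or above half the frame rate
are rejected (Nyquist).

## Forward models

**Photoacoustics.** Initial pressure is `p₀ = Γ·µa·Φ` with the Grüneisen
factor fixed at 1 (all amplitudes are relative). `µa` comes from the
shipped extinction table: `µa = ln(10)·Σ εₙ(λ)·Cₙ / 10` (decadic ε in
cm⁻¹M⁻¹, output mm⁻¹). Only chromophores radiate; the homogeneous
background absorption attenuates fluence but is not a source, so empty
scenes produce silent channels. Each source voxel contributes to each
element a Gaussian-enveloped cosine at the center frequency — the envelope
σ chosen so the −6 dB two-sided amplitude spectral width equals the
fractional bandwidth — delayed by `r/c` and scaled by `p₀/r`. Elements
accept a hard ±45° cone, a cheap far-field directivity. Receive gains
(54 dB PA / 39 dB US) are linear bookkeeping multipliers recorded in
metadata; reconstruction divides them back out, which mirrors a real
receive chain and is covered by a gain-invariance test.

**Ultrasound.** Each of the three steered packets (0°, −10°, +10°)
transmits 64 focused line beams sweeping the aperture. A transmitted line
is modeled as a virtual source at its 20 mm focus: the transmit delay to a
scatterer is `(F + sign(u−F)·|r − r_f|)/c`, the standard virtual-source
form, and the lateral transmit profile is Gaussian with
σ = 0.45·λ·F# (≈0.10 mm). Echo amplitude carries 1/r spreading each way.
The elevational dimension is collapsed per scan slice (2.5-D), matching a
probe that acquires B-scans and steps elevationally by 0.5 mm.

**Fluorescence.** The en-face frame is a depth-weighted projection of the
ICG grid with round-trip attenuation `exp(−2·µ_eff,FL·z)`. The default
attenuation 0.52 mm⁻¹ was calibrated once against a 6 dB detection
criterion over a 10⁻³ relative camera noise floor so that tube
detectability fades between roughly 4.5 and 7.3 mm — the depth scale at
which NIR fluorescence lymphography loses contrast in tissue.

**Analytic fluence.** As a fast stand-in for Monte Carlo transport,
`fluence_analytic()` applies broad-beam diffusion decay
`Φ = exp(−µ_eff·z_eff)`, `µ_eff = sqrt(3µa(µa+µs'))` on cumulative
depth-averaged coefficients, along the incidence direction, inside the
diverging beam footprint. Values are bounded by 1 and deliberately not
rescaled per volume, so fluence maps from different beam geometries remain
comparable.

## Reconstruction

PA images use one-way delay-and-sum with linear inter-sample
interpolation. The receive aperture is dynamic with f-number 1.0 and Hann
apodization by default — the paper-silent choice a practitioner would make
for sidelobe control; a rectangular window is available for
diffraction-limit measurements, since the textbook `λ·F#` estimate assumes
a uniform aperture. Out-of-trace delays contribute zero and are counted in
provenance. Display images are analytic-signal envelopes (FFT Hilbert
pair along depth) log-compressed to 40 dB (US) or 30 dB (PA).

US packets are beamformed per transmitted line (each line supporting
±0.4 mm laterally, about the transmit beam width — wider supports blur the
two-way point-spread function) and the three steered images are compounded
coherently before envelope detection. Whether the hardware platform
compounds coherently or incoherently is not public; coherent summation is
the default because it buys lateral resolution, and `compounding =
"incoherent"` is available. With coherent three-angle compounding the
simulated two-way lateral FWHM at the 20 mm focus lands within a few
percent of `λ·F#`; the one-way PA FWHM sits ≈1.3× above the paraxial
estimate, as expected at F# ≈ 1 where the small-angle sinc formula
undershoots.

A note on one deliberate deviation: the pixel grid is 0.1 mm isotropic
over a 40 × 20 mm field of view, and the frame sequencer groups raw events
into spectral cycles (five-wavelength in-vivo style or four-wavelength
in-vitro style), asserting that each US packet trails its PA event by the
configured 100 µs.

## Fluence compensation and unmixing

Depth-dependent illumination decay is estimated per wavelength from the
image itself: the background level at each depth row is the 20th
percentile of non-object pixels, a single exponential `A·exp(−kz)` is fit
to that profile by log-linear least squares, and the image is divided by
the fitted curve normalized to one at the surface. The percentile and the
single-exponential form are documented package choices — the estimator
behind "background determined at each depth" is not specified in the
source system — and both are exposed as configuration. Rows with fewer
than 8 background pixels fall back to the global fit with a warning.

Unmixing implements the pseudo-inverse exactly:
`C = PA·Mᵀ·(M·Mᵀ)⁻¹`. Negative concentrations are retained in stored maps
as diagnostics (the problem is unconstrained least squares) and clamped
only inside the sO2 ratio and for display. The sO2 map is masked where
`m_Hb + m_HbO2` falls below 5% of the stack's 99th-percentile amplitude.

The spectral matrix `M` is normalized by a single global constant rather
than per row. This matters: rescaling each species row individually would
multiply the recovered Hb and HbO2 by different factors, biasing
`sO2 = m_HbO2/(m_HbO2+m_Hb)` and destroying the Hb/HbO2 equality at the
796 nm isosbestic point. A per-row option (`normalize = "row_max"`)
remains for shape-only uses. The shipped extinction table is a smooth
synthetic compilation anchored on standard literature values (its header
records this); it is an external constant of the analysis, not a fitted
quantity.

## Volumes and projections

Scan lanes are registered purely by stage coordinates (a motorized stage
is trusted to better than a pixel; no image registration). Overlapping
lanes are blended by linear feathering across the full overlap width, so
contributing weights sum to one everywhere — re-stitching two lanes cut
from one volume reproduces it to machine precision. Maximum amplitude
projection takes the per-column absolute maximum; depth encoding maps the
argmax depth linearly onto a blue-to-red HSV ramp (hue monotone in depth,
range 0–10 mm by default) with MAP amplitude as value — any perceptually
reasonable fixed map would do, and this one is documented in the colorbar
attribute. Overlays render US in grayscale with the PA or unmixed-species
layer alpha-blended above a threshold (ICG green, Hb red).

## Monte Carlo photon transport

`run_mc()` is a standard weighted-photon voxel code: exponential step
sampling by the local `µt`, absorption deposition `w·µa/µt` at the
interaction voxel, Henyey–Greenstein scattering, Russian roulette below
weight 10⁻⁴ with survival probability 0.1. Photons crossing any grid face
escape; refractive-index boundaries are matched by default with specular
Fresnel reflection at the top/bottom faces behind a flag. The beam is an
x-y factorizable source: uniform entry over the fiber footprint with
independent uniform divergence tilts, a 45°-inclined and 4 mm-offset
variant representing conventional oblique illumination. Fluence is
deposited weight over `µa·V·N`, i.e. per launched photon per cm².

Two accounting choices deserve note. First, the per-run energy ledger
includes the net Russian-roulette weight (killed minus boost-gained);
roulette is unbiased only in expectation, and the ledger makes
`launched = absorbed + escaped + roulette_net` exact to machine precision.
Second, the coaxial-versus-oblique comparison is made per depth *within
the combined Monte Carlo uncertainty* (3 standard errors, with per-voxel
errors estimated from interaction counts): a strict inequality between two
noisy estimates is not statistically meaningful in deep, sparsely sampled
voxels, and the strict result is reported alongside. At desk scale the
default is 10⁵ photons (seconds); the 10⁷-photon configuration is a
supported long run.

## Metrology conventions

* `k_eff = sqrt(1 − (f_r/f_a)²)` with the resonance pair located at the
  impedance-magnitude minimum/maximum and refined parabolically.
* Pulse-echo spectra use a Hann window with 4× zero padding; −6 dB edges
  are linearly interpolated; a width at the window-mainlobe scale flags
  the bandwidth as resolution-limited. SNR is peak signal over the RMS of
  a pre-echo noise window.
* Crosstalk is the band-limited RMS ratio over 1–9 MHz, reported per
  neighbor order with a −30 dB pass/fail.
* CNR uses the pooled-deviation form `|µt−µb|/sqrt(σt²+σb²)` on linear
  envelope pixels; `|µt−µb|/σb` is available behind a flag. Estimator
  definitions vary across labs, so both common forms are provided.
* Pulsation analysis detrends linearly, Hann-windows, zero-pads, takes
  the largest non-DC peak as fundamental, and reports harmonics at integer
  multiples within the spectral resolution.

## Problem sizes and limitations

The test and demonstration scenes are deliberately small: 2-D slices of
12–30 mm laterally at 0.1 mm voxels, single-frame spectral cycles, 10⁵
Monte Carlo photons, ten replicates for the sO2 recovery study. These
sizes give second-scale runtimes while leaving every estimator deep in its
asymptotic regime.

What passing tests show — and what they do not: the synthetic generator
reproduces the geometry, spectra, timing, and noise structure the analysis
chain assumes (band-limited pulses, 1/r spreading, fully developed
speckle, known chromophores, exponential fluence decay). It does not model
acoustic attenuation or dispersion, sound-speed heterogeneity, nonlinear
propagation, elevational beam thickness, camera optics, or tissue
autofluorescence. Recovery results (e.g. sO2 within a few points of truth
at 20 dB channel SNR) therefore bound what the algorithms can do under
their own assumptions; hardware measurements quoted for real systems
(resolution in the 0.3–0.7 mm range, CNR, crosstalk floors) are properties
of physical devices that a desk-scale simulation neither proves nor
disproves.
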