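# tripai

Simulation and analysis toolkit for trimodal ultrasound (US),
photoacoustic (PA), and fluorescence (FL) imaging with a coaxial probe
built around a transparent 64-element linear transducer array
(300 µm pitch, 7 MHz center frequency, 45% fractional bandwidth).

The package is aimed at imaging-methods researchers who want a desk-scale,
fully synthetic, end-to-end model of such a system: digital phantoms with
blood vessels and indocyanine-green (ICG) filled lymphatics, raw channel
data simulation, delay-and-sum reconstruction, depth-wise fluence
compensation, pseudo-inverse multispectral unmixing with oxygen-saturation
mapping, mosaic 3-D volume assembly, voxel Monte Carlo photon transport for
illumination-geometry studies, and transducer/image metrology.

## The core computations

**Spectral unmixing.** Fluence-compensated PA amplitudes at k wavelengths
are decomposed per pixel into n chromophore concentrations by unconstrained
least squares via the pseudo-inverse:

    [C1 ... Cn] = [PA1 ... PAk] · Mᵀ · (M·Mᵀ)⁻¹

where row n of M is the normalized absorption spectrum of species n (Hb,
HbO2, ICG) sampled at the acquisition wavelengths — five wavelengths
(690, 756, 796, 820, 866 nm) bracketing the 796 nm Hb/HbO2 isosbestic
point for sO2 work, or four (690, 720, 756, 796 nm) for ICG isolation.
Oxygen saturation follows as

    sO2 = m_HbO2 / (m_HbO2 + m_Hb)

with negative concentrations clamped before the ratio and a mask where the
total hemoglobin signal is insignificant.

**Beamforming.** PA images use one-way delay-and-sum (delays `r/c`, linear
inter-sample interpolation, dynamic-aperture apodization); US images use
two-way delay-and-sum over three steered line-beam packets (0°, −10°, +10°)
with coherent compounding.

**Monte Carlo fluence.** A weighted-photon voxel Monte Carlo (exponential
step sampling, Henyey–Greenstein scattering, absorption deposition,
Russian roulette) compares coaxial illumination through the transparent
array against conventional oblique illumination (45° incidence, 4 mm
offset) in a 5 × 5 × 1.5 cm tissue block at 0.05 cm voxels.

**Metrology.** Effective electromechanical coupling
`k_eff = sqrt(1 − (f_r/f_a)²)` from impedance spectra, pulse-echo center
frequency / −6 dB bandwidth / SNR, band-limited crosstalk, FWHM resolution,
CNR, pulsation spectra, and pre/post-injection fold changes.

## Worked example

Simulate the two-tube trimodal benchmark scene (one blood tube at 95% sO2
and one ICG tube, both 3 mm deep in a speckle background), reconstruct the
four-wavelength PA stack, and unmix:

```r
library(tripai)
spectra <- load_spectra()
fx <- make_fixtures("two_tube", seed = 1)
fx$phantom
#> digital_phantom: 200 x 1 x 100 voxels @ 0.1 mm; 2 vessel(s)
#>   Hb    max 0.000115 mol/L, 80 positive voxels
#>   HbO2  max 0.00218 mol/L, 80 positive voxels
#>   ICG   max 0.0001 mol/L, 80 positive voxels

grid <- image_grid(16, 6, 0.1, z0_mm = 1)
imgs <- lapply(fx$acq$wavelengths_nm, function(wl) {
  raw <- pa_channel_data(fx$phantom, NULL, fx$tx, fx$acq, wl, spectra)
  envelope_image(das_pa(raw, grid = grid))
})
stack <- fluence_compensate(spectral_stack(imgs, fx$acq$wavelengths_nm))
M <- build_M(spectra, fx$acq$wavelengths_nm)
maps <- unmix(stack, M)
icg <- maps$conc$ICG
cat(sprintf("ICG signal, ICG-tube side: %.3g | blood-tube side: %.3g\n",
            max(icg[, grid$x > 0]), max(icg[, grid$x < 0])))
#> ICG signal, ICG-tube side: 12.8 | blood-tube side: 1.99
```

The unmixed ICG channel isolates the ICG tube (6.4× the residual on the
blood-tube side). Transducer metrology and the illumination comparison run
the same way:

```r
keff <- keff_from_frequencies(6.53, 7.54)
cat(sprintf("f_r = %.2f MHz, f_a = %.2f MHz -> k_eff = %.2f\n",
            keff$f_r_mhz, keff$f_a_mhz, keff$k_eff))
#> f_r = 6.53 MHz, f_a = 7.54 MHz -> k_eff = 0.50

cmp <- compare_illumination(optical_medium(), n_photons = 1e5, seed = 1)
#> coaxial/oblique on-axis fluence ratio at ~5 mm depth: 2.1
```

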