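---
title: "Methods: visible-light PS-OCT processing and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visible-light PS-OCT processing and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visoct)
```

## The measurement being modelled

A visible-light (400--700 nm) polarization-sensitive spectral-domain OCT
system illuminates the sample with circularly polarized light and detects
the backscattered interference spectrum on two spectrometers behind a
polarizing beam splitter, one per orthogonal polarization state.  Each
A-scan is the Fourier transform of a spectral fringe pattern; the huge
fractional bandwidth is what buys an axial resolution around 1 µm in air
(0.73 µm in retinal tissue at a group index of 1.37), and the two channels
together give access to the phase retardation of the sample,
`δ = arctan(|A_V| / |A_H|)`.

`visoct` implements the full processing chain for such data — background
subtraction, inter-channel alignment, k-space resampling, multi-band
numerical dispersion compensation, Fourier reconstruction, retardation
imaging with SNR masking, spectroscopic (true-color) band reconstruction,
en-face projections and lesion height mapping — together with a forward
simulator that generates dual-channel spectral interferograms from layered
phantoms, so every stage can be tested quantitatively without instrument
data.

## The forward model

For a layer at optical path `z` with reflectivity `R`, single-pass
retardance `δ(λ)` and fast axis `θ`, the two detected spectra receive

```
I_H(k) += A · S(k) · sqrt(R · w(λ)) · v(z) · cos δ(λ) · cos(2 k z + φ_d(k))
I_V(k) += A · S(k) · sqrt(R · w(λ)) · v(z) · sin δ(λ) · cos(2 k z + φ_d(k) + π − 2θ)
```

plus a reference-arm DC term proportional to `S(k)` and seeded shot/read
noise.  Here `S(k)` is the detected source *power* spectrum (the
interferometric cross term is `2·sqrt(I_ref·I_sam) ∝ S·sqrt(R)` when both
arms carry the source spectrum), `w(λ)` interpolates the layer's chromatic
scattering weights given at 460/550/640 nm, `v(z) = exp(−2 σ_k² z²)` is the
fringe-visibility loss of a Gaussian spectrometer pixel response of
standard deviation `σ_k` in k (the origin of sensitivity roll-off), and
`φ_d(k)` is an optionally imposed per-band dispersion phase
`a2(k−k0)² + a3(k−k0)³`.  The V-channel phase offset `π − 2θ` is the
standard two-channel PS-OCT convention; axis orientation is generated but
not reconstructed.

Waveplate-like layers scale their retardance as `δ(λ) = δ_ref · λ_ref / λ`
(a pure 1/λ fold; material birefringence dispersion is neglected for lack
of data — the 1/λ fold already reproduces the measured trend direction).
Layers with `retardance_ref_nm = NA` are achromatic, which is the right
model for validation phantoms with a set retardance.  Depolarizing layers
(the RPE preset) draw an independent uniform retardance in [0°, 90°] and a
uniform axis per A-scan: melanin-granule scattering randomizes the
polarization state at speckle scale, and this minimal i.i.d. model
reproduces a broad retardation histogram in the band without modelling
individual granules.

### What the simulator does *not* emulate

No speckle from sub-resolution scatterer interference, no eye motion or
breathing artifacts, no ocular aberrations or focus effects, no absolute
photon budgets, no wavelength-dependent absorption profile beyond the
three-point chroma weights.  Tests passing on these phantoms therefore
validate the *processing chain's* correctness and calibration arithmetic —
not robustness to every property of in vivo data.

## Reconstruction

1. **Background subtraction** removes the per-B-scan mean spectrum.  This
   only works when A-scans decorrelate laterally; on a laterally uniform
   noiseless phantom the mean *is* the signal.  The simulator therefore has
   a `depth_jitter_um` parameter (per-A-scan axial jitter emulating surface
   topography/axial motion); noiseless physics tests instead reconstruct
   with `background = FALSE`.
2. **Channel alignment**: the second spectrometer cannot be aligned
   identically to the first, so channel V is resampled at the pixel
   coordinate `m·x + c` (least-squares fit from shared spectral landmarks)
   and multiplied by a smoothed envelope-ratio normalization curve.  The
   order is remap-then-normalize.
3. **k-space resampling** interpolates each spectrum from the uniform-λ
   grid onto a uniform grid in `k = 2π/λ` spanning
   `[2π/λ_max, 2π/λ_min]`.  Interpolation is cubic spline by default
   (linear selectable); cubic keeps resampling sidelobes roughly below the
   −40 dB level at which the retardation mask behaves sensibly.
4. **Transform**: the complex analytic fringe (FFT half-spectrum method) is
   multiplied by the dispersion phase `exp(i·Φ̄(k))`, Fourier transformed
   and the positive-depth half kept.  Depth sampling is `dz = π/(N·dk)`
   (optical path); division by the tissue index 1.37 happens only in the
   explicit `to_tissue()` conversion, never silently.
5. **Reflectivity** is `|A_H|² + |A_V|²`, which is invariant to retardance
   and axis for polarization-preserving layers; dB values are referenced to
   the mean noise floor estimated from the deepest 10% of z-bins.

## Dispersion compensation

The per-band phase correction polynomial is
`Φ̄(k) = a1(k−k0) − a2(k−k0)² − a3(k−k0)³`, evaluated per wavelength band,
concatenated, and smoothed with a local cubic (Savitzky–Golay, window 5% of
the grid, exact at the edges) so neither the curve nor its first derivative
jumps at the seams.  The linear `a1` term re-aligns the depth position of
each band's image, compensating the first-order dispersion the
concatenation introduces.  Band boundaries default to equal thirds of the
*k* range (equal information per band on the processing grid; λ-thirds are
selectable).

Because manual trial-and-error coefficient tuning is slow, the coefficients
can also be searched automatically: per band, a deterministic coarse grid
scan over `a2` then `a3` (41 points each, escaping the many local optima of
the objective under strong dispersion) seeds a Nelder–Mead simplex that
minimizes the Shannon entropy of the normalized band-limited reflectivity
A-scan — low entropy means energy concentrated in sharp peaks, the
automated analogue of judging image quality by eye.  Note that over a band
that does not contain `k0`, a change of `a3` is partly equivalent to a
linear phase (a depth shift), so recovered `a3` values are only defined
modulo that trade-off; `a2` is identifiable and is what the recovery tests
assert.

The multi-band test condition: real broadband systems show `a2`, `a3`
varying *continuously* with wavelength by up to an order of magnitude
across the spectrum.  The test experiment imposes a quadratic-in-k
coefficient ramp from `a2 = 3×10⁵` at band center to `3×10⁶` rad/(rad/nm)²
at the spectrum edges (and `a3 = 150·a2`), sampled as 24 narrow
constant-coefficient bands — magnitudes chosen so the uncorrected PSF is
several-fold broadened, the severity regime where correction quality
matters.  A 3-band search restores the PSF FWHM to within 5% of the
transform limit; the best single-band (one global cubic) correction cannot
and leaves it ≥ 20% broadened.

## Retardation and error propagation

`δ = arctan(|A_V|/|A_H|)` is computed from the amplitude moduli, only where
reflectivity exceeds the mean noise floor by a threshold (default 4 dB, the
midpoint of the usual 3--5 dB practice); masked pixels carry `NA` and are
rendered neutral gray in exports.  For repeated measurements at a fixed
beam position, per-depth channel means and standard deviations over the
repeats are propagated to first order:

```
σ_δ² = ((A_H σ_V)² + (A_V σ_H)²) / (A_H² + A_V²)²   (radians)
```

validated against a 10⁶-draw Monte-Carlo oracle rather than any printed
reference (the closed form is standard; at 10% channel noise the two agree
within 5%).

The QWP-1300 validation phantom folds its retardance through the detection:
`δ_meas = arctan(|sin δ|/|cos δ|)` with `δ = 90°·1300/λ`, decreasing from
67.5° at 400 nm to ≈ 12.9° at 700 nm.  The fold has singular points at
λ ≈ 433 and 650 nm (where δ crosses 270° and 180°) at which the folded
value is non-differentiable and a finite spectral window necessarily
averages asymmetrically; window centers at the extreme grid edges also lose
part of their window.  The spectral-retardation tests therefore sample
centers on the smooth, untruncated part of the range (420--620 nm), where
a Gaussian k-window recovers the fold value essentially exactly — the
retardance is *linear in k* for a 1/λ waveplate, and a symmetric window
attenuates the in-phase and quadrature components equally, cancelling the
averaging bias to all orders captured by the Gaussian approximation.

## Spectroscopic true color

Gaussian windows centered at 460/550/640 nm are applied *after* k-space
resampling, with a width solved from the coherence-length relation
`FWHM_z(air) = 4 ln 2 / Δk_FWHM` for a common tissue-resolution target
(default 4 µm × 1.37 = 5.48 µm in air), which is what makes the axial
resolution identical across bands.  Each band image is smoothed by a 3
(lateral) × 2 (axial) rectangular mean filter, histogram-matched to the
green channel (quantile mapping — "normalization by histogram shape"
preserves relative local contrast rather than absolute intensities, which
wavelength-dependent attenuation would otherwise dominate), stacked into
RGB and clipped.  No roll-off/attenuation spectral correction is applied:
dividing by a depth- and wavelength-dependent sensitivity estimate
amplifies noise precisely where the blue channel is weakest, so the
channels are simply combined.

A PSF-width convention note: throughout the package the axial PSF width is
the FWHM of the A-scan *magnitude* |A(z)| — equivalently the −6 dB width of
the dB intensity plot.  This is the convention under which the Gaussian
coherence-length relation above and the familiar
`δz = (2 ln 2/π)·λ0²/Δλ` hold exactly, and it makes the window solver,
`psf_fwhm()` and the simulator mutually consistent.  The exact oracle used
in tests computes `Δk` between the half-power *wavelengths*
(`4 ln 2 / Δk`), which the λ-domain formula approximates to first order in
`Δλ/λ0`.

## En-face projection and lesion height

En-face projections are depth means over a z range or mask.  The lesion
height map scans, per lateral position, from the given RPE top surface
upward through a `max_height_um` window (default 40 µm) and reports the
height of the shallowest pixel exceeding the noise floor by a threshold;
a small `exclude_um` guard band (default 2 µm) just above the surface keeps
the RPE's own point-spread wing from registering as supra-RPE signal.  The
threshold that localizes the lesion boundary to within one z-bin is the
half-maximum of the supra-RPE signal (peak − 3 dB); detection-style
thresholds lower down the PSF skirt bias the height high by the skirt
width.  RPE segmentation is accepted as an input (it was manual in
practice); tests derive it per A-scan as the strongest return in a window
around the RPE depth.

The `retina` phantom preset places its last outer-retina band ≈ 55 µm above
the RPE — larger than real murine anatomy — so that a lesion-free phantom
yields an identically zero height map within the default search window;
this is a deliberate phantom simplification, not an anatomical claim.

## Numerical choices and problem sizes

* Spectrometer defaults follow the modelled instrument (8192 pixels over
  400--700 nm, 512 A-scans/B-scan); most tests run on 1024--4096-pixel
  grids, which preserve every relation being tested (depth sampling
  `dz ≈ 0.47 µm` is grid-size-independent) while keeping the suite fast.
* Sub-bin PSF measurements zero-pad the spectrum (factor 4--8) before the
  FFT; without padding, scalloping of a ~2-bin-wide PSF dominates FWHM and
  peak-amplitude comparisons.
* Roll-off characterization uses the full 8192-pixel grid and the first
  700 µm of depth, where cubic-spline resampling is transparent; near the
  resampling Nyquist (fringe phase steps approaching π/pixel) interpolation
  itself attenuates, which would confound the pixel-MTF measurement.
* The k-resampling endpoints are exactly `2π/λ_max` and `2π/λ_min`;
  alignment/resampling interpolation is `stats::spline` (FMM cubic), with
  out-of-range pixels zero-filled.
* `qwp_fold` and the retardation arctangent use `atan2` on moduli, so the
  `|A_H| = 0` limit returns 90° exactly.
* All randomness (noise, depolarizing draws, jitter) flows from the single
  integer seed in `acquisition_config`; a frame is bit-reproducible given
  its config.

## Known limitations

* Axis orientation and degree-of-polarization-uniformity are generated by
  the forward model but deliberately not reconstructed.
* The entropy-based dispersion search assumes at least one dominant
  reflector; diffuse-only scenes may need the manual coefficient path.
* Histogram matching is per-B-scan; volume-consistent color normalization
  across B-scans is not implemented.
* The instrument's absolute headline figures (1.0 µm air PSF, 96 dB
  sensitivity, 14--15 dB/mm roll-off) depend on the physical source and
  detectors and are treated as hardware-dependent inputs, not simulation
  outputs; the package validates the conversion arithmetic and the
  analytic-oracle agreements instead.
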