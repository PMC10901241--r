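---
title: "Methods: simulating PA/US dual-modality imaging of marker clips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating PA/US dual-modality imaging of marker clips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausim)
```

## Scope and physical model

`pausim` is an in-silico counterpart of a handheld photoacoustic/ultrasound
(PA/US) imaging system used to localize titanium marker clips implanted in
breast tissue. It covers the computational chain only: phantom → channel
data → filtering → delay-and-sum (DAS) reconstruction → display. It is not a
full-wave acoustic simulator; the deliberate simplifications are listed at
the end.

The forward model treats every photoacoustic source as an ideal point
radiator. Element $i$ records

$$ s_i(t) \;=\; \sum_k A_k\,\Phi(z_k)\,\frac{r_\mathrm{ref}}{r_{ik}}\,
   w\!\left(t - \frac{r_{ik}}{c}\right), $$

with amplitude $A_k$ (relative initial pressure), fluence
$\Phi(z) = e^{-\mu_\mathrm{eff} z}$, spherical $1/r$ spreading, and
$r_\mathrm{ref} = 1$ cm so amplitudes stay dimensionless. Pulse-echo
ultrasound is monostatic: the same element transmits and receives, giving
round-trip delay $2 r_{ik}/c$ and two-way $1/r^2$ spreading. Both models are
exactly linear in source amplitudes, which is what lets source contrast
(e.g. the titanium:blood amplitude ratio of 1 : 0.91) survive into the
reconstructed image unchanged — the test suite asserts this to $10^{-6}$
relative.

Reconstruction is per-pixel DAS with angular apodization
$w_i = \cos^q\theta_i$ for $\theta_i \le \theta_{max}$ (defaults $q = 1$,
$\theta_{max} = 60^\circ$), linear interpolation between time samples, and
normalization by $\sum_i w_i$ per pixel. The normalization flattens
aperture-coverage falloff so the depth-amplitude trend in a reconstructed
depth series is attributable to physics ($1/r$ and fluence) rather than to
how many elements see each pixel. PA images remain bipolar end to end: no
envelope detection and no non-negativity, because the paired
positive/negative lobes are the feature that distinguishes a small metal
target from diffuse background.

## The excitation pulses

A thermoelastically generated pressure transient is bipolar with zero DC
content. We model it as the time derivative of a Gaussian-modulated cosine.
A pure first-derivative-of-Gaussian has a *fixed* fractional bandwidth
(about 1.6), so it cannot simultaneously honor a 5 MHz spectral peak and a
70% −6 dB bandwidth; the modulated form adds the one degree of freedom
needed. Its two parameters (modulation frequency, envelope width) are
calibrated once per `(fc, bw)` pair by deterministic root-finding on the
closed-form spectrum $|W(f)| \propto f\,[G(f-f_m)+G(f+f_m)]$: the peak
condition gives $f_m = f_c - \sigma_f^2/f_c$ in closed form, and a single
`uniroot` sets the −6 dB width. The US pulse is a plain Gaussian-modulated
cosine with $\sigma_f = \mathrm{bw}\cdot f_c / (2\sqrt{2\ln 2})$. The test
suite verifies both pulses' discrete spectra peak at $f_c$ within 2% with
the stated width within 5%.

## What the phantom generator emulates

* **Marker clip** (`make_marker`): a lattice of point absorbers at
  `sample_spacing` (default 0.1 mm) on the surface and axis of a
  1 mm × 3 mm cylinder, with an optional quarter-circle hook tail of radius
  0.5 mm. The three canonical orientations — in-plane parallel to the
  array, perpendicular to the imaging plane, in-plane vertical (along
  depth) — are rigid rotations of one canonical cloud, so absorber count
  and total amplitude are orientation-invariant by construction. Uniform
  amplitude along coil and hook is assumed.
* **Amplitude presets**: titanium 1.0, blood 0.91 — normalized signal
  intensities of the two materials at 1064 nm; their ratio (~1.09) is the
  contrast the pipeline must preserve.
* **US visibility of the clip** (`marker_scatterers`): the smooth metal
  surface reflects specularly, so the monostatic echo comes from surface
  patches facing the transducer. Each cylinder-surface point becomes a
  scatterer with reflectivity $\max(0, -n_z)^p$ ($p = 4$ by default). This
  is what makes the vertical clip nearly invisible in US (no upward-facing
  surface) while the parallel clip returns a bright top-surface line —
  isotropic scatterers cannot reproduce that ordering.
* **Tissue background** (`make_tissue_background`): blood vessels in
  cross-section as point absorbers with the blood preset (the "point
  features" a clip can be confused with), plus uniformly random point
  scatterers with exponential reflectivity (fully developed speckle), count
  Poisson in density × area. One integer seed governs everything.
* **Optics** (`optical_model`): 1D exponential fluence,
  $\mu_\mathrm{eff} = 0.4\ \mathrm{cm}^{-1}$ by default. A diffusion or
  Monte-Carlo solution is out of scope; only the depth trend matters for
  the depth-series phenomenology, and at 25 mm depth the model gives
  exactly $e^{-1}$.

What it does **not** emulate: acoustic heterogeneity and refraction,
reflection artifacts, frequency-dependent attenuation, element directivity
from finite aperture, shear waves in the metal, speckle decorrelation. A
passing test therefore shows the *geometry and signal chain* behave
correctly, not that real tissue clutter is matched.

## Geometry, poses, elevation

Arrays live in the imaging plane: x lateral, z depth, y elevation. The
linear array (128 elements, 0.3 mm pitch → 38.1 mm aperture, consistent
with the 40 mm illumination width; pitch is our choice, not a measured
value) sits on z = 0 aiming at +z. The arc array (55 mm radius, 178°, 128
elements) is centered on the origin with normals pointing at the center.
Poses rotate about the elevation axis and translate; the y component of a
pose translation is carried for bookkeeping but slices are positioned by
`reconstruct_volume`. Multi-angle joint reconstruction is **coherent**: the
posed element sets are concatenated and one DAS runs over the union. The
alternative (incoherent image averaging) was rejected because coherent
summation is what actually narrows the point spread — the four-view vs
one-view FWHM comparison in the tests measures exactly this.

Element elevational focusing (the acoustic lens / the arc's 50 mm focal
length) is available as an optional Gaussian sensitivity
$e^{-y^2/2\sigma_y^2}$ per traversal (`elevation_sigma`; squared for
pulse-echo). Default is `NULL` (ideal point elements). The 3D preset and
the elevational-extent test use $\sigma_y = 0.6$ mm, the focal beam waist
implied by the arc geometry; without it, unfocused point elements integrate
the entire 3 mm clip into every slice and its elevational extent cannot be
recovered.

## Noise, interference, filtering

RF pickup from the pulsed laser is *common-mode*: an identical burst on all
channels, which DAS smears into a sharp full-width band ("horizontal line")
at the depth matching the burst time. The software analogue of shielding is
across-channel mean subtraction (`suppress_common_mode`), which removes a
common-mode signal exactly and perturbs a localized source only at order
1/(element count). Electronic noise is i.i.d. Gaussian per sample, seeded.
High-pass filtering is a 4th-order Butterworth applied forward-backward
(zero phase, so arrival times do not shift), default cutoff 0.5 MHz — the
filter family and cutoff are our choices. Records are padded by odd
reflection before `filtfilt` so edge transients decay outside the data.

## Numerical choices and degenerate inputs

* Time sampling 40 MHz, 2048 samples by default (covers ~38 mm one-way at
  1500 m/s); the sampling rate must exceed twice the array's upper band
  edge or simulation refuses.
* DAS interpolation is linear in time; delays outside the record contribute
  zero, and a pixel geometrically covered but temporally unreachable
  triggers a coverage warning and stays 0. Pixels with zero total weight
  are 0.
* `locate_peak` works on $|I|$ with a deterministic tie-break (smallest z,
  then smallest x) and 3-point parabolic sub-pixel refinement clamped to
  half a pixel; `feature_extent` takes the 4-connected component of the
  half-maximum mask containing the peak; `lateral_fwhm` interpolates the
  half-maximum crossings of the contiguous run through the peak.
* B-mode: per-column analytic-signal envelope (FFT construction), log
  compression over a 40 dB dynamic range, clipped to [0, 1]. Because each
  B-mode normalizes to a maximum, cross-image brightness comparisons use a
  shared reference (`ref_max`, via `us_envelope_max`).
* PA display normalization uses the 99.9th percentile of $|I|$ (robust to
  single-pixel outliers); an all-zero image renders uniform mid-gray.
* Containers are self-describing text (JSON header at 17 significant
  digits + TSV samples at `%.17g`), which round-trips IEEE doubles
  losslessly; this is asserted bitwise in the tests.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path while staying fast: 128-element arrays with
1024–4096 samples; grids from 100 × 100 (vectorized-vs-naive DAS
equivalence, checked to $10^{-6}$ relative) up to ~200 × 150 pixels at
0.1–0.2 mm spacing for the depth and orientation studies; marker clouds at
0.15 mm spacing (~500 points); four arc views for the multi-angle
comparison; 11 slices for the elevational extent check. All stochastic
steps take a single integer seed.

## Known limitations

Point-element arrays have no directivity, so off-axis sensitivity is
optimistic; the specular US model has a single tunable exponent rather than
measured directivity; fluence is 1D, so lateral illumination structure is
absent; and because no reflection or clutter artifacts are simulated, the
orientation/visibility results are orderings under clean conditions, not
detection-rate predictions for clinical data.
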