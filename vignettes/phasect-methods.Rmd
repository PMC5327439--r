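---
title: "Models and methods behind phasect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phasect)
```

phasect implements a complete desk-scale analysis chain for
propagation-based (near-field) x-ray phase-contrast tomography of weakly
absorbing specimens, of the kind produced by laboratory microfocus setups
imaging dried, unstained brain tissue. This vignette explains the physical
model each stage assumes, the parameters that matter, the numerical
choices, and what the synthetic studies do and do not demonstrate.

## Image formation model

The specimen is described by its complex refractive index
$n(\mathbf r) = 1 - \delta(\mathbf r) + i\beta(\mathbf r)$: the decrement
$\delta$ drives the phase shift, $\beta$ the attenuation. For hard x-rays
and soft tissue $\delta/\beta$ is of order $10^2$--$10^3$, which is the
entire motivation for phase contrast: the bundled phantoms use
$\delta/\beta = 50$ (dried protein matrix in air at 9.25 keV, the Ga
K$\alpha$ line of a liquid-metal-jet source).

`forward_project()` applies the projection approximation: along parallel
rays through the rotated volume,
$\phi = -k\int\delta\,ds$ and $\ln A = -k\int\beta\,ds$, with
$k = 2\pi/\lambda$. Cone-beam and "inverse" (source-far, detector-near)
geometries are reduced to this parallel model by Fresnel scaling:
projection at the magnified effective pixel
$p = p_\mathrm{det}/M$, $M = (z_1+z_2)/z_1$, followed by free-space
propagation over the effective distance $z_\mathrm{eff} = z_1 z_2/(z_1+z_2)$
— the same equivalence that single-distance phase retrieval itself relies
on. Exact divergent-ray tracing is out of scope.

`fresnel_propagate()` applies the paraxial angular-spectrum propagator
$H(k_\perp) = \exp(-i\,z_\mathrm{eff}|k_\perp|^2/2k)$ to the exit wave
$\psi = e^{\ln A + i\phi}$ and returns $|\psi_z|^2$. The propagator is
unitary, so pure phase objects conserve intensity; the near-field
signature is the familiar over/undershoot fringe at every edge.
`simulate_scan()` warns when the first Fresnel zone
$\sqrt{\lambda z_\mathrm{eff}}$ exceeds 5 effective pixels, where the
single-distance (transport-of-intensity) description the retrieval assumes
starts to erode.

`corrupt()` models the detector: Gaussian penumbra blur of FWHM
$s\,z_2/z_1$ for a source spot of FWHM $s$ (the reason the laboratory
"inverse geometry" keeps $z_2 \ll z_1$), per-detector-column multiplicative
gain errors drawn once per scan (2% by default — the mechanism that
produces sinogram stripes and reconstruction rings), an additive dark
level (1% of the flat level), and Poisson counting noise. Twenty flats and
twenty darks accompany every scan. All randomness flows from one integer
seed; identical seeds give bit-identical scans.

## Phase retrieval: MBA and BAC

In the near field the measured, flat-corrected intensity of a weak object
obeys the linearized transport-of-intensity relation: contrast is the sum
of absorption and a term proportional to the Laplacian of the phase. The
Modified Bronnikov Algorithm (`mba()`) inverts this with a regularised
Fourier filter applied to $g = 1 - I$:

$$\tilde\varphi = \mathcal F^{-1}\!\left[\frac{\mathcal F[1-I]}
{|\kappa|^2 + \alpha}\right],$$

where $\kappa$ is the Nyquist-normalised frequency (Nyquist $= 1$), so
$\alpha$ is resolution-independent. All physical prefactors
($k$, $z_\mathrm{eff}$, $2\pi$ conventions) are absorbed into the scale of
$\tilde\varphi$; with this convention $\tilde\varphi$ is a positive
"projected density" (an intensity deficit maps to positive phase), and the
near-field intensity reads $I = I_0(1 + \nabla^2\tilde\varphi_s)$. The
Bronnikov-Aided Correction (`bac()`) therefore divides by
$(1 + \gamma\nabla^2\tilde\varphi)$; texts that define the optical phase
with the opposite sign write the same correction with a minus sign. The
DC mode is zeroed rather than inverted, and the denominator is clamped at
0.05 with the clamp count reported, never silently.

### The matched regularization

For a homogeneous specimen (one $\delta/\beta$ everywhere) absorption and
phase contrast are proportional, and a short calculation gives a matched
value

$$\alpha^\* = \frac{2k}{z_\mathrm{eff}\,(\pi/p)^2}\cdot
\frac{\beta}{\delta},$$

at which MBA followed by BAC at $\gamma = 1$ recovers the pure absorption
image exactly in the weak-contrast limit — this is the precise sense in
which the regularizer is "absorption-dependent". `mba_alpha()` computes it
and `retrieve_stack()` uses it as the default ($\delta/\beta = 50$). On
simulation this raises end-to-end voxel correlation with ground truth from
roughly 0.6 (generic small $\alpha$ with a tuned $\gamma$) to 0.97--0.99.
When $\alpha$ is not matched, $\gamma$ partially compensates;
`tune_bac_gamma()` grid-searches $\gamma$ on a simulated edge, scoring
overshoot while guarding the flat-region coefficient of variation. The
defaults are the package's own calibration on simulation; they are not
claims about any particular instrument's settings.

Mirror (reflective) padding of 25% per side precedes every Fourier
operation and is cropped afterwards; mirror rather than constant padding
avoids step artifacts at frame borders. On periodic test patterns padding
can be disabled, where the single-mode transfer of `mba()` is exact to
$10^{-10}$.

## Ring removal

Column gain errors are constant across angles, so after the logarithm they
are additive vertical stripes in the (angle $\times$ channel) sinogram.

`ring_remove_wavelet()` decomposes the channel axis with a periodized
orthonormal Daubechies-4 transform (implemented in-package), Fourier
transforms each detail band along the angle axis, damps low angular
frequencies with the complementary Gaussian weight
$1 - e^{-f^2/2\sigma^2}$ ($\sigma = 2$ bins), and inverts. Depth trades
stripe capture against object damage: every detail band loses its
near-angle-constant content, and in deep (coarse) bands that includes real
circularly-symmetric structure. The default depth
$\lfloor\log_2 n_\mathrm{ch}\rfloor - 5$ keeps the distortion of
stripe-free sinograms near 1% RMS while removing $\gtrsim 85\%$ of white
(per-column independent) stripe profiles; this is intrinsically a
compromise — no sinogram filter can distinguish a true ring from a
circularly symmetric feature centred on the rotation axis.

`ring_remove_simple()` subtracts the detrended angle-mean profile. The
trend is estimated with a quadratic Savitzky–Golay smoother (default
window 51 channels) rather than a moving average: the quadratic fit
follows the curvature of genuine object structure exactly, so the window
can be wide (strong stripe removal, measured $\gtrsim 95\%$ for constant
per-channel offsets) with $\approx 1.5\%$ RMS object distortion. It is
much faster than the wavelet filter and is the right tool for strictly
angle-constant stripes.

## Reconstruction

`fbp_parallel()` implements standard filtered back-projection: Ram-Lak
filtering on rows zero-padded to at least twice the channel count, then
linear-interpolation back-projection with $\pi/n_\mathrm{angles}$
weighting. The ramp's frequency response is built from its exact
band-limited spatial kernel ($1/4$ at lag 0, $-1/(\pi n)^2$ at odd lags);
sampling $|f|$ directly would bias the DC term and leave a constant offset
outside objects. Pixels outside the inscribed circle of the field of view
are zeroed (they lie outside the measured region). Angles are
counter-clockwise with the beam along $+x$ at $0°$; the rotation center
defaults to the fractional channel $(n_\mathrm{ch}-1)/2$ and fractional
centers are supported. An independent brute-force back-projector
(`backproject_bruteforce()`) serves as a cross-check oracle in the tests;
on analytic disk sinograms (exact ellipse chord lengths, no grid sampling
— `analytic_sinogram()`) the interior of a reconstructed disk is correct
to $\ll 1\%$.

`fdk_cone()` is a voxel-driven Feldkamp reconstruction for circular
cone-beam scans: cosine (source-distance) weighting on the virtual
detector through the rotation axis, row-wise ramp filtering, and weighted
back-projection along the diverging rays with bilinear detector sampling.
No short-scan weighting is applied; a full 360° arc is assumed for cone
data. In the small-cone limit it agrees with parallel FBP to well under
2% RMS.

Region-of-interest (local) tomography truncates projections and produces
a cupping bias after ramp filtering; `pad_roi()` extends each row with its
own edge value (default pad: half the detector width) and the
reconstruction is cropped back. The ramp kernel's spatial reach is fixed
at the unpadded row width so that padding complete (untruncated) data is
a no-op to machine precision, while cupping on truly truncated data drops
by well over half. `bin2()` provides the factor-2 projection resampling
used before reconstruction for noisy data; binning happens after phase
retrieval and before reconstruction (a configuration switch allows
pre-retrieval binning for experimentation). `reconstruct_scan()`
orchestrates bin → sinogram assembly → ring removal → FBP/FDK with full
provenance; inverse-geometry scans ($M \approx 1.1$) are reconstructed
quasi-parallel at the effective pixel.

## Virtual histology

The reconstructed contrast is an effective quantity (absorption plus
residual phase mixture, arbitrary units). `n_slices_for_thickness()`
converts a physical section thickness to a slice count (largest $n$ with
$n \cdot \mathrm{voxel} \le$ thickness; 30 µm at 0.95 µm voxels → 31
slices). `slab()` produces single slices or max/min/mean projections over
consecutive planes — MIPs emulate thick stained sections for
cytoarchitecture, MinIPs highlight low-density structures such as vessel
lumina; oblique planes are resampled trilinearly with nearest-edge
clamping at the boundary. `render_hne()` applies a monotone
white–pink–magenta ramp (denser = darker) with 1–99 percentile contrast;
it is cosmetic and excluded from anything quantitative.

`threshold_label()` is the scriptable counterpart of an interactive
threshold brush: a gray range restricted to an explicit seed-mask volume,
26-connected components (6 available), components below 27 voxels
(≈ a 1.5 µm-radius sphere at 1 µm voxels) discarded with a reported count.
Labels are ordered deterministically by first voxel index.
`cell_statistics()` yields centroids in µm, equivalent-sphere diameters
and per-layer counts against a layer mask.

## The synthetic studies: what they show and what they do not

`build_phantom()` generates voxelized $\delta/\beta$ maps with exact
bookkeeping of every placed object: `cortex_layers` (a tissue cylinder
with banded densities of non-touching 5–10 µm spherical "cells"),
`vessel_tree` (air-lumen tubes), `fiber_bundle` (aligned cylinders),
`disk_stack` (analytic-oracle-friendly ellipsoids) and `slab` (a single
straight edge). Defaults: 0.95 µm voxels, cell $\delta = 2\times10^{-6}$,
background $5\times10^{-7}$, $\delta/\beta = 50$.

`cortex_recovery_study()` is the package's reference end-to-end
experiment: a 128³ cortex phantom, inverse geometry ($z_1 = 200$ mm,
$z_2 = 20$ mm, 10 µm source, detector pixel $0.95 M$ µm), 200 projections
over 180°. Problem sizes are chosen so the full study runs in minutes on
one CPU; the paper-scale equivalent (thousands of projections,
$2000^2$ detectors) is a straightforward scale-up of the same code paths.
Noise-free, the reconstructed volume correlates with the ground-truth
attenuation map at $r > 0.95$ after the standard factor-2 resampling;
with Poisson noise at $10^4$ flat counts and 2% column gains, threshold
segmentation recovers the true cell count to within 10% with matched
detections verified against generator truth.

The simulator reproduces the *mechanisms* the pipeline must undo — edge
enhancement, penumbra blur, shot noise, gain stripes, truncation — but
not everything about real data: no polychromatic spectrum (one effective
energy), no scatter, no detector point-spread beyond a Gaussian, no
specimen motion or drift, phantoms far simpler than tissue. Passing tests
therefore demonstrate algorithmic correctness and calibrated behaviour
under the stated model, not instrument-level validation.

## Numerical conventions and degenerate inputs

* Volumes are indexed (z, y, x); slices are (y, x); the rotation axis is
  the central image column.
* Frequency grids use the half-sample (Nyquist) convention of the DFT;
  $\kappa = 1$ at Nyquist.
* Normalization clamps at $10^{-6}$, the BAC denominator at 0.05; both
  are counted in QC output.
* Empty phantoms, all-zero sinograms, gamma = 0, pad width 0 and empty
  segmentation results all degrade to exact no-ops or empty tables, and
  are tested as such.
* 32-bit TIFF samples are integer-quantized by the TIFF library; count
  data are stored one-count-per-step (exact round trip), other data with
  ~2×10⁻¹⁰ relative quantization. Determinism of a full pipeline run is
  checksum-tested.
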