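# phasect

Propagation-based x-ray phase-contrast tomography for weakly absorbing
specimens, as an R package: simulate laboratory scans of brain-like
phantoms, retrieve per-projection contrast with the Modified Bronnikov
Algorithm (MBA) and the Bronnikov Aided Correction (BAC), reconstruct
volumes with ring-corrected filtered back-projection (parallel Ram-Lak
FBP and Feldkamp FDK), and produce virtual-histology sections with
threshold-based single-cell segmentation.

## The problem

Soft, unstained tissue barely absorbs hard x-rays, but its refractive
decrement δ (in n = 1 − δ + iβ) is orders of magnitude larger than the
extinction β. A point-like microfocus source and free-space propagation
behind the specimen convert phase gradients into measurable near-field
edge enhancement, described by the linearized transport-of-intensity
relation. Dried tissue measured in air in an "inverse" geometry
(source-to-sample distance z₁ ≫ sample-to-detector distance z₂, which
minimizes penumbra blur s·z₂/z₁) gives cell-scale contrast without any
staining — virtual histology from a tabletop instrument.

The per-projection processing chain is

1. empty-beam normalization: I = (raw − dark)/(flat − dark);
2. MBA phase retrieval: φ̃ = F⁻¹[ F(1 − I) / (|κ|² + α) ], with κ the
   Nyquist-normalised spatial frequency and α the absorption-dependent
   regularizer;
3. BAC: I₀ = I / (1 + γ ∇²φ̃), which removes the edge fringes while the
   Laplacian filter simultaneously averages noise;

followed by sinogram-domain ring removal (wavelet-FFT or fast angle-mean
subtraction), Ram-Lak FBP (or FDK for cone-beam scans), optional
region-of-interest edge-padding and factor-2 binning, and
virtual-histology products (MIP/MinIP slabs, H&E-like rendering,
threshold segmentation with 3D cell statistics).

A result derived and used throughout: for a homogeneous specimen the
matched regularizer α\* = (2k / (z_eff·(π/p)²)) · (β/δ) makes MBA + BAC
at γ = 1 recover the pure absorption image in the weak-contrast limit
(`mba_alpha()`); z_eff = z₁z₂/(z₁+z₂) is the effective propagation
distance and p the effective pixel.

## Worked example

```r
library(phasect)

# a 64^3 cortex-like phantom: banded layers of 5-10 um "cells"
ph <- build_phantom("cortex_layers", size = 64, n_cells = 20, seed = 5,
                    voxel_size_um = 0.95)

# laboratory inverse geometry, 9.25 keV, effective pixel 0.95 um
g <- acquisition_geometry("inverse", z1 = 200, z2 = 20,
                          detector_pixel_um = 0.95 * 1.1,
                          source_fwhm_um = 10)
g
#> <phasect_geometry> mode=inverse  E=9.25 keV  lambda=0.000134 um
#>   z1=200 mm  z2=20 mm  M=1.1  z_eff=18.18 mm
#>   detector pixel=1.045 um  effective pixel=0.95 um  penumbra FWHM=1 um

scan <- simulate_scan(ph, g, n_angles = 120, arc = 180,
                      photon_count = 1e4, ring_sigma = 0.02, seed = 5)
ctr  <- retrieve_stack(scan)          # matched alpha, gamma = 1
ctr$alpha
#> [1] 0.009430298

vol <- reconstruct_scan(ctr, ring = "wavelet", bin = 1)
cor(as.vector(vol$values), as.vector(2 * g$k_um * ph$beta))
#> [1] 0.9721889

# threshold "brush" at the midpoint of cell/background attenuation
mu_cell <- 2 * g$k_um * 2e-6 / 50; mu_bg <- 2 * g$k_um * 5e-7 / 50
cells <- threshold_label(vol, c((mu_cell + mu_bg) / 2, Inf), min_voxels = 27)
cells
#> <phasect_labels> 20 cells (0 small components discarded)

# a 30 um-thick virtual section (31 slices at 0.95 um) as a MIP
n <- n_slices_for_thickness(30, vol$voxel_size_um)   # 31
sec <- slab(vol, "axial", start = 17, n_slices = n, mode = "max")
rgb <- render_hne(sec)                               # H&E-like 8-bit image
```

The correlation of 0.97 is against the phantom's ground-truth attenuation
map 2kβ; the 20 recovered components match the 20 generated cells. With
`ring = "none"` the same scan reconstructs with visible concentric rings
(the simulated 2% per-column gain errors).

A thin CLI wrapping these functions ships in `inst/exec/phasect`
(subcommands `simulate`, `retrieve`, `reconstruct`, `run`, `segment`,
`render`).

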