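# mesokit

Analysis toolkit for mesoscale two-photon microscopy of the mouse cortex.

Modern mesoscope designs image an ~8 mm diameter field of view (FOV) at
cellular resolution, deep enough to follow vasculature, dendrites and
calcium activity across many cortical regions at once. `mesokit`
implements the downstream quantitative analyses such experiments need, as
a tested, reusable R package exercised end-to-end on synthetic data with
known ground truth:

* **Vascular morphometry** — preprocessing, threshold segmentation, 3D
  topological skeletonization, and the four standard centerline metrics:
  per-segment diameter `D = 2 · median(r_j)` (with `r_j` the anisotropic
  Euclidean distance from centerline point `v_j` to the nearest background
  voxel), length `L = Σᵢ ‖pᵢ₊₁ − pᵢ‖`, inter-vessel distance
  `IVD = min` over midpoint-to-midpoint Euclidean distances, and volume
  density `ρ = V_v / V_ROI`.
* **Calcium trace analysis** — ROI averaging, neuropil subtraction
  (`f − c·f_neuropil`), ΔF/F with a 15th-percentile baseline
  (`ΔF/F = (f − f₀)/f₀`), a declared transient-based SNR, and pairwise
  Pearson correlation structure.
* **Locomotion-resolved functional connectivity** — stationary/moving
  state classification from treadmill speed, connectivity graphs with
  edges at Pearson `r > 0.3` split into intra-/inter-region counts, and
  per-node degree, clustering coefficient and strength at `r > 0.1`.
* **Sensorless adaptive optics (simulation)** — Noll-indexed,
  RMS-normalized Zernike pupil phases, a scalar Fourier-optics two-photon
  PSF, and modal optimization using mean image intensity as the feedback
  metric (21 steps × 5 cycles per mode).
* **Resolution characterization** — Gaussian FWHM fitting of bead
  z-stacks (`FWHM = 2√(2 ln 2)·σ`), the ring-sampling FOV layout
  (radii 1.33 / 2.66 / 3.99 mm, 45° spacing), and analytic system
  geometry (FOV area, imaged volume, spatial bandwidth product).
* **Synthetic data generators** — tube phantoms with exact centerline and
  radius ground truth, calcium scenes with region-structured latent
  coupling and a locomotion-gated shared gain, Gaussian bead stacks with
  closed-form observed widths, and textured "pollen-like" AO samples.

## Worked example

Quantify a synthetic vascular stack:

```r
library(mesokit)

spec <- phantom_spec(shape_voxels = c(21, 21, 120), spacing_um = c(1, 1, 1),
                     segments = list(list(start = c(10, 10, -10),
                                          end = c(10, 10, 1e4),
                                          radius_um = 5)),
                     noise_sd = 0, psf_sigma_um = c(0, 0, 0))
ph   <- generate_vascular_phantom(spec, seed = 1)
mask <- vessel_mask(ph$truth$mask, spacing_um = c(1, 1, 1))
cl   <- extract_centerlines(mask)

segment_diameter(cl, 1)
#> [1] 10.19804
as.numeric(segment_length(cl, 1))
#> [1] 116.7863
vascular_density(mask, array(TRUE, dim(ph$truth$mask)))$density
#> [1] 0.1836735
```

The tube's true diameter is 10 µm; the recovered 10.198 µm reflects the
half-voxel bias of measuring the distance to the nearest *background
voxel centre*. The axis spans 119 µm of grid; the skeleton stops ~1
voxel short of each cut face. The density compares with the analytic
cross-section fraction π·25/441 ≈ 0.178 (3 % discretization excess).

Analytic system geometry for an 8 mm FOV at 0.9 mm depth and 1 µm
lateral resolution:

```r
geo <- system_geometry(8, 0.9, 1.0)
geo$rounded
#> $area_mm2   50.27
#> $volume_mm3 45.24
#> $sbp        5.03e+07
```

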