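---
title: "Methods: models, parameters and design choices in mesokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mesokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mesokit` quantifies mesoscale two-photon experiments along four analysis
paths — vascular morphometry, calcium functional connectivity, sensorless
adaptive optics, and PSF resolution — each validated against synthetic data
with known ground truth. This vignette documents the models behind each
path, the tunable parameters and their defaults, the numerical choices,
and what the synthetic generators do and do not emulate.

## Conventions

All volumes are `(z, y, x)` arrays with anisotropic voxel spacing in
microns; voxel indices are 0-based in physical terms, so voxel `[i, j, k]`
(1-based in R) is centred at `((i−1)·dz, (j−1)·dy, (k−1)·dx)` µm. Distances
and radii are always physical (µm), never voxel counts: at a typical 10 µm
z-step against ~1.7 µm lateral pitch, voxel-based distances would be badly
biased, so the Euclidean distance transform is anisotropy-aware.

## Vascular morphometry

**Pipeline.** Per-slice adaptive histogram equalization (`EBImage::clahe`),
min–max normalization (a constant stack maps to all zeros), Gaussian
denoising, and per-slice rigid translation registration to the middle
slice via phase correlation, each independently switchable. Crosstalk and
dura removal are documented no-ops in single-channel data. Segmentation is
classical global thresholding (Otsu or fixed) with small-object removal —
sufficient for phantoms whose intensities are separable by construction;
CNN segmentation of in vivo stacks is out of scope.

**Skeletonization.** The mask is thinned to a curve skeleton by
distance-ordered homotopic thinning: border voxels are deleted in
increasing order of their EDT value, one at a time, only while
topologically *simple* (deletion preserves both the 26-connectivity of the
foreground and the 6-connectivity of the background in the 3×3×3
neighbourhood) and not a curve endpoint (≤ 1 remaining neighbour). EDT
ordering keeps the skeleton medial; endpoint preservation keeps the
centerline spanning the vessel.

**Metrics.** The skeleton is decomposed at branch voxels (≥ 3 skeleton
neighbours); branch voxels are appended to adjacent segments for geometric
continuity but carry no radius, so junction bulges cannot inflate
diameters. Per-point radii are EDT values at centerline voxels — the
distance to the nearest *background voxel centre*, which overestimates the
true radius by up to half a voxel (visible as D ≈ 10.2 µm for a 10 µm
tube at 1 µm pitch). Diameter is twice the median radius; length sums
consecutive point distances; density is the exact voxel-count volume
fraction. Segment coordinates are smoothed with a 5-point moving average
(endpoints fixed) before length measurement: raw voxel paths overestimate
oblique and curved arc lengths by 10–15 % (staircase effect); with
smoothing a helical tube reproduces its closed-form arc length within
~1.5 %. Segments shorter than 3 interior voxels are dropped as thinning
spurs (configurable; never leaves an empty graph).

**Inter-vessel distance.** The printed formula takes a minimum over an
index whose range is ambiguous between "all centerline points of other
vessels" and "the midpoints of the two closest vessels". The implemented
contract is midpoint-to-midpoint (the midpoint is the centerline point at
half arc length); `mode = "pointwise"` provides the alternative, which can
only produce smaller values.

**Boxplot conventions.** Regional summaries use the exclusive-median
quartile convention (R `quantile` type 6; `[1,2,3,4,5]` gives Q1 = 1.5,
Q3 = 4.5) and 1.5×IQR whiskers at the most extreme observation inside the
fence. Quartile conventions differ between tools; this one is declared
here and asserted by tests.

## Calcium analysis

ΔF/F uses `f₀` = the 15th percentile of each neuron's full recording,
computed with linear interpolation between order statistics; ΔF/F is
invariant to any positive gain applied to the raw fluorescence, and a
non-positive baseline (a symptom of neuropil over-subtraction) is an
error, not a silent NaN. Neuropil subtraction is `f − c·f_neuropil` with
`c = 0.7` by default; if the correction drives a trace non-positive, a
constant offset restores positivity and is recorded, since ΔF/F needs
`f₀ > 0`.

No standard SNR definition exists for calcium transients, so the module
declares one: transients are excursions above `median + 3·MAD` lasting
≥ 2 frames; SNR = mean transient peak amplitude (above the median) divided
by the SD of the trace with transient frames removed. Both `k` and the
duration are configurable. Published in vivo SNR values depend on this
unstated choice and are therefore generator settings here, never
verification targets.

Zero-variance traces are excluded (NA rows) from correlation matrices
rather than assigned r = 0, which would bias graph metrics toward
spurious isolation.

## Functional connectivity

Locomotion states: speeds are boxcar-smoothed (0.5 s), thresholded at
10 mm/s, and bouts shorter than 0.5 s are merged into the surrounding
state. The threshold and smoothing are package defaults chosen to
separate a ~1 mm/s stationary regime from a ~70–90 mm/s moving regime;
they are configuration, not measured constants, and reported state
fractions are data-dependent.

Connectivity edges use strict `r > 0.3` on signed correlations (an
absolute-value mode exists behind a flag); per-node metrics binarize at
`r > 0.1` for degree and unweighted triangle-ratio clustering, while
strength sums suprathreshold weights. Graph metrics are computed with
`igraph` and cross-checked in tests against a brute-force triangle
enumeration oracle. State comparisons compute correlations separately on
stationary and moving frames with identical thresholds; both states must
contribute ≥ 30 frames. Note a finite-sample property the tests account
for: with fewer frames the correlation estimate is wider, so the shorter
state shows more suprathreshold edges even without any true state effect —
null comparisons must equalize frame counts.

## Sensorless adaptive optics simulation

**Forward model.** Scalar 2D Fourier optics: the focal one-photon
intensity is `PSF₁ₚ = |FFT(A·e^{iφ})|²` on a ≥ 2× zero-padded pupil,
normalized to unit total energy. Two-photon excitation is the *square* of
the focal photon density, so the imaging kernel is `PSF₁ₚ²` **without**
renormalization: its total, `Σ PSF₁ₚ²`, is the two-photon excitation
efficiency, and it falls as aberration spreads the focus. This is what
makes mean image intensity a usable feedback metric — a unit-sum kernel
would leave the image mean exactly invariant under any aberration. A
unit-sum-normalized two-photon PSF is also returned for shape metrics
(FWHM, Strehl). The model omits 3D/vectorial diffraction and tissue
scattering; it exists to exercise the optimization logic.

**Zernike basis.** Noll indexing from index 2 (piston excluded),
RMS-normalized so a unit coefficient is 1 rad RMS of pupil phase;
orthonormality holds to < 1 % on a 512² grid. Grids too coarse to resolve
the highest requested order (< 4 px per fringe at the pupil edge) are
rejected.

**Optimization.** Modes are scanned sequentially over 21 evenly spaced
corrections spanning ±1.5 rad (odd step count, so 0 is always tested); the
tested coefficient with the peak metric is selected and incorporated into
subsequent scans. Tip and tilt are excluded from the default scan: they
only translate the image, the intensity metric is exactly flat in them,
and scanning them under noise would select an arbitrary shift. On flat or
tied metric curves the smallest |correction| wins.

The five `cycles` can be spent as repeated per-mode scans whose metric
curves are averaged (`strategy = "average"`, pure noise mitigation) or as
five full passes over all modes (`strategy = "sweep"`, the default). The
sweep is the default because of a real property of sharpness-type metrics:
at ~1 rad RMS total aberration the conditional metric peak for one mode is
displaced by several scan steps while other modes remain uncorrected, so a
single pass leaves 30–50 % residual regardless of noise; repeated sweeps
are coordinate ascent and converge to the quantization floor (half a scan
step per mode). Both strategies cost exactly
`n_modes × steps × cycles` coefficient transitions (200 × 21 × 5 = 21,000
at the full configuration; desk-scale tests use 10–12 modes on a 64² pupil
with a 128² sample).

**Noise.** Poisson photon noise at a configurable budget plus Gaussian
read noise. The standard noisy-recovery condition sets the budget so the
brightest pixel of the unaberrated image collects ~400 expected photons
(peak SNR ≈ 20).

## Resolution characterization

Bead stacks are fit per axis with `A·exp(−(x−µ)²/2σ²) + offset` by
Levenberg–Marquardt (`minpack.lm`), `FWHM = 2√(2 ln 2)·σ`; a constant
offset term is included (whether reference instruments fit one is usually
unstated — declared here). Fits report R² and fail below 0.5. Peaks are
refined to sub-voxel positions by per-axis quadratic interpolation before
profiles are taken, avoiding the half-voxel bias that a brightest-voxel
profile would suffer at 10:1 axial anisotropy. Beads within 3 fitted FWHM
of the stack border are excluded from summaries; detection requires maxima
prominent above 5 MAD of the stack. Axis profiles assume no second bead
lies on the same axis line through a peak — generic (jittered) bead fields
satisfy this; regular grids need an explicit profile halfwidth.

The FOV sampling layout is the field centre plus three rings (1.33, 2.66,
3.99 mm) sampled every 45°, 25 positions. System geometry is analytic:
`area = π(d/2)²`, `volume = area × depth`,
`SBP = area[µm²] / resolution²`.

## Synthetic generators: what they emulate, and what they don't

Every generator is a pure function of its specification and a seed
(bit-identical regeneration), and always emits ground truth alongside the
data.

*Vascular phantoms* rasterize tubes by the voxel-centre-in-cylinder rule,
apply a small Gaussian optical blur and additive noise. The rasterized
volume converges to the analytic cylinder volume as spacing shrinks
(tests assert the error drops under 2× refinement). Tubes thinner than
half the largest voxel spacing are flagged unresolvable. No scattering,
depth-dependent SNR decay, or vessel pulsation.

*Calcium scenes* draw spikes from inhomogeneous Poisson processes whose
rates mix a global drive, a region-shared drive and a private drive with
weights `√c_inter`, `√(c_intra − c_inter)`, `√(1 − c_intra)`, so latent
correlations are `c_intra` within and `c_inter` across regions; shared
drives are multiplied by `moving_gain` during moving epochs of a two-state
semi-Markov locomotion trace (stationary ≈ 1.2 mm/s, moving ≈ 70–90 mm/s,
default 30 % moving). Spikes are convolved with a difference-of-
exponentials indicator kernel — GCaMP6s rise 0.18 s / decay 1.5 s, GCaMP6f
0.08 s / 0.4 s, standard literature kinetics, configurable; neither the
kinetics nor the neuropil coefficient (0.7) are measured values, they are
declared defaults. Neuropil is a low-pass-filtered population average
scaled into each trace. Spatial structure is regional clustering
(σ = 150 µm around centres ≥ 1 mm apart), which yields the
high-correlation-within-300 µm contrast as a regional effect; there is no
within-region continuous distance dependence. Movies are rendered at pixel
level only for small scenes (disk ROIs over a neuropil background); large
populations are analysed at trace level with the identical model. Passing
tests therefore demonstrate correctness of the analysis chain on data with
this structure — not robustness to motion artefacts, photobleaching, or
overlapping ROIs, which the generator does not emulate.

*Bead stacks* are Gaussian blobs, so the imaged width obeys the exact
quadrature `FWHM_obs = √(FWHM_PSF² + FWHM_bead²)` and recovery can be
checked against a closed form. *AO samples* are sparse textured grains
with untextured cores (a single centred grain peaks exactly at its
centre), normalized to [0, 1].

## Problem sizes and determinism

Default test and acceptance runs use: 21×21×120 voxel phantoms at 1 and
0.5 µm pitch, 40–60 neurons × 7 Hz × 7 min calcium scenes, 10–12 Zernike
modes on a 64² pupil, and 204×180×180 bead stacks — sizes chosen so the
full suite and the acceptance script each complete in a few minutes on a
single core while keeping every Monte-Carlo check at ≥ 10 seeds. All
stochastic steps consume explicit seeds; reported quantities are
recomputed from scratch on every run.

## Known limitations

* The thinning skeleton is only approximately rotation-equivariant;
  end-cap erosion at cut tube faces costs ~1 voxel per end and scan-order
  ties can shift endpoints by a few voxels.
* The AO forward model is 2D scalar optics with circular convolution; it
  cannot represent field-position-dependent aberrations or depth effects.
* The SNR definition, locomotion threshold, neuropil coefficient and
  indicator kinetics are declared conventions, so cross-study numerical
  comparisons require matching them.
* `IVD` implements the midpoint reading of an ambiguous formula (above).
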