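---
title: "Augmented laminography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmented laminography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging problem

Computed laminography (CL) is computed tomography with the rotation axis
tilted by the laminographic angle $\theta$ away from the conventional
orientation in which the axis is perpendicular to the beam. For flat,
laterally extended specimens the tilt keeps the X-ray path length through
the object short at every rotation angle $\varphi$ and lets the projected
region of interest stay on the detector at much higher geometric
magnification than a conventional CT scan of the same object would allow.
The price is sampling: in the parallel-beam model a spatial frequency
$\mathbf{k}$ is acquired if and only if it is perpendicular to some beam
direction on the acquisition cone, and tilting the axis leaves the **double
cone** of half-angle $\theta$ about the axis frequency $k_z$ entirely
unsampled. Its solid-angle fraction is $1-\cos\theta$: zero at $\theta = 0$
(CT samples everything up to Nyquist) and one at $\theta = 90^\circ$, the
degenerate limit of rotated radiography. Structures whose spectra live in
the cone — laterally extended, slowly varying "coarse and vertical"
features such as the layering of a flat slab — are blurred away along $z$,
while compact lateral detail is preserved at full sharpness.

Augmented laminography (AL) repairs the cone with a second, lower-
magnification CT scan of the same object: the two reconstructions are
brought onto a common grid and intensity scale, the empty cone is located
in the CL volume's 3D Fourier transform, the corresponding CT coefficients
are implanted (only up to the CT's own band limit), and the fused volume is
the inverse transform. The package implements this pipeline end to end on
synthetic data: a seeded phantom generator, a tilted-axis parallel-beam
projector with raw-intensity simulation and flat/dark correction, filtered
backprojection for both geometries, the Fourier fusion itself, and
quantitative comparison metrics.

## Geometry and units

All interfaces use millimetres and degrees. A `scan_geometry` carries the
source-to-detector and source-to-object distances (SDD, SOD), whose ratio
$M = \mathrm{SDD}/\mathrm{SOD}$ is the geometric magnification; the
detector pixel pitch (0.2 mm by default, a common flat-panel pitch); and
the effective voxel size, pitch$/M$. The default simulation mirrors a
realistic microfocus setup: SDD 1135 mm with SOD 137 mm for the CL scan
($M = 8.28$, effective voxel $\approx 24\,\mu$m) at $\theta = 29.8^\circ$,
and a five-fold lower magnification for the CT scan, so CT voxels are five
times coarser than CL voxels. Cone-beam magnification enters *only* through
this voxel-size bookkeeping; rays are parallel, which is the model under
which the missing-cone analysis is exact.

`check_ct_sampling()` evaluates the two classical conditions for
truncation-free reconstruction of a rotating region of interest — the ROI
shadow must stay on the detector, and shadows of regions that leave the
detector must never overlap it. The object is modelled as a centred
bounding cylinder; with a tilted axis an off-field point's shadow acquires
an axial offset proportional to $\sin\theta$ times its lateral radius, so
thin specimens of arbitrary lateral extent pass the overlap condition that
dooms high-magnification CT. The closed-form footprints are
regression-tested against a brute-force shadow sweep.

## The synthetic specimen

`flat_specimen_preset()` builds the study object: a $128\times128\times32$
grid (lateral/thickness aspect ratio 4) whose central 60% in $z$ carries
three attenuation layers (0.030, 0.045, 0.025 mm$^{-1}$ — values typical of
light minerals at a few hundred keV), a fixed central box of
0.090 mm$^{-1}$ providing known sharp in-plane and axial edges, and six
randomly placed spheres, cylinders and boxes of distinct attenuation
(0.055–0.100 mm$^{-1}$), seeded and reproducible. Membership is decided at
voxel centres so solid volumes are exactly countable; an optional
supersampling flag renders partial-volume edges instead. The generator
emulates the *geometry* of a flat layered specimen with embedded
structures; it does not attempt realistic mineral textures, polychromatic
beam hardening, scatter or detector blur, so passing tests demonstrate the
Fourier-domain mechanics of the method, not robustness to those physical
effects.

## Projection and reconstruction

The projector integrates attenuation along rays by trilinear interpolation
with a step of half a voxel (configurable, capped at one voxel), clipping
each ray to the volume's bounding box. The interpolation domain extends
half a voxel beyond the outer voxel centres with edge-value clamping, so a
voxel row of constant attenuation integrates to exactly its voxel sum —
this is what makes the discrete Fourier-slice test exact to interpolation
error. Raw-intensity simulation applies Beer–Lambert per pixel,
$I = (\mathrm{flat}-\mathrm{dark})e^{-p} + \mathrm{dark}$, optionally with
Poisson noise on the transmitted counts; `normalize_flat_dark()` inverts it
and clamps non-positive transmittance to a configurable maximum
attenuation, counting the clamped pixels.

Reconstruction is filtered backprojection, generalized to the tilted axis
by filtering each frame only along the detector direction perpendicular to
the rotation axis' projection and backprojecting voxel-wise with bilinear
detector sampling and the $\pi/n_{\text{proj}}$ parallel-beam weight. Two
numerical choices matter and are worth recording:

* **The ramp filter keeps its natural zero-frequency residual.** The
  classical band-limited kernel, truncated to the padded FFT length, has a
  small positive DC response that decays as one over the padded length.
  Forcing that bin to zero shifts every filtered row by a constant and
  biases reconstructed attenuation low by several percent; with the
  residual kept, the sphere-phantom centre is recovered to better than
  0.1%, matching a direct spatial-domain convolution oracle.
* **Filtered rows are sinc-upsampled (factor 4) before backprojection.**
  The ramp-filtered signal carries pixel-scale curvature, and plain
  bilinear sampling of it biases voxel values low by about 5%; FFT
  zero-padding interpolation removes the bias at negligible cost.

With 360 projections over $360^\circ$ the angular sampling satisfies the
$\sim \pi/2 \times$ lateral-grid-size criterion for the 128-wide default
phantom; reconstructions are angularly converged (doubling the count
changes RMSE in the fifth digit). These desk-scale sizes — $128^3$-scale
FFTs, full pipeline in tens of seconds — are the problem sizes used
throughout the tests and the acceptance script.

## Fusion

`resample_to_grid()` maps the coarse CT reconstruction onto the CL grid by
trilinear interpolation under a known rigid-plus-isotropic-scale transform
(synthetic data replaces the manual alignment a real experiment needs; a
correlation-peak check in the tests verifies sub-quarter-voxel
registration). `match_intensity()` then fits the gain on Fourier
*amplitudes* over the low-frequency annulus both scans sample reliably —
excluding the missing cone, where CL carries no signal and a naive
real-space least-squares fit collapses the gain — and aligns the means.

The missing region is located by the amplitude-comparison rule: a
frequency is declared missing when the (locally smoothed) CL amplitude
falls below $\tau$ times the CT amplitude, restricted to the trusted CT
band. Defaults, and why:

* `tau = 0.9`. A discrete, windowed backprojection never leaves the cone
  literally empty: the first $k_z$ bins retain a leakage floor of roughly
  10–60% of the matched CT amplitude (finite-window sidelobes of the
  backprojection extrusions). Sampled frequencies sit at an amplitude
  ratio of about 1 after gain matching, so the classifier threshold
  belongs just under 1. A threshold of 0.1, which a noiseless idealization
  would suggest, classifies nothing.
* `smooth_size = 5` (envelope smoothing) and `median_size = 3` (binary
  cleanup). Single-bin amplitudes fluctuate strongly; comparing local
  envelopes and median-filtering the raw mask stabilize the decision. On
  grids with anisotropic frequency steps — the flat volume's $k_z$ bins
  are four times coarser than its $k_x$ bins — both kernels shrink
  per-axis to stay frequency-isotropic; a naive cubic kernel swallows the
  thin cone entirely.
* `ct_band_radius = 0.16`, i.e. 80% of the nominal $1/5$ voxel-size ratio.
  Cone bins at the CT's own Nyquist frequency are neither detectable nor
  fillable (its modulation transfer vanishes there), so the band is
  derated the way any practical MTF budget would be.
* The threshold compares the two amplitudes as a *ratio* (an absolute-level
  variant of the same rule can be had by scaling `tau`, and the geometric
  `analytic` mask mode bypasses estimation entirely); coefficients are
  substituted *hard* at the mask boundary — no phase blending — with an
  optional raised-cosine apodization (`apodization_width`, default 2
  frequency voxels) to suppress ringing. Width 0 is the fidelity
  reference: fusion is then exactly idempotent and preserves the CL
  spectrum outside the mask coefficient-for-coefficient.

The mask is always inversion-symmetrized and excludes DC, which guarantees
a real-valued fused volume; fusion verifies the imaginary residual is
below $10^{-8}$ of the output RMS and rejects asymmetric masks outright.

## What the metrics show

`method_report()` scores CL, upsampled CT and AL against the ground truth:
RMSE, PSNR, the spectral energy fraction inside the cone, and two edge
widths. The in-plane width is the interpolated 10–90% rise across the
central box's lateral face; a sampled unit-slope edge reads 0.8 voxels,
the sampling-limited minimum. The axial width is measured at the slab's
top surface — a laterally extended $z$-edge whose spectrum lies in the
cone, i.e. precisely what CL loses — using the local-slope estimator
$0.8\,C/\max|dP/dz|$ (identical to the 10–90% convention for clean ramps)
because laminographic blur spreads that edge beyond any window that fits
between the slab's layer boundaries. On the default simulation the
orderings are stable across seeds: in-plane CT $\gg$ CL $\approx$ AL
$\approx$ 0.8; axial CL $>$ AL $\ge$ CT; and RMSE AL $<$ CT-upsampled $<$
CL.

## Known limitations

* **The reconstructed cone is suppressed, not empty.** An idealized
  analysis predicts essentially zero spectral energy inside the cone of a
  CL reconstruction. The package's measured ratio on the default flat
  phantom is about 0.26 of the (mean-removed) spectrum: the dominant
  contributions are the first $k_z$ bins next to DC, where the finite
  reconstruction window turns each backprojected plane contribution into a
  thickened slab whose sidelobes deposit roughly a tenth of the true
  amplitude. Enlarging the grid does not help (the detector's support then
  truncates the extrusions instead); the effect is scale-invariant in the
  grid depth. This leakage floor is exactly why the mask threshold sits
  near 1 rather than near 0, and it is reported honestly by
  `cone_energy_ratio()` rather than hidden by windowing tricks.
* The CT comparison volume is the trilinear-upsampled coarse
  reconstruction — the volume a practitioner would actually lay beside the
  CL scan. Its interpolation loss is part of what fusion must beat, and
  part of why implanted coefficients near the CT band edge remain
  attenuated.
* Real-data concerns — registration of physically separate scans,
  beam hardening, scatter, ring artifacts, detector lag — are out of
  scope; the known-transform resampler stands in for manual alignment.
* The paper-scale acquisition (2048 projections) is supported but not the
  default; at the package's grid sizes 360 projections are converged, and
  the angular count is exposed on every entry point.
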