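---
title: "In-silico training for fluorescence depth mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico training for fluorescence depth mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sfdepth` builds, end to end, the in-silico machinery needed to train and
evaluate a convolutional network that maps spatial frequency domain imaging
(SFDI) measurements of a fluorescent "iceberg" tumor — one flush with, or
protruding through, the tissue surface — to per-pixel maps of tumor depth
(distance from the surface plane, or the protruding apex, to the tumor's
bottom surface) and fluorophore concentration. This vignette records the
scientific models, the tunable parameters, and the design decisions taken
where the design space was genuinely open.

## Coordinate and grid conventions

All computation happens on a fixed lattice: 101 x 101 lateral pixels at
0.5 mm/pixel (a 50 mm field of view) and an axial grid from -5 mm to +15 mm
at 0.5 mm steps. The axial coordinate z increases *downward into the
tissue*; the tissue surface is z = 0, and "protruding above the surface"
means z < 0. Voxels are occupied when their center lies inside the
generating surface. The axial extent keeps both 10 mm-deep training shapes
and the protruding part of patient-style meshes on the grid.

## Synthetic tumor shape families

Three families of increasing geometric complexity share the same training
ranges: lateral widths (axis-aligned bounding-box sides) of 10-40 mm and
depths of 1-10 mm, both drawn uniformly.

**Cylinders** are the proof-of-concept family: a right circular cylinder
with its top face flush with the surface.

**Spherical harmonics** perturb a 10 mm sphere radially,
`r(theta, phi) = R (1 + a Y_lm)`, then scale each axis to the drawn
extents and cut everything above the surface. The degree l is drawn
uniformly on 2..20. A literal pairing of l with an order fixed at
"l - 20" is impossible for l < 10 (it would violate |m| <= l), so the
order m is drawn uniformly on -l..l. The perturbation amplitude is drawn
uniformly on 0.1-0.3: large enough for clearly visible lobes, small enough
that the radius stays positive and the shape stays star-convex (both are
verified at generation time; amplitudes producing non-positive radii are
rejected with an error).

**Composite spherical harmonics (CSH)** merge four independent
spherical-harmonic surfaces as curvilinear quadrants of the XY plane
delimited by two reciprocal curves `x y = c1` and `x y = c2`
(`c1 ~ U(2, 20)` mm^2, `c2 ~ -U(2, 20)` mm^2). A literal sign-based
partition by the two curves produces five connected components rather
than four quadrants, and any hard assignment leaves radial discontinuities,
so the radial field is blended: a cosine ramp in `t = x y` between the two
curves selects between the "outer" quadrant pair and the opposite pair,
and the two members of each pair are mixed by a second cosine ramp in x of
2 mm half-width. The result is continuous everywhere, reduces to a single
spherical harmonic when all four quadrant fields are identical, and shows
clear quadrant structure away from the seams. The merged shape is rotated
(uniform +/-30 degrees about X and Y — keeping the shape roughly
surface-facing — and +/-180 degrees about Z), shifted downward by
0-2 mm (this is what creates buried regions whose top surface sits below
z = 0), scaled to the drawn extents, and cut at the surface.

Scaling to target extents is computed on the *post-cut* shape: the surface
is sampled densely, rotated and shifted, clipped against z = 0 (the clipped
ray points trace the cut face boundary of a star-convex solid exactly), and
the axis scale factors are taken as target/measured extents. This makes
width and depth exact by construction, rather than approximate after the
cut; voxelized measurements agree within half a voxel.

**Ground truth.** Per image column, with ztop/zbot the shallowest/deepest
occupied voxel faces: depth is `zbot - min(ztop, 0)` — the distance from
the surface plane to the tumor bottom for flush or buried columns, and the
full top-to-bottom thickness for protruding columns (patient-mesh mode,
where occupancy above the surface is permitted). Non-star-convex columns
(possible after rotation) are treated as their occupied span — internal
gaps are filled for depth purposes. The concentration map is the
homogeneous tumor concentration over the footprint.

**Patient-style meshes.** The patient tongue-tumor contours behind the
original study are not publicly deposited, so mesh-mode test sets run on
programmatically generated *synthetic surrogate meshes*: watertight
UV-sphere triangulations of randomly perturbed radial fields, positioned so
part of the shape protrudes above the surface. They exercise the identical
code path (STL/PLY input, watertightness validation, z-rotation and
per-axis scaling augmentation, parity voxelization, protrusion-aware ground
truth) without standing in for the patients' actual geometry in any claim.

## Optical forward model

The simulator treats the bulk tissue as homogeneous with absorption
mu_a (training range 0.0015-0.015 mm^-1) and reduced scattering
mu_s' (0.75-2 mm^-1), refractive index 1.4, and works in the diffusion
approximation throughout.

* **Reflectance.** The modulated diffuse reflectance is the standard SFDI
  closed form `Rd(fx) = 3 A a' / ((mu_eff'/mu_tr + 1)(mu_eff'/mu_tr + 3A))`
  with `mu_eff'(fx) = sqrt(mu_eff^2 + (2 pi fx)^2)` and
  `A = (1 - R_eff) / (2 (1 + R_eff))`. Reflectance frames are spatially
  flat (bulk properties are per-sample constants; optical contrast of the
  tumor in reflectance is out of scope) with shot noise applied.
* **Excitation fluence.** The 1-D modulated planar-source solution
  `phi(z) = C [exp(-mu_tr z) - B exp(-mu_eff' z)]` under the
  partial-current boundary condition. A consistency note: writing the
  boundary condition as `phi(0) = z_b phi'(0)`, the same closed form for
  Rd drops out of `Rd = D phi'(0)` only with the standard extrapolation
  length `z_b = 2 D (1 + R_eff)/(1 - R_eff)`; that convention is used for
  both the fluence and the escape kernel. The removable singularity at
  `mu_eff' = mu_tr` is handled by a relative 1e-6 nudge.
* **Emission escape.** The surface-detected intensity from a buried
  isotropic emitter uses the dipole image-source construction across the
  extrapolated boundary at `-z_b`.
* **Fluorescence.** A first-Born perturbation sum over the voxel lattice:
  excitation fluence x fluorophore absorption x escape kernel, integrated
  per z-slice as a lateral FFT convolution (padded to 256 so kernels
  truncate at the aliasing-safe radius of ~38 mm; kernels are additionally
  truncated below 1e-6 of their on-axis value). Emission-wavelength
  optical properties are set equal to excitation properties. The
  fluorophore is homogeneous in the tumor at concentration C
  (1-10 ug/mL), converted to absorption by a configurable factor
  epsilon_C = 0.02 mm^-1 per ug/mL, with quantum efficiency eta = 0.046
  (protoporphyrin IX); only the internal consistency between simulator and
  network matters for recovery, since the same constants generate training
  and test data. Fluorophore voxels protruding above the surface are
  folded into the shallowest tissue slice — there is no overlying tissue
  to attenuate them, and the diffusion model has no representation of a
  non-scattering protrusion. When background fluorescence is enabled, the
  healthy tissue (all z >= 0) carries a drawn fraction (0.1-50%) of the
  tumor concentration, and the ground-truth concentration map keeps that
  background level off-footprint, matching what the forward model emits.
* **Noise.** "Shot noise" means each frame is scaled so its maximum pixel
  corresponds to the photon budget (default 1e4 expected counts), Poisson
  sampled, and rescaled.

Each closed form is validated in the test suite against an independent
second-order finite-difference diffusion solver (reflectance and fluence to
<0.5% across the training property box) and against 1-D quadrature for the
laterally-infinite-slab fluorescence limit (<1%).

## Lookup-table property inversion

Per-pixel (mu_a, mu_s') are recovered from reflectance at fx = 0 and
0.2 mm^-1. The table is a 200 x 200 linear grid spanning the training
ranges whose injectivity is audited at build time (measurement-space
near-coincidences may only occur between neighbouring property nodes).
The inverse itself is a damped, fully vectorized Newton iteration on the
closed-form forward map with finite-difference Jacobians, seeded from the
nearest tabulated node; results are clamped to the tabulated domain and
flagged when the measurement falls outside it or the iteration fails to
converge. Round-trip error on noiseless data is at machine precision,
comfortably inside the 1% contract. Demodulation is out of scope: the
simulator emits already-demodulated AC amplitudes.

## Network

The model is a two-arm convolutional network. The property arm applies two
3x3 convolutions (2 -> 72 -> 96 channels) and a residual block (two 3x3
convolutions with identity skip). The fluorescence arm applies one
volumetric 3x3x6 convolution with 24 filters across the six-frequency
stack (zero-padded along frequency, weights shared across positions),
reshapes the result to 144 channels, applies convolutions 144 -> 96 ->
96 and a residual block. The arms are concatenated (192 channels), mixed
by a depthwise-separable convolution down to 96 channels and a residual
block, and split into two heads that taper 96 -> 64 -> 16 -> 1. All
layers use stride 1, zero padding, and rectifier activations, including
the final layer (enforcing non-negative physical outputs). This schedule
carries exactly 920,514 trainable parameters; the figure-level filter
counts were under-determined, so the committed schedule was chosen by
constrained search as a regular taper consistent with the architecture
description and that exact total.

No deep-learning framework is available in this R stack, so the layers,
their backward passes, and the Adam optimizer are implemented in the
package itself: a C++ patch-gather kernel (im2col) feeds BLAS matrix
multiplies; gradients were verified against numerical differentiation to
1e-6 (the verification jitters biases away from zero first — freshly
initialized networks otherwise have activations sitting exactly on ReLU
kinks, where two-sided numerical differences measure the subgradient
average rather than the one-sided derivative the backward pass correctly
returns).

Training choices (the sources are silent on all of them): composite loss =
MSE on depth normalized by 10 mm + MSE on concentration normalized by
10 ug/mL, equally weighted; Adam with exponential learning-rate decay
(x0.95/epoch at full scale); batch size 16; early stopping on validation
loss with patience 10 and best-weight restore; 90/10 train/validation
split; He-normal initialization.

Two input-representation choices deserve explanation. Property maps are
min-max scaled by the training ranges; the fluorescence stack is divided
by the dataset's 99th percentile. A logarithmic variant
(`log1p(100 x)` after the scaling) was considered, on the argument that
depth is encoded in the *shape* of the frequency decay — a ratiometric
quantity that becomes affine under a log — but in side-by-side runs at
equal compute it trained clearly worse (it amplifies the shot-noise
contrast of the dark off-footprint region, and the concentration head,
which needs the linear amplitude, degenerated), so linear scaling is the
default and the log variant remains an option (`fluor_log`).

Because every layer is convolutional with stride 1, the network is
fully convolutional: it can be trained on randomly cropped sub-windows and
applied to full 101 x 101 frames. Reduced-scale training runs in this
package use 48-64 pixel crops as a throughput and augmentation device;
validation and inference always run at full frame size.

## Problem sizes

The study-scale configuration is 10,000 training samples per shape family
and up to 100 epochs. The package's own test suite and the bundled
acceptance analysis run the same pipeline end to end at reduced sizes
chosen to keep a complete run on one CPU core in the tens of minutes: a
couple of hundred simulated cylinders, a reduced filter schedule of the
same topology, crop-window training, and about twenty epochs. At that
scale the held-out footprint depth error on cylinders lands between one
and two millimetres rather than the few tenths of a millimetre a
full-scale run reports; what the reduced runs demonstrate is the complete
learning loop — steadily decreasing validation loss and errors well below
the 2-3 mm a depth-blind predictor would incur — not the full-scale
accuracy. The full-scale configuration remains available through the same
functions (`generate_training_set`, `train_config(epochs = 100)`).

## Evaluation

Per-sample error is the mean absolute per-pixel difference over the
ground-truth footprint (pixels with true depth > 0) — with union and
full-image supports available for sensitivity checks — and cohorts are
summarized as mean +/- sample SD (divisor n - 1). Model comparisons use a
two-sided paired Wilcoxon signed-rank test (exact for n < 25 without
ties), with a paired t-test behind a flag; the original report does not
name its test, and the signed-rank choice is robust to the heavy-tailed
per-sample error distributions seen here.

## Phantom preprocessing

Camera images arrive at 0.1 mm/pixel with a manual crop. The chain is:
crop (caller-supplied box, recorded in metadata) -> pad to 505 x 505 with
i.i.d. uniform draws on [mean - SD, mean + SD] of the non-fluorescent
background intensity (the phrasing "values within one standard deviation
of the mean" supports either random or constant padding; a constant-mean
fallback is provided) -> exact non-overlapping 5x5 block means down to
101 x 101 at 0.5 mm/pixel. All channels of a group share the same pad
pattern. Property maps are inverted at camera resolution before
downsampling, so they pass through the identical chain.

## Known limitations

* The diffusion approximation, not Monte-Carlo transport; no surface
  profilometry; flat reflectance (no optical contrast of the tumor).
* Homogeneous fluorophore in the tumor; no infiltrative microstructure
  ("finger-like" projections, satellite nodules) in any shape family.
* The synthetic-mesh surrogates exercise the patient-mesh code path but
  say nothing about performance on real patient geometry.
* Reduced-scale training demonstrates the pipeline and its scaling trend,
  not the full-scale accuracy figures.
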