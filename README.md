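# sfdepth

Deep-learning fluorescence depth mapping for spatial frequency domain
imaging (SFDI), trained entirely in silico.

## The problem

Fluorescence-guided surgery shows *where* a tumor is, but standard
wide-field imaging cannot say *how deep* it goes — and for oral cancer the
depth of invasion is precisely what drives positive margins. Under
spatially modulated illumination, the frequency-dependent attenuation of
diffuse light encodes depth: high spatial frequencies probe shallow
tissue, low frequencies probe deep. `sfdepth` implements the full
in-silico pipeline for learning that encoding for "iceberg" tumors (flush
with or protruding through the mucosal surface, infiltrating downward):

1. **Synthetic tumor shapes** — cylinders, spherical-harmonic perturbed
   spheres, and composite spherical harmonics (CSH; four harmonic fields
   merged as curvilinear quadrants along two reciprocal curves, rotated,
   shifted, scaled, cut at the surface), voxelized on a 101 x 101 grid at
   0.5 mm/pixel, widths 10-40 mm, depths 1-10 mm. Patient-style closed
   surface meshes (STL/PLY) are supported, with programmatically generated
   synthetic surrogates standing in for unreleased patient contours.
2. **Diffusion-theory SFDI simulator** — calibrated reflectance
   `Rd(fx) = 3 A a' / ((mu_eff'/mu_tr + 1)(mu_eff'/mu_tr + 3A))` and a
   first-Born fluorescence model (modulated planar excitation fluence x
   fluorophore absorption x dipole escape kernel, summed per z-slice by
   FFT convolution) at fx = 0, 0.05, 0.10, 0.15, 0.20, 0.25 mm^-1, with
   Poisson shot noise. Validated against an independent finite-difference
   diffusion solver.
3. **Lookup-table inversion** — per-pixel (mu_a, mu_s') from reflectance
   at fx = 0 and 0.2 mm^-1 by Newton inversion of the tabulated forward
   map (round-trip error far below 1%).
4. **Two-arm convolutional network** — one arm ingests the two optical
   property maps, the other the six-frequency fluorescence stack through a
   volumetric 3x3x6 entry layer; after concatenation, a separable
   convolution, residual blocks, and two heads produce per-pixel depth
   (mm) and fluorophore concentration (ug/mL) maps. The committed filter
   schedule carries exactly 920,514 trainable parameters. Layers,
   backpropagation, and the Adam training loop are implemented in the
   package (C++ patch gathering + BLAS); gradients are verified against
   numerical differentiation in the test suite.
5. **Evaluation and phantom preprocessing** — footprint mean-absolute
   errors, cohort mean +/- SD, paired signed-rank comparisons, and the
   camera-image chain (background-statistics padding, exact 5x5 block-mean
   downsampling from 0.1 to 0.5 mm/pixel).

## A worked example

```r
library(sfdepth)

lut <- build_lut()                       # two-frequency SFDI lookup table

# one simulated sample: a 20 mm wide, 5 mm deep cylinder at typical optics
shape <- make_cylinder(width_mm = 20, depth_mm = 5)
props <- optical_props(mu_a = 0.0045, mu_s_prime = 1.0)
set.seed(1)
sim  <- simulate_sample(shape, props, fluor_spec(concentration = 5))
pm   <- optical_property_maps(sim$stack, lut)

c(mu_a = median(pm$mu_a), mu_s = median(pm$mu_s_prime))
#>      mu_a      mu_s
#> 0.0045012 1.0001016

# a reduced-scale end-to-end training run (a few minutes on one core)
ds <- generate_training_set("cylinder", 220, seed = 42, lut = lut)
te <- generate_test_set("cylinder", 40, seed = 99, lut = lut)
set.seed(7)
model <- build_model(model_config(op_widths = c(8, 12), vol_filters = 2,
                                  fl_widths = c(12, 12), trunk_width = 16,
                                  head_widths = c(8, 4)))
model <- train_model(model, ds,
                     train_config(lr = 1e-3, lr_decay = 0.93, epochs = 18,
                                  batch_size = 8, crop_px = 48, seed = 7))
errs <- lapply(te$samples, function(s)
  sample_error(predict_maps(model, load_sample(s)$inputs), s$gt))
cohort_stats(errs)
#> n = 40: depth error 1.66 (1.06) mm, concentration error 0.754 (0.527) ug/mL
```

The median recovered optical properties match the simulation truth to a
fraction of a percent, and the depth error — the mean absolute per-pixel
difference between predicted and true depth maps over the tumor
footprint, averaged over held-out samples — is 1.66 mm for this
minutes-scale run. The full study-scale configuration (10,000 samples per
family, up to 100 epochs, the default 920,514-parameter schedule) uses
exactly the same functions; see the methods vignette
(`vignettes/depth-mapping-methods.Rmd`) for what the reduced problem
sizes do and do not demonstrate.

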