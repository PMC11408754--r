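lut_ds <- build_lut(n_nodes = 120)

test_that("an empty request yields a valid empty manifest", {
  ds <- generate_training_set("cylinder", 0, seed = 1, lut = lut_ds)
  expect_equal(nrow(ds$manifest), 0)
  expect_length(ds$samples, 0)
})

test_that("training-set randomization stays inside the declared intervals", {
  ds <- generate_training_set("cylinder", 12, bg_enabled = TRUE, seed = 2,
                              lut = lut_ds)
  m <- ds$manifest
  expect_equal(nrow(m), 12)
  expect_true(all(m$mu_a > 0.0015 & m$mu_a < 0.015))
  expect_true(all(m$mu_s_prime > 0.75 & m$mu_s_prime < 2))
  expect_true(all(m$concentration > 1 & m$concentration < 10))
  expect_true(all(m$bg_fraction > 0.001 & m$bg_fraction < 0.5))
  expect_true(all(m$depth >= 1 - 0.51 & m$depth <= 10 + 0.51))
  expect_true(all(table(m$split)[c("train", "val")] > 0))
  expect_false(any(duplicated(m$id)))
})

test_that("generation is bit-stable under a fixed seed", {
  d1 <- generate_training_set("cylinder", 4, seed = 5, lut = lut_ds)
  d2 <- generate_training_set("cylinder", 4, seed = 5, lut = lut_ds)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$samples[[3]]$stack$fluorescence,
                   d2$samples[[3]]$stack$fluorescence)
  expect_identical(d1$samples[[2]]$prop_maps$mu_a,
                   d2$samples[[2]]$prop_maps$mu_a)
})

test_that("test sets fix the evaluation optics and support mesh augmentation", {
  te <- generate_test_set("cylinder", 5, seed = 3, lut = lut_ds)
  expect_true(all(te$manifest$mu_a == 0.0045))
  expect_true(all(te$manifest$mu_s_prime == 1))
  expect_true(all(te$manifest$concentration == 5))

  set.seed(61)
  meshes <- replicate(2, synthetic_tumor_mesh(), simplify = FALSE)
  tm <- generate_test_set(meshes, 4, seed = 4, lut = lut_ds)
  expect_equal(nrow(tm$manifest), 4)
  expect_true(all(tm$manifest$family == "mesh"))
  expect_true(all(tm$manifest$depth >= 0.5 & tm$manifest$depth <= 10.6))

  bad <- mesh3(meshes[[1]]$vertices, meshes[[1]]$faces[-1, ])
  expect_error(generate_test_set(list(bad), 2, seed = 1, lut = lut_ds),
               "mesh validation failed")
})

test_that("an oversized mesh is flagged out of the training range", {
  set.seed(62)
  m <- synthetic_tumor_mesh(base_radius_mm = 8)
  tm <- generate_test_set(list(m), 1, seed = 9, lut = lut_ds,
                          mesh_scale = FALSE)
  # unscaled 16-mm shape: depth beyond 10 mm must raise the flag
  expect_true(tm$manifest$depth > 10)
  expect_true(tm$manifest$out_of_range)
})

test_that("background fluorescence shows off-footprint in inputs and targets as configured", {
  ds <- generate_training_set("cylinder", 1, bg_enabled = TRUE, seed = 8,
                              lut = lut_ds, val_frac = 0)
  s <- ds$samples[[1]]
  ls <- load_sample(s)
  fp <- s$gt$depth_mm > 0
  # input fluorescence is nonzero off the footprint...
  expect_gt(mean(ls$inputs$fluorescence[, , 1][!fp]), 0)
  # ...and the concentration target off-footprint carries the background level
  bg_level <- s$record$bg_fraction * s$record$concentration
  expect_equal(ls$targets$concentration[!fp][1], bg_level, tolerance = 1e-12)
  expect_equal(max(ls$targets$concentration[fp]), s$record$concentration)
})

test_that("dataset containers round-trip through disk", {
  ds <- generate_training_set("cylinder", 2, seed = 10, lut = lut_ds,
                              val_frac = 0)
  dir <- file.path(tempdir(), "ds-rt")
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(nrow(ds2$manifest), 2)
  l1 <- load_sample(ds$samples[[1]])
  l2 <- load_sample(ds2$samples[[1]])
  # on-disk pixels are 32-bit; agreement to float precision
  expect_equal(l1$inputs$fluorescence, l2$inputs$fluorescence,
               tolerance = 1e-6)
  expect_equal(l1$targets$depth_mm, l2$targets$depth_mm, tolerance = 1e-6)
  # a second write/read cycle reproduces values to the container's
  # 32-bit quantization step
  s2 <- ds2$samples[[1]]
  stack2 <- read_stack(s2$paths$stack)
  path3 <- file.path(tempdir(), "stack3.tif")
  write_stack(stack2, path3)
  stack3 <- read_stack(path3)
  q <- max(stack2$fluorescence) * 2^-31
  expect_lt(max(abs(stack2$fluorescence - stack3$fluorescence)), q)
  expect_lt(max(abs(stack2$reflectance - stack3$reflectance)),
            max(stack2$reflectance) * 2^-31)
})

test_that("normalization restores physical units to machine precision", {
  ds <- generate_training_set("cylinder", 1, seed = 11, lut = lut_ds,
                              val_frac = 0)
  ls <- load_sample(ds$samples[[1]])
  norm <- sfdepth:::default_norm()
  norm$fluor_scale <- 0.123
  ni <- normalize_inputs(ls$inputs, norm)
  back <- ni$fluorescence * norm$fluor_scale
  expect_equal(back, ls$inputs$fluorescence, tolerance = 1e-14)
  mu_a_back <- ni$props[, , 1] * diff(norm$mu_a_range) + norm$mu_a_range[1]
  expect_equal(mu_a_back, ls$inputs$props[, , 1], tolerance = 1e-12)
})
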