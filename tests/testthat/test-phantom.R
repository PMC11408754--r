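test_that("background padding honors extent, range, and moments", {
  st <- background_stats(10, 2)
  img <- matrix(5, 40, 40)
  expect_identical(pad_with_background(img, st, c(40, 40)), img)
  expect_error(pad_with_background(img, st, c(30, 40)), "smaller")
  set.seed(90)
  padded <- pad_with_background(img, st, c(400, 420))
  pad_mask <- padded != 5
  vals <- padded[pad_mask]
  expect_true(all(vals >= 8 & vals <= 12))
  # uniform-law mean within 3 standard errors
  se <- (2 * 2 / sqrt(12)) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 10), 3 * se)
  # constant fallback
  padc <- pad_with_background(img, st, c(50, 50), constant = TRUE)
  expect_true(all(padc[padc != 5] == 10))
})

test_that("box downsampling is exactly the 5x5 block-mean operator", {
  expect_error(box_downsample(matrix(0, 101, 101)), "505")
  img <- matrix(3.7, 505, 505)
  out <- box_downsample(img)
  expect_identical(dim(out), c(101L, 101L))
  expect_true(all(out == 3.7))
  # single hot pixel in one block -> block mean 1/25 of its value
  img <- matrix(0, 505, 505)
  img[7, 3] <- 25
  out <- box_downsample(img)
  expect_equal(out[2, 1], 1.0)
  expect_equal(sum(out != 0), 1L)
  # independent double-loop oracle on a random image
  set.seed(91)
  img <- matrix(rnorm(505 * 505), 505, 505)
  out <- box_downsample(img)
  for (k in 1:25) {
    i <- sample(101, 1); j <- sample(101, 1)
    blk <- img[(5 * i - 4):(5 * i), (5 * j - 4):(5 * j)]
    expect_equal(out[i, j], mean(blk), tolerance = 1e-12)
  }
})

test_that("stack preprocessing crops, pads all channels identically, and resizes", {
  st <- background_stats(0.2, 0.05)
  imgs <- list(r0 = matrix(0.7, 600, 600), r2 = matrix(0.3, 600, 600))
  out <- preprocess_stack(imgs, crop_box = c(48, 48, 552, 552), stats = st)
  expect_identical(dim(out$channels$r0), c(101L, 101L))
  expect_true(all(out$channels$r0 == 0.7))  # pure downsample path, no pad
  # a 400x400 crop needs padding; the pad pattern is shared across channels.
  # blocks mixing pad and interior pixels differ by construction, so compare
  # on purely padded blocks (via a downsampled pad-indicator image)
  out2 <- preprocess_stack(imgs, crop_box = c(101, 101, 500, 500), stats = st,
                           pad_seed = 7)
  ind <- matrix(1, 505, 505)
  r0 <- (505 - 400) %/% 2
  ind[r0 + 1:400, r0 + 1:400] <- 0
  pure_pad <- box_downsample(ind) == 1
  expect_gt(sum(pure_pad), 0)
  expect_equal(out2$channels$r0[pure_pad], out2$channels$r2[pure_pad],
               tolerance = 1e-12)
  expect_identical(dim(out2$channels$r2), c(101L, 101L))
  imgs_bad <- list(a = matrix(0, 600, 600), b = matrix(0, 500, 600))
  expect_error(preprocess_stack(imgs_bad, NULL, st), "shape disagreement")
})

test_that("camera-resolution rendering round-trips through the preprocessing chain", {
  # flat reflectance frames at known properties, rendered at 0.1 mm/pixel
  lut <- build_lut(n_nodes = 120)
  pr <- unit_props()
  r0 <- matrix(diffuse_reflectance(pr, 0), 505, 505)
  r2 <- matrix(diffuse_reflectance(pr, 0.2), 505, 505)
  set.seed(92)
  r0 <- add_poisson_noise(r0, 1e5)
  r2 <- add_poisson_noise(r2, 1e5)
  out <- preprocess_stack(list(r0 = r0, r2 = r2), NULL,
                          background_stats(0.1, 0.01))
  inv <- invert_pixel(as.vector(out$channels$r0), as.vector(out$channels$r2),
                      lut)
  expect_lt(abs(median(inv$mu_a) - 0.0045) / 0.0045, 0.02)
  expect_lt(abs(median(inv$mu_s_prime) - 1), 0.02)
})
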