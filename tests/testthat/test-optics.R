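test_that("diffuse reflectance is physical and monotone in frequency and absorption", {
  pr <- unit_props()
  rd <- diffuse_reflectance(pr, FX_LIST)
  expect_true(all(rd > 0 & rd < 1))
  expect_true(all(diff(rd) < 0))
  # absorbing limit
  rd_seq <- diffuse_reflectance(optical_props(c(0.5, 5, 500), 1.0), 0)
  expect_true(all(diff(rd_seq) < 0))
  expect_lt(rd_seq[3], 1e-3)
  expect_error(optical_props(-1, 1), "non-physical")
})

test_that("Rd and the planar fluence match the finite-difference diffusion oracle", {
  # evaluation conditions plus the corners of the training property box
  cases <- rbind(c(0.0045, 1.0), c(0.0015, 0.75), c(0.0015, 2),
                 c(0.015, 0.75), c(0.015, 2))
  for (r in seq_len(nrow(cases))) {
    pr <- optical_props(cases[r, 1], cases[r, 2])
    for (fx in c(0, 0.1, 0.2)) {
      o <- fd_diffusion(cases[r, 1], cases[r, 2], fx)
      expect_lt(abs(diffuse_reflectance(pr, fx) - o$rd) / o$rd, 0.005)
      zq <- c(0.5, 2, 5, 10)
      pa <- excitation_fluence(zq, fx, pr)
      pf <- approx(o$z, o$phi, zq)$y
      expect_lt(max(abs(pa - pf) / pf), 0.005)
    }
  }
})

test_that("fluence decays to zero and high-frequency content concentrates at the surface", {
  pr <- unit_props()
  z <- seq(0.25, 60, by = 0.25)
  phi0 <- excitation_fluence(z, 0.05, pr)
  phi1 <- excitation_fluence(z, 0.2, pr)
  expect_lt(phi0[length(z)] / max(phi0), 1e-4)
  ratio <- phi1 / phi0
  expect_true(all(diff(ratio) <= 1e-12))  # non-increasing with depth
})

test_that("escape kernel is radially symmetric and attenuates with burial depth", {
  pr <- unit_props()
  expect_equal(emission_escape(-3, 5, pr), emission_escape(3, 5, pr))
  expect_gt(emission_escape(0, 5, pr), emission_escape(0, 10, pr))
  # total escaped power decreases with depth (quadrature oracle)
  ints <- vapply(c(2, 5, 10), escape_plane_integral, numeric(1), props = pr)
  expect_true(all(diff(ints) < 0))
  # monotone in lateral offset
  e <- emission_escape(seq(0, 20, by = 0.5), 5, pr)
  expect_true(all(diff(e) < 0))
})

test_that("fluorescence forward model is linear in concentration", {
  cy <- make_cylinder(16, 4)
  pr <- unit_props()
  f0 <- simulate_fluorescence(cy, pr, fluor_spec(0), fx = c(0, 0.1))
  expect_true(all(f0 == 0))
  f1 <- simulate_fluorescence(cy, pr, fluor_spec(2), fx = c(0, 0.1))
  f2 <- simulate_fluorescence(cy, pr, fluor_spec(4), fx = c(0, 0.1))
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("wide-slab center pixel matches the 1-D quadrature limit", {
  # a cylinder much wider than the field of view approximates an infinite slab
  g <- grid_spec()
  x <- grid_x(g); z <- grid_z(g)
  occ <- array(FALSE, dim = c(g$nx, g$ny, g$nz))
  occ[, , z >= 0 & z <= 4] <- TRUE    # slab filling the whole lateral grid
  slab <- shape_volume(g, occ)
  pr <- unit_props()
  fl <- fluor_spec(5)
  for (fx in c(0, 0.15)) {
    img <- simulate_fluorescence(slab, pr, fl, fx = fx)
    center <- img[51, 51, 1]
    oracle <- slab_fluorescence_1d(4, fx, pr, fl)
    expect_lt(abs(center - oracle) / oracle, 0.01)
  }
})

test_that("normalized frequency decay steepens with slab depth", {
  pr <- unit_props()
  fl <- fluor_spec(5)
  decay <- vapply(c(2, 8), function(d) {
    cy <- make_cylinder(30, d)
    img <- simulate_fluorescence(cy, pr, fl, fx = c(0, 0.25))
    fp <- ground_truth_maps(cy, 5)$depth_mm > 0
    mean(img[, , 2][fp]) / mean(img[, , 1][fp])
  }, numeric(1))
  expect_lt(decay[2], decay[1])  # deeper slab loses high-frequency signal
})

test_that("Poisson noise preserves zeros, means, and the expected variance", {
  expect_identical(add_poisson_noise(matrix(0, 4, 4), 100), matrix(0, 4, 4))
  img <- matrix(c(10, 5, 2, 1), 2, 2)
  set.seed(77)
  draws <- replicate(10000, add_poisson_noise(img, 1000))
  m <- apply(draws, c(1, 2), mean)
  # mean within 3 standard errors: var = peak/budget scaling per pixel
  se <- sqrt(img * (max(img) / 1000)) / sqrt(10000)
  expect_true(all(abs(m - img) < 3 * se + 1e-9))
  v_peak <- var(draws[1, 1, ])
  expect_lt(abs(v_peak - img[1, 1] * max(img) / 1000) / (img[1, 1] * max(img) / 1000), 0.1)
})

test_that("simulated samples are reproducible under a fixed seed", {
  cy <- make_cylinder(14, 3)
  pr <- unit_props()
  run <- function() {
    set.seed(123)
    simulate_sample(cy, pr, fluor_spec(4), photon_budget = 1e4)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$stack$fluorescence, s2$stack$fluorescence)
  expect_identical(s1$stack$reflectance, s2$stack$reflectance)
  # infinite photon budget reproduces the noiseless stack
  s_inf <- simulate_sample(cy, pr, fluor_spec(4), photon_budget = Inf)
  noiseless <- simulate_fluorescence(cy, pr, fluor_spec(4))
  expect_equal(s_inf$stack$fluorescence, noiseless)
})
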