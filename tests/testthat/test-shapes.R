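test_that("cylinder occupancy matches a brute-force point-in-cylinder oracle", {
  g <- grid_spec()
  cy <- make_cylinder(20, 5, g)
  x <- grid_x(g); y <- grid_y(g); z <- grid_z(g)
  n_oracle <- 0L
  for (k in which(z >= 0 & z <= 5)) {
    for (i in seq_along(x)) for (j in seq_along(y)) {
      if (x[i]^2 + y[j]^2 <= 100) n_oracle <- n_oracle + 1L
    }
  }
  expect_identical(sum(cy$occupancy), n_oracle)
  # every column inside the radius has the full [0, 5] mm span
  inside <- outer(x^2, y^2, `+`) <= 100
  span <- apply(cy$occupancy, c(1, 2), sum)
  expect_true(all(span[inside] == sum(z >= 0 & z <= 5)))
  expect_true(all(span[!inside] == 0))
})

test_that("cylinder rejects geometry outside the training ranges or grid", {
  expect_error(make_cylinder(45, 5), "training range")
  expect_error(make_cylinder(20, 0.5), "training range")
  g_small <- grid_spec(nx = 101, ny = 101, z_max_mm = 10)
  expect_silent(make_cylinder(40, 10, g_small))
})

test_that("unperturbed spherical harmonic is a scaled cut sphere", {
  p <- sh_params(l = 5, m = 2, amplitude = 0)
  s <- make_spherical_harmonic(p, target_mm = c(24, 24, 6))
  ext <- shape_extents(s)
  expect_equal(unname(ext["depth"]), 6, tolerance = 1e-9)
  expect_lte(abs(ext["width_x"] - 24), 0.5)   # half-voxel quantization
  expect_lte(abs(ext["width_y"] - 24), 0.5)
})

test_that("perturbed spherical harmonics are star-convex for amplitude <= 0.3", {
  set.seed(11)
  for (rep in 1:5) {
    l <- sample(2:20, 1); m <- sample(seq(-l, l), 1)
    p <- sh_params(l, m, amplitude = 0.3)
    # ray-marching oracle: the radial surface is single-valued by
    # construction; check r stays positive and each voxel ray crosses the
    # boundary once (monotone membership along random rays)
    th <- runif(200, 0, pi); ph <- runif(200, 0, 2 * pi)
    r_surf <- sfdepth:::sh_radius(p, th, ph)
    expect_true(all(r_surf > 0))
    for (k in sample(200, 20)) {
      rr <- seq(0.05, 15, by = 0.05)
      inside <- rr <= r_surf[k]
      expect_true(all(diff(inside) <= 0))  # once outside, stays outside
    }
  }
})

test_that("excessive perturbation amplitude is rejected", {
  p <- sh_params(l = 2, m = 0, amplitude = 4)
  expect_error(make_spherical_harmonic(p, c(20, 20, 5)),
               "non-positive surface radius")
})

test_that("shape generation is deterministic under a fixed seed", {
  make <- function() {
    set.seed(314)
    generate_shape(draw_shape_params("csh"))
  }
  s1 <- make(); s2 <- make()
  expect_identical(s1$occupancy, s2$occupancy)
})

test_that("CSH with four identical quadrants equals the single-harmonic shape", {
  q <- sh_params(l = 6, m = 3, amplitude = 0.25)
  cp <- csh_params(quadrants = list(q, q, q, q), c1 = 8, c2 = -8,
                   rot_deg = c(0, 0, 0), z_shift_mm = 0,
                   target_mm = c(22, 26, 7))
  s_csh <- make_csh(cp)
  s_sh <- make_spherical_harmonic(q, target_mm = c(22, 26, 7))
  expect_identical(s_csh$occupancy, s_sh$occupancy)
})

test_that("CSH z-shift buries part of the footprint", {
  set.seed(21)
  q <- replicate(4, sh_params(sample(2:8, 1), 0, 0.2), simplify = FALSE)
  cp <- csh_params(quadrants = q, c1 = 10, c2 = -10,
                   rot_deg = c(15, -10, 40), z_shift_mm = 2,
                   target_mm = c(25, 25, 8))
  s <- make_csh(cp)
  z <- grid_z(s$grid)
  k0 <- which(z >= 0)[1]  # shallowest tissue slice
  top <- s$occupancy[, , k0]
  fp <- apply(s$occupancy, c(1, 2), any)
  # column-scan oracle: buried columns have tumor but no surface-slice voxel
  expect_gt(sum(fp & !top), 0)
})

test_that("training shape draws respect the width/depth ranges after cutting", {
  set.seed(5)
  n <- 60
  for (family in c("cylinder", "sh", "csh")) {
    for (i in seq_len(n / 3)) {
      s <- generate_shape(draw_shape_params(family))
      ext <- shape_extents(s)
      expect_gte(ext["depth"], 1 - 0.51)
      expect_lte(ext["depth"], 10 + 0.51)
      expect_gte(ext["width_x"], 10 - 0.51)
      expect_lte(ext["width_x"], 40 + 0.51)
      zc <- grid_z(s$grid)
      expect_false(any(s$occupancy[, , zc < 0]))
    }
  }
})

test_that("cut_above_surface is idempotent and never adds occupancy", {
  set.seed(8)
  s <- generate_shape(draw_shape_params("sh"))
  # half-buried sphere probe: push occupancy above the surface artificially
  occ <- s$occupancy
  occ[, , 1:5] <- occ[, , 15:19]
  s$occupancy <- occ
  cut1 <- cut_above_surface(s)
  cut2 <- cut_above_surface(cut1)
  expect_identical(cut1$occupancy, cut2$occupancy)
  expect_true(all(cut1$occupancy <= s$occupancy))
  zc <- grid_z(s$grid)
  expect_false(any(cut1$occupancy[, , zc < 0]))
})

test_that("ground-truth depth follows the iceberg rule for buried and protruding columns", {
  g <- grid_spec()
  z <- grid_z(g)
  occ <- array(FALSE, dim = c(g$nx, g$ny, g$nz))
  # buried column: occupied 2..7 mm -> depth = 7 (distance surface->bottom)
  occ[10, 10, z > 2 & z < 7] <- TRUE
  # protruding column: occupied -2..5 mm -> depth = 7 (top->bottom)
  occ[20, 20, z > -2 & z < 5] <- TRUE
  s <- shape_volume(g, occ)
  gt <- ground_truth_maps(s, concentration = 3, allow_protrusion = TRUE)
  expect_equal(gt$depth_mm[10, 10], 7)
  expect_equal(gt$depth_mm[20, 20], 7)
  expect_equal(gt$concentration[10, 10], 3)
  expect_equal(sum(gt$depth_mm > 0), 2)
  # protrusion must be opted into
  expect_error(ground_truth_maps(s, 3), "allow_protrusion")
})

test_that("ground-truth maps equal the per-column brute-force oracle on random CSHs", {
  set.seed(40)
  for (i in 1:6) {
    s <- generate_shape(draw_shape_params("csh"))
    gt <- ground_truth_maps(s, concentration = 5)
    or <- gt_oracle(s, 5)
    expect_identical(gt$depth_mm, or$depth_mm)
    expect_identical(gt$concentration, or$concentration)
  }
})
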