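# Independent numerical oracles used to validate the closed-form physics and
# the map computations. These deliberately share no code with the package
# implementations beyond the optical-property definitions.

# 1-D finite-difference diffusion solver for the modulated planar source:
#   -D phi'' + (mu_a + D k^2) phi = mu_s' exp(-mu_tr z),
# partial-current boundary phi(0) = z_b phi'(0) via a second-order ghost
# node, phi(L) = 0. Returns the depth grid, fluence, and the diffuse
# reflectance D phi'(0).
fd_diffusion <- function(mu_a, mu_sp, fx, n = 1.4, L = 100, N = 20000) {
  pr <- optical_props(mu_a, mu_sp, n)
  h <- L / N
  z <- (0:N) * h
  k2 <- (2 * pi * fx)^2
  D <- pr$D
  cdiag <- mu_a + D * k2
  rhs <- pr$mu_s_prime * exp(-pr$mu_tr * z)
  a <- rep(-D / h^2, N + 1)   # sub-diagonal
  b <- rep(2 * D / h^2 + cdiag, N + 1)
  cc <- rep(-D / h^2, N + 1)  # super-diagonal
  # ghost node at -h: phi(-h) = phi(h) - 2h/zb * phi(0) (second order)
  b[1] <- 2 * D / h^2 + cdiag + 2 * D / (h * pr$zb)
  cc[1] <- -2 * D / h^2
  a[N + 1] <- 0; b[N + 1] <- 1; cc[N + 1] <- 0; rhs[N + 1] <- 0
  # Thomas algorithm
  for (i in 2:(N + 1)) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    rhs[i] <- rhs[i] - w * rhs[i - 1]
  }
  phi <- numeric(N + 1)
  phi[N + 1] <- rhs[N + 1] / b[N + 1]
  for (i in N:1) phi[i] <- (rhs[i] - cc[i] * phi[i + 1]) / b[i]
  # one-sided second-order derivative at the surface
  dphi0 <- (-3 * phi[1] + 4 * phi[2] - phi[3]) / (2 * h)
  list(z = z, phi = phi, rd = D * dphi0)
}

# Lateral integral of the escape kernel, by fine radial quadrature:
# E_plane(z) = int E(rho, z) 2 pi rho drho.
escape_plane_integral <- function(z, props, rmax = 150, dr = 0.01) {
  r <- seq(dr / 2, rmax, by = dr)
  sum(emission_escape(r, z, props) * 2 * pi * r * dr)
}

# 1-D quadrature oracle for the center-pixel fluorescence of a laterally
# infinite slab of thickness d at the surface.
slab_fluorescence_1d <- function(d, fx, props, fluor, dz = 0.005) {
  z <- seq(dz / 2, d, by = dz)
  phi <- excitation_fluence(z, fx, props)
  epl <- vapply(z, escape_plane_integral, numeric(1), props = props)
  fluor$eta * fluor$mu_af * sum(phi * epl * dz)
}

# Brute-force per-column scan of an occupancy lattice (the depth-rule
# oracle): independent double loop, no vectorization shared with the
# implementation.
gt_oracle <- function(shape, concentration, allow_protrusion = FALSE) {
  g <- shape$grid
  z <- grid_z(g)
  depth <- matrix(0, g$nx, g$ny)
  conc <- matrix(0, g$nx, g$ny)
  for (i in seq_len(g$nx)) for (j in seq_len(g$ny)) {
    occ <- which(shape$occupancy[i, j, ])
    if (!length(occ)) next
    ztop <- z[min(occ)] - g$dz_mm / 2
    zbot <- z[max(occ)] + g$dz_mm / 2
    depth[i, j] <- if (allow_protrusion) zbot - min(ztop, 0) else zbot
    conc[i, j] <- concentration
  }
  list(depth_mm = depth, concentration = conc)
}

# Exhaustive enumeration of the two-sided Wilcoxon signed-rank null for
# paired differences d (no zeros/ties assumed).
signed_rank_exact_p <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% rk
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Small deterministic test fixtures
unit_props <- function() optical_props(0.0045, 1.0)

tiny_model_config <- function() {
  model_config(op_widths = c(4, 6), vol_filters = 2, fl_widths = c(6, 6),
               trunk_width = 8, head_widths = c(4, 2))
}
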