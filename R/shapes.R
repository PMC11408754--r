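# Synthetic "iceberg" tumor shape families: cylinders, spherical-harmonic
# perturbed spheres, and composite spherical harmonics (CSH). All shapes are
# voxelized on the simulation grid (voxel occupied iff its center lies inside
# the surface) and cut flush with the tissue surface at z = 0.

TRAIN_WIDTH_MM <- c(10, 40)
TRAIN_DEPTH_MM <- c(1, 10)

#' Right circular cylinder flush with the tissue surface
#'
#' Axis along z, top face at z = 0, centered laterally on the grid.
#'
#' @param width_mm Cylinder diameter in mm, inside the 10-40 mm training range.
#' @param depth_mm Cylinder height (depth below the surface) in mm, 1-10 mm.
#' @param grid An [grid_spec()] object.
#' @return An `sfdi_shape`.
#' @export
make_cylinder <- function(width_mm, depth_mm, grid = grid_spec()) {
  if (width_mm < TRAIN_WIDTH_MM[1] || width_mm > TRAIN_WIDTH_MM[2]) {
    stop("cylinder width ", width_mm, " mm outside the 10-40 mm training range")
  }
  if (depth_mm < TRAIN_DEPTH_MM[1] || depth_mm > TRAIN_DEPTH_MM[2]) {
    stop("cylinder depth ", depth_mm, " mm outside the 1-10 mm training range")
  }
  if (width_mm > grid$nx * grid$pixel_mm || depth_mm > grid$z_max_mm) {
    stop("cylinder of width ", width_mm, " mm / depth ", depth_mm,
         " mm does not fit the grid extent")
  }
  x <- grid_x(grid); y <- grid_y(grid); z <- grid_z(grid)
  lat <- outer(x^2, y^2, `+`) <= (width_mm / 2)^2
  inz <- z >= 0 & z <= depth_mm
  occ <- array(FALSE, dim = c(grid$nx, grid$ny, grid$nz))
  occ[, , inz] <- lat
  shape_volume(grid, occ, list(family = "cylinder", width_mm = width_mm,
                               depth_mm = depth_mm))
}

#' Spherical-harmonic shape parameters
#'
#' @param l Degree index, 2-20.
#' @param m Order index, `|m| <= l`.
#' @param amplitude Unitless perturbation scale of the radial surface
#'   `r = R (1 + amplitude * Y_lm)`.
#' @param base_radius_mm Base radius before scaling (10 mm).
#' @return An object of class `sh_params`.
#' @export
sh_params <- function(l, m, amplitude, base_radius_mm = 10) {
  stopifnot(l >= 2, l <= 20, abs(m) <= l, base_radius_mm > 0)
  structure(list(l = as.integer(l), m = as.integer(m),
                 amplitude = amplitude, base_radius_mm = base_radius_mm),
            class = "sh_params")
}

# Radial surface r(theta, phi) of one perturbed sphere; errors if the
# perturbation drives the radius non-positive anywhere on a dense probe.
sh_radius <- function(params, theta, phi) {
  params$base_radius_mm *
    (1 + params$amplitude * real_sph_harm(params$l, params$m, theta, phi))
}

check_positive_radius <- function(radius_fun) {
  th <- seq(0, pi, length.out = 91)
  ph <- seq(0, 2 * pi, length.out = 181)[-181]
  g <- expand.grid(th = th, ph = ph)
  r <- radius_fun(g$th, g$ph)
  if (any(r <= 0)) {
    stop("perturbation amplitude produces a non-positive surface radius")
  }
  invisible(TRUE)
}

rot_xyz <- function(rx_deg, ry_deg, rz_deg) {
  a <- rx_deg * pi / 180; b <- ry_deg * pi / 180; c <- rz_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# Dense surface sampling of a star-convex radial solid after rotation and
# z-shift, clipped at the surface plane z = 0 (z down). Returns the lateral
# bounding box of the kept part, its lateral center, and its maximum depth,
# all in unscaled mm. The kept part is { z >= 0 }; rays crossing the plane
# contribute their clipped intersection points, which trace the cut face
# boundary, so the extents are exact for star-convex solids up to sampling.
star_extents <- function(radius_fun, rot = diag(3), z_shift = 0,
                         n_theta = 121, n_phi = 241) {
  th <- seq(0, pi, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi)[-n_phi]
  g <- expand.grid(th = th, ph = ph)
  r <- radius_fun(g$th, g$ph)
  p <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
             r * cos(g$th))
  q <- p %*% t(rot)
  q[, 3] <- q[, 3] + z_shift
  kept <- q[, 3] >= 0
  if (!any(kept)) stop("shape lies entirely above the surface after transform")
  xs <- q[kept, 1]; ys <- q[kept, 2]; zs <- q[kept, 3]
  if (any(!kept)) {
    # clip the center->surface segments at z = 0 (center sits at (0,0,z_shift))
    qc <- q[!kept, , drop = FALSE]
    t <- z_shift / (z_shift - qc[, 3])
    xs <- c(xs, t * qc[, 1])
    ys <- c(ys, t * qc[, 2])
  }
  list(ext_x = max(xs) - min(xs), ext_y = max(ys) - min(ys),
       cx = (max(xs) + min(xs)) / 2, cy = (max(ys) + min(ys)) / 2,
       max_z = max(zs))
}

# Voxelize a star-convex radial solid under the transform
#   world = Scale_about_surface( Rot(body) + (0,0,z_shift) ) - lateral recenter
# keeping only z >= 0 (the cut). scale = c(sx, sy, sz); center = c(cx, cy)
# is the unscaled lateral bbox center used for recentering.
voxelize_star <- function(radius_fun, rot, z_shift, scale, center, grid,
                          half_extent_mm) {
  x <- grid_x(grid); y <- grid_y(grid); z <- grid_z(grid)
  xi <- which(abs(x) <= half_extent_mm[1] + grid$pixel_mm)
  yi <- which(abs(y) <= half_extent_mm[2] + grid$pixel_mm)
  zi <- which(z >= 0 & z <= half_extent_mm[3] + grid$dz_mm)
  occ <- array(FALSE, dim = c(grid$nx, grid$ny, grid$nz))
  if (!length(xi) || !length(yi) || !length(zi)) return(occ)
  cand <- expand.grid(x = x[xi], y = y[yi], z = z[zi])
  p <- cbind(cand$x / scale[1] + center[1],
             cand$y / scale[2] + center[2],
             cand$z / scale[3] - z_shift)
  u <- p %*% rot  # rot is orthonormal: p %*% rot == t(t(rot) %*% t(p))
  ru <- sqrt(rowSums(u^2))
  theta <- acos(pmin(1, pmax(-1, ifelse(ru > 0, u[, 3] / pmax(ru, 1e-300), 1))))
  phi <- atan2(u[, 2], u[, 1])
  inside <- ru <= radius_fun(theta, phi)
  occ[xi, yi, zi] <- array(inside, dim = c(length(xi), length(yi), length(zi)))
  occ
}

#' Spherical-harmonic tumor shape
#'
#' A sphere of base radius 10 mm with its radial surface perturbed by one real
#' spherical harmonic, anisotropically scaled to target extents, and cut flush
#' with the tissue surface at z = 0.
#'
#' @param params An [sh_params()] object.
#' @param target_mm Numeric `c(width_x, width_y, depth)` in mm; widths in
#'   10-40 mm, depth in 1-10 mm.
#' @param grid An [grid_spec()] object.
#' @return An `sfdi_shape`.
#' @export
make_spherical_harmonic <- function(params, target_mm, grid = grid_spec()) {
  stopifnot(inherits(params, "sh_params"), length(target_mm) == 3)
  rf <- function(th, ph) sh_radius(params, th, ph)
  check_positive_radius(rf)
  ext <- star_extents(rf)
  scale <- c(target_mm[1] / ext$ext_x, target_mm[2] / ext$ext_y,
             target_mm[3] / ext$max_z)
  occ <- voxelize_star(rf, diag(3), 0, scale, c(ext$cx, ext$cy), grid,
                       c(target_mm[1] / 2, target_mm[2] / 2, target_mm[3]))
  sh <- shape_volume(grid, occ,
                     list(family = "sh", l = params$l, m = params$m,
                          amplitude = params$amplitude,
                          width_x = target_mm[1], width_y = target_mm[2],
                          depth = target_mm[3]))
  cut_above_surface(sh)
}

#' Composite spherical harmonic (CSH) parameters
#'
#' Four spherical-harmonic quadrant fields merged along two reciprocal curves
#' `x*y = c1` and `x*y = c2` (`c1 > 0 > c2`, mm^2) in the XY plane, then
#' rotated, shifted downward, scaled, and cut at the surface.
#'
#' @param quadrants List of four [sh_params()] objects.
#' @param c1,c2 Reciprocal-curve constants, mm^2; `c1 > 0 > c2`.
#' @param rot_deg Numeric `c(rx, ry, rz)` Euler rotations in degrees.
#' @param z_shift_mm Downward shift in mm (creates buried tumor regions).
#' @param target_mm Numeric `c(width_x, width_y, depth)` in mm.
#' @param blend_mm Width of the cosine transition band, mm.
#' @return An object of class `csh_params`.
#' @export
csh_params <- function(quadrants, c1, c2, rot_deg, z_shift_mm, target_mm,
                       blend_mm = 2) {
  stopifnot(length(quadrants) == 4,
            all(vapply(quadrants, inherits, TRUE, "sh_params")),
            c1 > 0, c2 < 0, length(rot_deg) == 3, z_shift_mm >= 0,
            length(target_mm) == 3)
  structure(list(quadrants = quadrants, c1 = c1, c2 = c2, rot_deg = rot_deg,
                 z_shift_mm = z_shift_mm, target_mm = target_mm,
                 blend_mm = blend_mm),
            class = "csh_params")
}

# smooth 0->1 cosine ramp of u over [lo, hi]
cos_ramp <- function(u, lo, hi) {
  t <- pmin(1, pmax(0, (u - lo) / (hi - lo)))
  0.5 * (1 - cos(pi * t))
}

# Blended radial surface of the CSH. Quadrant membership is driven by
# t = x*y evaluated at base radius: t >= c1 selects the "outer" pair of
# curvilinear quadrants, t <= c2 the opposite pair, and the band between the
# two reciprocal curves ramps smoothly; the two branches of each pair are
# split by the sign of x with a cosine ramp of width blend_mm so the surface
# stays continuous everywhere.
csh_radius <- function(params, theta, phi) {
  r0 <- params$quadrants[[1]]$base_radius_mm
  x <- r0 * sin(theta) * cos(phi)
  y <- r0 * sin(theta) * sin(phi)
  t <- x * y
  w_t <- cos_ramp(t, params$c2, params$c1)      # 0 at/below c2, 1 at/above c1
  w_x <- cos_ramp(x, -params$blend_mm, params$blend_mm)
  r1 <- sh_radius(params$quadrants[[1]], theta, phi)  # x>0, t>=c1
  r2 <- sh_radius(params$quadrants[[2]], theta, phi)  # x<0, t>=c1
  r3 <- sh_radius(params$quadrants[[3]], theta, phi)  # x>0, t<=c2
  r4 <- sh_radius(params$quadrants[[4]], theta, phi)  # x<0, t<=c2
  w_x * (w_t * r1 + (1 - w_t) * r3) + (1 - w_x) * (w_t * r2 + (1 - w_t) * r4)
}

#' Composite spherical-harmonic tumor shape
#'
#' @param params A [csh_params()] object.
#' @param grid An [grid_spec()] object.
#' @return An `sfdi_shape`.
#' @export
make_csh <- function(params, grid = grid_spec()) {
  stopifnot(inherits(params, "csh_params"))
  rf <- function(th, ph) csh_radius(params, th, ph)
  check_positive_radius(rf)
  rot <- rot_xyz(params$rot_deg[1], params$rot_deg[2], params$rot_deg[3])
  ext <- star_extents(rf, rot, params$z_shift_mm)
  tg <- params$target_mm
  scale <- c(tg[1] / ext$ext_x, tg[2] / ext$ext_y, tg[3] / ext$max_z)
  occ <- voxelize_star(rf, rot, params$z_shift_mm, scale, c(ext$cx, ext$cy),
                       grid, c(tg[1] / 2, tg[2] / 2, tg[3]))
  if (!any(occ)) stop("CSH is empty after cutting at the surface")
  sh <- shape_volume(grid, occ, list(family = "csh", params = params))
  cut_above_surface(sh)
}

#' Draw random shape parameters for one training family
#'
#' Uses the current R random-number stream. Widths are uniform on 10-40 mm,
#' depths uniform on 1-10 mm. Spherical-harmonic degree is uniform on 2-20
#' with order uniform on -l..l, and perturbation amplitude uniform on
#' 0.1-0.3. CSH rotations are uniform on +/-30 deg about X and Y and +/-180
#' deg about Z, with a 0-2 mm downward shift.
#'
#' @param family One of `"cylinder"`, `"sh"`, `"csh"`.
#' @return A named list of parameters understood by [generate_shape()].
#' @export
draw_shape_params <- function(family = c("cylinder", "sh", "csh")) {
  family <- match.arg(family)
  if (family == "cylinder") {
    return(list(family = "cylinder",
                width_mm = runif(1, TRAIN_WIDTH_MM[1], TRAIN_WIDTH_MM[2]),
                depth_mm = runif(1, TRAIN_DEPTH_MM[1], TRAIN_DEPTH_MM[2])))
  }
  target <- c(runif(2, TRAIN_WIDTH_MM[1], TRAIN_WIDTH_MM[2]),
              runif(1, TRAIN_DEPTH_MM[1], TRAIN_DEPTH_MM[2]))
  draw_sh <- function() {
    l <- sample(2:20, 1)
    sh_params(l = l, m = sample(seq(-l, l), 1), amplitude = runif(1, 0.1, 0.3))
  }
  if (family == "sh") {
    return(list(family = "sh", params = draw_sh(), target_mm = target))
  }
  list(family = "csh",
       params = csh_params(
         quadrants = list(draw_sh(), draw_sh(), draw_sh(), draw_sh()),
         c1 = runif(1, 2, 20), c2 = -runif(1, 2, 20),
         rot_deg = c(runif(2, -30, 30), runif(1, -180, 180)),
         z_shift_mm = runif(1, 0, 2),
         target_mm = target))
}

#' Generate one shape from drawn parameters
#'
#' @param params A list from [draw_shape_params()].
#' @param grid An [grid_spec()] object.
#' @return An `sfdi_shape`.
#' @export
generate_shape <- function(params, grid = grid_spec()) {
  switch(params$family,
         cylinder = make_cylinder(params$width_mm, params$depth_mm, grid),
         sh = make_spherical_harmonic(params$params, params$target_mm, grid),
         csh = make_csh(params$params, grid),
         stop("unknown shape family: ", params$family))
}

#' Per-pixel ground-truth depth and concentration maps
#'
#' Depth follows the iceberg convention: for each image column containing
#' tumor, `ztop` is the shallowest occupied z (top voxel face) and `zbot` the
#' deepest (bottom voxel face); depth is `zbot - min(ztop, 0)`, i.e. the
#' distance from the surface plane to the bottom of the tumor for flush or
#' buried columns, and the full top-to-bottom thickness for protruding
#' columns (patient-mesh mode). Columns without tumor have depth 0. The
#' concentration map is the homogeneous tumor concentration over the
#' footprint and 0 elsewhere.
#'
#' @param shape An `sfdi_shape`.
#' @param concentration Fluorophore concentration in ug/mL (> 0).
#' @param allow_protrusion Permit occupancy above the surface (z < 0); if
#'   `FALSE`, such occupancy is an error (training shapes are cut).
#' @return List with `depth_mm` and `concentration` matrices (nx x ny), class
#'   `sfdi_gt`.
#' @export
ground_truth_maps <- function(shape, concentration, allow_protrusion = FALSE) {
  stopifnot(inherits(shape, "sfdi_shape"), concentration > 0)
  g <- shape$grid
  z <- grid_z(g)
  occ2 <- matrix(shape$occupancy, g$nx * g$ny, g$nz)
  any_occ <- rowSums(occ2) > 0
  kmin <- rep(NA_integer_, g$nx * g$ny)
  kmax <- rep(NA_integer_, g$nx * g$ny)
  for (k in seq_len(g$nz)) {
    hit <- occ2[, k]
    kmin[hit & is.na(kmin)] <- k
    kmax[hit] <- k
  }
  ztop <- z[kmin] - g$dz_mm / 2
  zbot <- z[kmax] + g$dz_mm / 2
  if (!allow_protrusion && any(ztop < 0, na.rm = TRUE)) {
    stop("occupancy above the surface (z < 0): cut the shape or set ",
         "allow_protrusion = TRUE")
  }
  depth <- numeric(g$nx * g$ny)
  depth[any_occ] <- zbot[any_occ] - pmin(ztop[any_occ], 0)
  conc <- numeric(g$nx * g$ny)
  conc[any_occ] <- concentration
  structure(list(depth_mm = matrix(depth, g$nx, g$ny),
                 concentration = matrix(conc, g$nx, g$ny)),
            class = "sfdi_gt")
}
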