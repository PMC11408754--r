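#' Simulation grid specification
#'
#' Defines the voxel lattice all shapes and images live on. The lateral field
#' of view is `nx * pixel_mm` by `ny * pixel_mm` (default 50.5 mm x 50.5 mm at
#' 0.5 mm/pixel, covering the 50 mm field of view), centered on the optical
#' axis. The axial coordinate `z` increases downward into the tissue; the
#' tissue surface is the plane `z = 0`, so "protruding above the surface"
#' means `z < 0`. Voxel centers sit at half-step offsets.
#'
#' @param nx,ny Lateral pixel counts.
#' @param pixel_mm Lateral resolution in mm/pixel.
#' @param z_min_mm,z_max_mm Axial extent in mm (z positive downward).
#' @param dz_mm Axial resolution in mm.
#' @return An object of class `sfdi_grid`.
#' @export
grid_spec <- function(nx = 101L, ny = 101L, pixel_mm = 0.5,
                      z_min_mm = -5, z_max_mm = 15, dz_mm = 0.5) {
  stopifnot(nx >= 1, ny >= 1, pixel_mm > 0, dz_mm > 0, z_max_mm > z_min_mm)
  if (nx * pixel_mm < 50 || ny * pixel_mm < 50) {
    stop("grid must cover at least the 50 mm field of view")
  }
  if (z_max_mm < 10) {
    stop("z_max_mm must be >= 10 mm to hold the maximum training depth")
  }
  g <- list(nx = as.integer(nx), ny = as.integer(ny), pixel_mm = pixel_mm,
            z_min_mm = z_min_mm, z_max_mm = z_max_mm, dz_mm = dz_mm,
            nz = as.integer(round((z_max_mm - z_min_mm) / dz_mm)))
  class(g) <- "sfdi_grid"
  g
}

#' @export
print.sfdi_grid <- function(x, ...) {
  cat(sprintf("<sfdi_grid> %d x %d px @ %.2f mm, z in [%g, %g] mm @ %.2f mm\n",
              x$nx, x$ny, x$pixel_mm, x$z_min_mm, x$z_max_mm, x$dz_mm))
  invisible(x)
}

#' Voxel-center coordinates of a simulation grid
#'
#' Lateral axes are centered on zero; the axial axis starts at `z_min_mm`
#' with centers at half-step offsets (z positive downward).
#'
#' @param grid An [grid_spec()] object.
#' @return Numeric vector of voxel-center coordinates in mm.
#' @export
grid_x <- function(grid) (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$pixel_mm

#' @rdname grid_x
#' @export
grid_y <- function(grid) (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$pixel_mm

#' @rdname grid_x
#' @export
grid_z <- function(grid) grid$z_min_mm + (seq_len(grid$nz) - 0.5) * grid$dz_mm

#' Construct a voxelized shape volume
#'
#' @param grid An `sfdi_grid`.
#' @param occupancy Logical array of dim `c(nx, ny, nz)`.
#' @param provenance Named list tagging the shape family, generation
#'   parameters and seed.
#' @return An object of class `sfdi_shape`.
#' @export
shape_volume <- function(grid, occupancy, provenance = list()) {
  stopifnot(inherits(grid, "sfdi_grid"),
            identical(dim(occupancy), c(grid$nx, grid$ny, grid$nz)))
  structure(list(grid = grid, occupancy = occupancy, provenance = provenance),
            class = "sfdi_shape")
}

#' @export
print.sfdi_shape <- function(x, ...) {
  cat(sprintf("<sfdi_shape> family=%s, %d occupied voxels\n",
              x$provenance$family %||% "?", sum(x$occupancy)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove occupancy above the tissue surface
#'
#' Zeroes every voxel with center `z < 0`, making the shape flush with (or
#' buried below) the surface. Idempotent; never adds occupancy.
#'
#' @param shape An `sfdi_shape`.
#' @return The cut `sfdi_shape`.
#' @export
cut_above_surface <- function(shape) {
  stopifnot(inherits(shape, "sfdi_shape"))
  zc <- grid_z(shape$grid)
  shape$occupancy[, , zc < 0] <- FALSE
  shape
}

#' Measured lateral/axial extents of a shape volume
#'
#' Axis-aligned bounding-box side lengths of the occupied voxels, counting
#' full voxel widths (outer faces), plus the maximum ground-truth depth.
#'
#' @param shape An `sfdi_shape`.
#' @return Named numeric vector with `width_x`, `width_y`, `depth` (mm).
#' @export
shape_extents <- function(shape) {
  occ <- shape$occupancy
  if (!any(occ)) return(c(width_x = 0, width_y = 0, depth = 0))
  ix <- which(apply(occ, 1, any)); iy <- which(apply(occ, 2, any))
  g <- shape$grid
  gt <- ground_truth_maps(shape, concentration = 1, allow_protrusion = TRUE)
  c(width_x = (max(ix) - min(ix) + 1) * g$pixel_mm,
    width_y = (max(iy) - min(iy) + 1) * g$pixel_mm,
    depth = max(gt$depth_mm))
}
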