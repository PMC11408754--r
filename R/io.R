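# On-disk containers: multi-frame TIFF for image stacks (one frame per
# channel per spatial frequency) with a JSON sidecar carrying the frequency
# list, optical/fluorophore parameters and seeds. Pixels are quantized to
# 32-bit samples relative to the recorded per-channel scale (relative
# precision 2^-32 of the channel maximum); sidecar numbers round-trip
# exactly (17 significant digits).

#' Write / read an SFDI stack
#'
#' Frames are ordered reflectance at each fx, then fluorescence at each fx.
#' Intensities are divided by the recorded per-channel scale so they fit the
#' unit range of the TIFF container and are restored on read.
#'
#' @param stack An `sfdi_stack`.
#' @param path Path of the `.tif` file; the JSON sidecar sits next to it.
#' @return `write_stack` invisibly returns `path`; `read_stack` returns the
#'   stack.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "sfdi_stack"))
  nfx <- length(stack$fx)
  scale_r <- max(stack$reflectance, 1e-12)
  scale_f <- max(stack$fluorescence, 1e-12)
  frames <- c(
    lapply(seq_len(nfx), function(i) stack$reflectance[, , i] / scale_r),
    lapply(seq_len(nfx), function(i) stack$fluorescence[, , i] / scale_f))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- c(stack$meta, list(fx = stack$fx, scale_reflectance = scale_r,
                             scale_fluorescence = scale_f))
  jsonlite::write_json(meta, sidecar_path(path), digits = I(17),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  nfx <- length(meta$fx)
  d <- dim(frames[[1]])
  refl <- array(0, dim = c(d[1], d[2], nfx))
  fluo <- array(0, dim = c(d[1], d[2], nfx))
  for (i in seq_len(nfx)) {
    refl[, , i] <- frames[[i]] * meta$scale_reflectance
    fluo[, , i] <- frames[[nfx + i]] * meta$scale_fluorescence
  }
  keep <- setdiff(names(meta), c("fx", "scale_reflectance", "scale_fluorescence"))
  structure(list(fx = meta$fx, reflectance = refl, fluorescence = fluo,
                 meta = meta[keep]),
            class = "sfdi_stack")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write / read ground-truth maps as TIFF + JSON
#'
#' @param gt An `sfdi_gt` object.
#' @param path Path of the `.tif` file.
#' @return `write_gt` invisibly returns `path`; `read_gt` returns the maps.
#' @export
write_gt <- function(gt, path) {
  scale_d <- max(gt$depth_mm, 1e-12)
  scale_c <- max(gt$concentration, 1e-12)
  tiff::writeTIFF(list(gt$depth_mm / scale_d, gt$concentration / scale_c),
                  path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale_depth = scale_d, scale_conc = scale_c),
                       sidecar_path(path), digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gt
#' @export
read_gt <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  structure(list(depth_mm = frames[[1]] * meta$scale_depth,
                 concentration = frames[[2]] * meta$scale_conc),
            class = "sfdi_gt")
}

#' Export a shape volume as an ASCII STL surface
#'
#' Emits the boundary faces of the occupied voxel lattice (voxel-exact
#' surface, suitable for inspection or 3D printing).
#'
#' @param shape An `sfdi_shape`.
#' @param path Output `.stl` path.
#' @return Invisibly `path`.
#' @export
write_shape_stl <- function(shape, path) {
  g <- shape$grid
  occ <- shape$occupancy
  x <- grid_x(g); y <- grid_y(g); z <- grid_z(g)
  hx <- g$pixel_mm / 2; hz <- g$dz_mm / 2
  tris <- list()
  emit_quad <- function(p1, p2, p3, p4) {
    tris[[length(tris) + 1]] <<- rbind(p1, p2, p3)
    tris[[length(tris) + 1]] <<- rbind(p1, p3, p4)
  }
  pad <- array(FALSE, dim = dim(occ) + 2)
  pad[2:(g$nx + 1), 2:(g$ny + 1), 2:(g$nz + 1)] <- occ
  idx <- which(occ, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    cx <- x[i]; cy <- y[j]; cz <- z[k]
    nb <- function(di, dj, dk) pad[i + 1 + di, j + 1 + dj, k + 1 + dk]
    if (!nb(-1, 0, 0)) emit_quad(c(cx - hx, cy - hx, cz - hz), c(cx - hx, cy + hx, cz - hz),
                                 c(cx - hx, cy + hx, cz + hz), c(cx - hx, cy - hx, cz + hz))
    if (!nb(1, 0, 0)) emit_quad(c(cx + hx, cy - hx, cz - hz), c(cx + hx, cy - hx, cz + hz),
                                c(cx + hx, cy + hx, cz + hz), c(cx + hx, cy + hx, cz - hz))
    if (!nb(0, -1, 0)) emit_quad(c(cx - hx, cy - hx, cz - hz), c(cx - hx, cy - hx, cz + hz),
                                 c(cx + hx, cy - hx, cz + hz), c(cx + hx, cy - hx, cz - hz))
    if (!nb(0, 1, 0)) emit_quad(c(cx - hx, cy + hx, cz - hz), c(cx + hx, cy + hx, cz - hz),
                                c(cx + hx, cy + hx, cz + hz), c(cx - hx, cy + hx, cz + hz))
    if (!nb(0, 0, -1)) emit_quad(c(cx - hx, cy - hx, cz - hz), c(cx + hx, cy - hx, cz - hz),
                                 c(cx + hx, cy + hx, cz - hz), c(cx - hx, cy + hx, cz - hz))
    if (!nb(0, 0, 1)) emit_quad(c(cx - hx, cy - hx, cz + hz), c(cx - hx, cy + hx, cz + hz),
                                c(cx + hx, cy + hx, cz + hz), c(cx + hx, cy - hx, cz + hz))
  }
  soup <- do.call(rbind, tris)
  write_mesh(soup_to_mesh(soup), path)
}
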