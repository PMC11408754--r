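# Seeded dataset assembly: draw randomized shapes and optics, simulate SFDI
# stacks, LUT-invert property maps, and bundle network-ready samples with a
# manifest. Randomized quantities follow the training distributions: width
# U(10,40) mm, depth U(1,10) mm, mu_a U(0.0015,0.015) mm^-1,
# mu_s' U(0.75,2) mm^-1, concentration U(1,10) ug/mL, and, when background
# fluorescence is enabled, bg_fraction U(0.001,0.5).

TRAIN_MUA <- c(0.0015, 0.015)
TRAIN_MUS <- c(0.75, 2)
TRAIN_CONC <- c(1, 10)
TRAIN_BG <- c(0.001, 0.5)

sample_seed <- function(global_seed, i) {
  (as.numeric(global_seed) * 1000003 + i * 7919) %% 2147483647
}

make_record <- function(id, family, params, mu_a, mu_s, conc, bg, seed,
                        split = "train") {
  list(id = id, family = family, params = params, mu_a = mu_a,
       mu_s_prime = mu_s, concentration = conc, bg_fraction = bg,
       seed = seed, split = split)
}

simulate_record <- function(rec, grid, lut, photon_budget = 1e4) {
  set.seed(rec$seed)
  shape <- generate_shape(rec$params, grid)
  props <- optical_props(rec$mu_a, rec$mu_s_prime)
  fl <- fluor_spec(rec$concentration)
  sim <- simulate_sample(shape, props, fl, bg_fraction = rec$bg_fraction,
                         photon_budget = photon_budget)
  pm <- optical_property_maps(sim$stack, lut)
  list(record = rec, stack = sim$stack, prop_maps = pm, gt = sim$gt)
}

#' Generate a seeded training dataset
#'
#' Draws `n` samples of one shape family with randomized geometry, optics,
#' and concentration, simulates the SFDI stacks, and recovers the per-pixel
#' optical property maps that form the network's first input arm. Samples
#' are split 90/10 into train/validation under the global seed.
#'
#' @param family `"cylinder"`, `"sh"`, or `"csh"`.
#' @param n Number of samples.
#' @param bg_enabled Randomize background fluorescence (phantom-style
#'   training variant).
#' @param seed Global seed; every sample derives its own stream from it.
#' @param grid An [grid_spec()] object.
#' @param lut An `sfdi_lut` (built once if omitted).
#' @param photon_budget Poisson photon budget per frame.
#' @param val_frac Validation fraction.
#' @param out_dir Optional directory: per-sample TIFF/JSON containers and a
#'   JSON-lines manifest are written there.
#' @return Object of class `sfdi_dataset`: `manifest` (data.frame),
#'   `samples` (list of simulated records) and the `lut` used.
#' @export
generate_training_set <- function(family, n, bg_enabled = FALSE, seed = 1,
                                  grid = grid_spec(), lut = NULL,
                                  photon_budget = 1e4, val_frac = 0.1,
                                  out_dir = NULL) {
  stopifnot(family %in% c("cylinder", "sh", "csh"), n >= 0)
  if (is.null(lut)) lut <- build_lut()
  set.seed(seed)
  n_val <- floor(n * val_frac)
  split <- rep("train", n)
  if (n_val > 0) split[sample.int(n, n_val)] <- "val"
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- sample_seed(seed, i)
    set.seed(si)
    params <- draw_shape_params(family)
    rec <- make_record(
      id = sprintf("%s-%05d", family, i), family = family, params = params,
      mu_a = runif(1, TRAIN_MUA[1], TRAIN_MUA[2]),
      mu_s = runif(1, TRAIN_MUS[1], TRAIN_MUS[2]),
      conc = runif(1, TRAIN_CONC[1], TRAIN_CONC[2]),
      bg = if (bg_enabled) runif(1, TRAIN_BG[1], TRAIN_BG[2]) else 0,
      seed = si, split = split[i])
    samples[[i]] <- simulate_record(rec, grid, lut, photon_budget)
  }
  ds <- structure(list(manifest = manifest_frame(samples), samples = samples,
                       lut = lut, grid = grid, seed = seed),
                  class = "sfdi_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Generate a seeded test dataset
#'
#' Family mode draws `n` shapes of one family; mesh mode cycles over the
#' supplied watertight meshes, drawing scale targets (widths 10-40 mm,
#' depths 1-10 mm) and a random z rotation (-180 to 180 deg) per
#' augmentation. Optics are fixed at the evaluation conditions
#' (mu_a = 0.0045 mm^-1, mu_s' = 1 mm^-1, concentration 5 ug/mL) unless
#' overridden. Samples whose realized geometry leaves the training ranges
#' are flagged `out_of_range` in the manifest.
#'
#' @param family_or_meshes A family name or a list of `sfdi_mesh` objects.
#' @param n Number of samples.
#' @param seed Global seed.
#' @param mu_a,mu_s_prime,concentration Fixed evaluation optics.
#' @param bg_enabled Randomize background fluorescence.
#' @param grid,lut,photon_budget As in [generate_training_set()].
#' @param mesh_scale If `FALSE`, meshes are voxelized unscaled/unrotated.
#' @return An `sfdi_dataset`.
#' @export
generate_test_set <- function(family_or_meshes, n, seed = 1,
                              mu_a = 0.0045, mu_s_prime = 1,
                              concentration = 5, bg_enabled = FALSE,
                              grid = grid_spec(), lut = NULL,
                              photon_budget = 1e4, mesh_scale = TRUE) {
  if (is.null(lut)) lut <- build_lut()
  mesh_mode <- is.list(family_or_meshes) && !is.character(family_or_meshes)
  if (mesh_mode) {
    meshes <- family_or_meshes
    errs <- lapply(meshes, function(m) tryCatch({
      check_watertight(m); NULL
    }, error = function(e) conditionMessage(e)))
    bad <- !vapply(errs, is.null, TRUE)
    if (any(bad)) {
      stop("mesh validation failed:\n", paste(sprintf("  mesh %d: %s",
           which(bad), unlist(errs[bad])), collapse = "\n"))
    }
  }
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- sample_seed(seed + 13, i)
    set.seed(si)
    bg <- if (bg_enabled) runif(1, TRAIN_BG[1], TRAIN_BG[2]) else 0
    if (mesh_mode) {
      mesh <- meshes[[(i - 1) %% length(meshes) + 1]]
      if (mesh_scale) {
        tg <- c(runif(2, TRAIN_WIDTH_MM[1], TRAIN_WIDTH_MM[2]),
                runif(1, TRAIN_DEPTH_MM[1], TRAIN_DEPTH_MM[2]))
        rotz <- runif(1, -180, 180)
        v <- mesh$vertices
        a <- rotz * pi / 180
        xr <- cos(a) * v[, 1] - sin(a) * v[, 2]
        yr <- sin(a) * v[, 1] + cos(a) * v[, 2]
        # bbox-based targets: lateral sides to the width draws, axial span
        # (including protrusion) to the depth draw
        sx <- tg[1] / diff(range(xr))
        sy <- tg[2] / diff(range(yr))
        sz <- tg[3] / (max(v[, 3]) - min(min(v[, 3]), 0))
        params <- list(family = "mesh", mesh = mesh,
                       scale_xyz = c(sx, sy, sz), rot_z_deg = rotz)
      } else {
        params <- list(family = "mesh", mesh = mesh,
                       scale_xyz = c(1, 1, 1), rot_z_deg = 0)
      }
      rec <- make_record(sprintf("mesh-%05d", i), "mesh", params,
                         mu_a, mu_s_prime, concentration, bg, si, "test")
      set.seed(si)
      shape <- augment_mesh(params$mesh, params$scale_xyz, params$rot_z_deg,
                            grid)
      props <- optical_props(mu_a, mu_s_prime)
      sim <- simulate_sample(shape, props, fluor_spec(concentration),
                             bg_fraction = bg, photon_budget = photon_budget)
      pm <- optical_property_maps(sim$stack, lut)
      samples[[i]] <- list(record = rec, stack = sim$stack, prop_maps = pm,
                           gt = sim$gt)
    } else {
      params <- draw_shape_params(family_or_meshes)
      rec <- make_record(sprintf("%s-test-%05d", family_or_meshes, i),
                         family_or_meshes, params, mu_a, mu_s_prime,
                         concentration, bg, si, "test")
      samples[[i]] <- simulate_record(rec, grid, lut, photon_budget)
    }
  }
  structure(list(manifest = manifest_frame(samples), samples = samples,
                 lut = lut, grid = grid, seed = seed),
            class = "sfdi_dataset")
}

manifest_frame <- function(samples) {
  if (!length(samples)) {
    return(data.frame(id = character(), family = character(),
                      split = character(), mu_a = numeric(),
                      mu_s_prime = numeric(), concentration = numeric(),
                      bg_fraction = numeric(), seed = numeric(),
                      width_x = numeric(), width_y = numeric(),
                      depth = numeric(), out_of_range = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(samples, function(s) {
    r <- s$record
    dep <- max(s$gt$depth_mm)
    ext <- shape_footprint_extents(s$gt)
    data.frame(id = r$id, family = r$family, split = r$split, mu_a = r$mu_a,
               mu_s_prime = r$mu_s_prime, concentration = r$concentration,
               bg_fraction = r$bg_fraction, seed = r$seed,
               width_x = ext[1], width_y = ext[2], depth = dep,
               out_of_range = dep > TRAIN_DEPTH_MM[2] + 1e-9 ||
                 max(ext) > TRAIN_WIDTH_MM[2] + 1e-9,
               stringsAsFactors = FALSE)
  }))
}

# lateral bounding-box sides of the ground-truth footprint, in mm
shape_footprint_extents <- function(gt, pixel_mm = 0.5) {
  fp <- gt$depth_mm > 0
  if (!any(fp)) return(c(0, 0))
  ix <- range(which(apply(fp, 1, any)))
  iy <- range(which(apply(fp, 2, any)))
  c((ix[2] - ix[1] + 1) * pixel_mm, (iy[2] - iy[1] + 1) * pixel_mm)
}

#' Network input/target arrays for one simulated sample
#'
#' @param sample One element of an `sfdi_dataset`'s `samples` list, or a
#'   record with on-disk paths (from [read_dataset()]).
#' @return List with `inputs` (list `props` nx x ny x 2,
#'   `fluorescence` nx x ny x 6) and `targets` (list `depth_mm`,
#'   `concentration`).
#' @export
load_sample <- function(sample) {
  if (!is.null(sample$paths)) {
    stack <- read_stack(sample$paths$stack)
    pm <- read_gt_propmaps(sample$paths$props)
    gt <- read_gt(sample$paths$gt)
  } else {
    stack <- sample$stack; pm <- sample$prop_maps; gt <- sample$gt
  }
  list(inputs = list(
         props = array(c(pm$mu_a, pm$mu_s_prime),
                       dim = c(dim(pm$mu_a), 2)),
         fluorescence = stack$fluorescence),
       targets = list(depth_mm = gt$depth_mm,
                      concentration = gt$concentration))
}

#' Write / read a dataset directory
#'
#' One subdirectory per sample holding the stack, property-map, and
#' ground-truth containers, plus a JSON-lines manifest at the root.
#'
#' @param ds An `sfdi_dataset`.
#' @param dir Output directory.
#' @return `write_dataset` invisibly returns `dir`; `read_dataset` returns a
#'   dataset whose samples carry `paths` for lazy [load_sample()].
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in ds$samples) {
    sd <- file.path(dir, s$record$id)
    dir.create(sd, showWarnings = FALSE)
    write_stack(s$stack, file.path(sd, "stack.tif"))
    write_propmaps(s$prop_maps, file.path(sd, "props.tif"))
    write_gt(s$gt, file.path(sd, "gt.tif"))
  }
  con <- file(file.path(dir, "manifest.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ds$manifest))) {
    writeLines(jsonlite::toJSON(as.list(ds$manifest[i, ]), digits = I(17),
                                auto_unbox = TRUE), con)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  lines <- readLines(file.path(dir, "manifest.jsonl"))
  rows <- lapply(lines, jsonlite::fromJSON)
  manifest <- do.call(rbind, lapply(rows, as.data.frame))
  samples <- lapply(rows, function(r) {
    sd <- file.path(dir, r$id)
    list(record = r,
         paths = list(stack = file.path(sd, "stack.tif"),
                      props = file.path(sd, "props.tif"),
                      gt = file.path(sd, "gt.tif")))
  })
  structure(list(manifest = manifest, samples = samples, lut = NULL,
                 grid = NULL, seed = NA),
            class = "sfdi_dataset")
}

write_propmaps <- function(pm, path) {
  sa <- max(pm$mu_a, 1e-12); ss <- max(pm$mu_s_prime, 1e-12)
  tiff::writeTIFF(list(pm$mu_a / sa, pm$mu_s_prime / ss,
                       pm$flag * 1), path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale_mu_a = sa, scale_mu_s = ss),
                       sidecar_path(path), digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

read_gt_propmaps <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  structure(list(mu_a = frames[[1]] * meta$scale_mu_a,
                 mu_s_prime = frames[[2]] * meta$scale_mu_s,
                 flag = frames[[3]] > 0.5),
            class = "sfdi_propmaps")
}
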