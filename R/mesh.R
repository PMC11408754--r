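# Closed-surface mesh handling for patient-style tumor contours: minimal
# STL/PLY readers and writers, a watertightness check, a z-column parity
# voxelizer, and generators for synthetic surrogate meshes (the stand-ins for
# patient contours, which are not publicly available).

#' Construct a triangle mesh
#'
#' @param vertices Numeric matrix `n x 3` (mm; z positive downward).
#' @param faces Integer matrix `m x 3` of 1-based vertex indices.
#' @return An object of class `sfdi_mesh`.
#' @export
mesh3 <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "sfdi_mesh")
}

#' @export
print.sfdi_mesh <- function(x, ...) {
  cat(sprintf("<sfdi_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a mesh is closed (watertight) and consistently oriented
#'
#' Every undirected edge must be shared by exactly two faces, with opposite
#' directions. Errors with a description of the defect otherwise.
#'
#' @param mesh An `sfdi_mesh`.
#' @return Invisibly `TRUE`.
#' @export
check_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(undirected)
  bad <- cnt != 2
  if (any(bad)) {
    stop("non-watertight mesh: ", sum(cnt == 1), " boundary edge(s) and ",
         sum(cnt > 2), " over-shared edge(s)")
  }
  directed <- paste(e[, 1], e[, 2])
  if (any(table(directed) != 1)) {
    stop("inconsistently oriented mesh: some directed edge occurs twice")
  }
  invisible(TRUE)
}

#' Read a surface mesh from STL (ASCII or binary) or ASCII PLY
#'
#' Triangle-soup vertices are merged by exact coordinate match so the
#' connectivity checks can run.
#'
#' @param path File path; format chosen by extension (.stl / .ply).
#' @return An `sfdi_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") read_stl(path)
  else if (ext == "ply") read_ply_ascii(path)
  else stop("unsupported mesh format: .", ext)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 80)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    length(grep("facet", readLines(path, n = 20, warn = FALSE))) > 0
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  soup_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  if (nrow(nums) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  nums
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  out <- matrix(0, ntri * 3, 3)
  for (i in seq_len(ntri)) {
    readBin(con, "numeric", n = 3, size = 4, endian = "little")  # normal
    v <- readBin(con, "numeric", n = 9, size = 4, endian = "little")
    out[(3 * i - 2):(3 * i), ] <- matrix(v, 3, 3, byrow = TRUE)
    readBin(con, "raw", n = 2)
  }
  out
}

soup_to_mesh <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "_")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  mesh3(verts, faces)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file")
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  body <- lines[(hdr_end + 1):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                 function(p) as.integer(p[2:4]) + 1L))
  mesh3(verts, faces)
}

#' Write a mesh to ASCII STL or ASCII PLY
#'
#' @param mesh An `sfdi_mesh`.
#' @param path Output path; format chosen by extension.
#' @return Invisibly `path`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "stl") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid sfdepth", con)
    for (i in seq_len(nrow(f))) {
      p <- v[f[i, ], , drop = FALSE]
      n <- pracma::cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid sfdepth", con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

# Parity voxelization: cast a z ray through each image column, collect
# triangle crossings, and fill between successive crossing pairs. Column
# coordinates get a tiny deterministic offset so rays avoid vertices and
# edges (generic position).
voxelize_mesh <- function(mesh, grid = grid_spec()) {
  v <- mesh$vertices; f <- mesh$faces
  x <- grid_x(grid) + 1.23e-6 * grid$pixel_mm
  y <- grid_y(grid) + 2.47e-6 * grid$pixel_mm
  z <- grid_z(grid)
  hits_col <- vector("list", nrow(f)); hits_z <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    xi <- which(x >= min(p[, 1]) & x <= max(p[, 1]))
    yi <- which(y >= min(p[, 2]) & y <= max(p[, 2]))
    if (!length(xi) || !length(yi)) next
    denom <- (p[2, 2] - p[3, 2]) * (p[1, 1] - p[3, 1]) +
      (p[3, 1] - p[2, 1]) * (p[1, 2] - p[3, 2])
    if (abs(denom) < 1e-12) next  # vertical triangle: zero projected area
    px <- rep(x[xi], times = length(yi))
    py <- rep(y[yi], each = length(xi))
    a <- ((p[2, 2] - p[3, 2]) * (px - p[3, 1]) +
            (p[3, 1] - p[2, 1]) * (py - p[3, 2])) / denom
    b <- ((p[3, 2] - p[1, 2]) * (px - p[3, 1]) +
            (p[1, 1] - p[3, 1]) * (py - p[3, 2])) / denom
    cc <- 1 - a - b
    ins <- a >= 0 & b >= 0 & cc >= 0
    if (!any(ins)) next
    zhit <- a[ins] * p[1, 3] + b[ins] * p[2, 3] + cc[ins] * p[3, 3]
    cols <- (rep(xi, times = length(yi)) +
               (rep(yi, each = length(xi)) - 1L) * grid$nx)[ins]
    hits_col[[i]] <- cols; hits_z[[i]] <- zhit
  }
  cols <- unlist(hits_col); zs <- unlist(hits_z)
  occ <- array(FALSE, dim = c(grid$nx, grid$ny, grid$nz))
  if (!length(cols)) return(shape_volume(grid, occ, list(family = "mesh")))
  occ2 <- matrix(FALSE, grid$nx * grid$ny, grid$nz)
  sp <- split(zs, cols)
  idx <- as.integer(names(sp))
  for (j in seq_along(sp)) {
    cz <- sort(sp[[j]])
    npair <- length(cz) %/% 2
    if (npair == 0) next
    inside <- rep(FALSE, grid$nz)
    for (k in seq_len(npair)) {
      inside <- inside | (z > cz[2 * k - 1] & z < cz[2 * k])
    }
    occ2[idx[j], ] <- inside
  }
  shape_volume(grid, array(occ2, dim = c(grid$nx, grid$ny, grid$nz)),
               list(family = "mesh"))
}

#' Voxelize a (possibly protruding) tumor mesh with augmentation
#'
#' The mesh is recentered laterally on the grid, rotated about the z axis,
#' scaled per-axis (lateral scaling about the grid center, axial scaling
#' about the surface plane z = 0 so protrusion is preserved), and voxelized.
#' No cut is applied: patient-style meshes may protrude above the surface.
#'
#' @param mesh An `sfdi_mesh`; must be watertight.
#' @param scale_xyz Numeric multiplicative scale factors `c(sx, sy, sz)`.
#' @param rot_z_deg Rotation about the z axis in degrees.
#' @param grid An [grid_spec()] object.
#' @return An `sfdi_shape` (occupancy may include z < 0).
#' @export
augment_mesh <- function(mesh, scale_xyz = c(1, 1, 1), rot_z_deg = 0,
                         grid = grid_spec()) {
  check_watertight(mesh)
  v <- mesh$vertices
  ctr <- c((max(v[, 1]) + min(v[, 1])) / 2, (max(v[, 2]) + min(v[, 2])) / 2)
  v[, 1] <- v[, 1] - ctr[1]; v[, 2] <- v[, 2] - ctr[2]
  a <- rot_z_deg * pi / 180
  xr <- cos(a) * v[, 1] - sin(a) * v[, 2]
  yr <- sin(a) * v[, 1] + cos(a) * v[, 2]
  v <- cbind(xr * scale_xyz[1], yr * scale_xyz[2], v[, 3] * scale_xyz[3])
  out <- voxelize_mesh(mesh3(v, mesh$faces), grid)
  out$provenance <- list(family = "mesh", scale_xyz = scale_xyz,
                         rot_z_deg = rot_z_deg)
  out
}

# Closed UV-sphere triangulation of a star-convex radial function.
uv_sphere_mesh <- function(radius_fun, n_theta = 24, n_phi = 36,
                           center_z = 0) {
  th <- pi * seq_len(n_theta - 1) / n_theta
  ph <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  g <- expand.grid(ph = ph, th = th)  # phi fastest: ring-major vertex order
  r <- radius_fun(g$th, g$ph)
  verts <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
                 r * cos(g$th) + center_z)
  rN <- radius_fun(0, 0); rS <- radius_fun(pi, 0)
  verts <- rbind(c(0, 0, rN + center_z), verts, c(0, 0, -rS + center_z))
  npole <- 1L
  spole <- nrow(verts)
  ring <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1]] <- c(npole, ring(1, j), ring(1, j + 1))
  }
  for (i in seq_len(n_theta - 2)) {
    for (j in seq_len(n_phi)) {
      a1 <- ring(i, j); a2 <- ring(i, j + 1)
      b1 <- ring(i + 1, j); b2 <- ring(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a1, b1, b2)
      faces[[length(faces) + 1]] <- c(a1, b2, a2)
    }
  }
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1]] <- c(spole, ring(n_theta - 1, j + 1),
                                    ring(n_theta - 1, j))
  }
  mesh3(verts, do.call(rbind, faces))
}

#' Synthetic surrogate tumor mesh
#'
#' A watertight, organically lobed closed surface standing in for patient
#' tumor contours (which are not publicly deposited). Built as a UV-sphere
#' triangulation of a randomly perturbed radial function, with the center
#' placed below the surface plane so that part of the shape protrudes above
#' z = 0. Uses the current R random-number stream.
#'
#' @param base_radius_mm Base radius in mm.
#' @param protrusion_frac Fraction of the radius protruding above the
#'   surface plane.
#' @return An `sfdi_mesh`.
#' @export
synthetic_tumor_mesh <- function(base_radius_mm = 8, protrusion_frac = 0.25) {
  l1 <- sample(2:6, 1); m1 <- sample(seq(-l1, l1), 1)
  l2 <- sample(3:8, 1); m2 <- sample(seq(-l2, l2), 1)
  a1 <- runif(1, 0.05, 0.2); a2 <- runif(1, 0.05, 0.15)
  rf <- function(th, ph) {
    base_radius_mm * (1 + a1 * real_sph_harm(l1, m1, th, ph) +
                        a2 * real_sph_harm(l2, m2, th, ph))
  }
  check_positive_radius(rf)
  # z down: protrusion means the top of the shape sits at z < 0
  uv_sphere_mesh(rf, center_z = base_radius_mm * (1 - protrusion_frac))
}

#' Unit cube mesh (12 triangles)
#'
#' Convenience closed mesh spanning `[0, 1]^3`, mainly for validating the
#' voxelizer against analytic volumes.
#'
#' @return An `sfdi_mesh`.
#' @export
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces with outward orientation, indices into the expand.grid order
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),  # x = 0 ... orientations fixed below if needed
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6))
  mesh3(v, f)
}
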