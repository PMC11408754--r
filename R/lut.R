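# Two-frequency lookup-table inversion: recover per-pixel (mu_a, mu_s') from
# diffuse reflectance at fx = 0 and 0.2 mm^-1. The forward map is the
# closed-form diffusion reflectance; the inverse is a damped, vectorized
# Newton iteration on that map, seeded from the nearest tabulated node and
# clamped to the tabulated domain with an out-of-domain flag.

LUT_FX <- c(0, 0.2)

#' Build the two-frequency SFDI lookup table
#'
#' Tabulates `(Rd at fx = 0, Rd at fx = 0.2)` on a dense property grid and
#' verifies injectivity of the forward map by checking that measurement-space
#' near-coincidences only occur between neighbouring property nodes.
#'
#' @param mu_a_range,mu_s_range Property ranges (mm^-1); must cover the
#'   training ranges 0.0015-0.015 and 0.75-2.
#' @param n_nodes Nodes per axis (default 200).
#' @param n Refractive index.
#' @return Object of class `sfdi_lut`.
#' @export
build_lut <- function(mu_a_range = c(0.0015, 0.015),
                      mu_s_range = c(0.75, 2),
                      n_nodes = 200L, n = 1.4) {
  if (n_nodes < 2) stop("degenerate LUT grid: need at least 2 nodes per axis")
  if (mu_a_range[1] > 0.0015 || mu_a_range[2] < 0.015 ||
      mu_s_range[1] > 0.75 || mu_s_range[2] < 2) {
    stop("LUT ranges must cover the training property ranges")
  }
  mu_a <- seq(mu_a_range[1], mu_a_range[2], length.out = n_nodes)
  mu_s <- seq(mu_s_range[1], mu_s_range[2], length.out = n_nodes)
  gr <- expand.grid(mu_a = mu_a, mu_s = mu_s)
  pr <- optical_props(gr$mu_a, gr$mu_s, n)
  rd0 <- diffuse_reflectance(pr, LUT_FX[1])
  rd2 <- diffuse_reflectance(pr, LUT_FX[2])
  lut <- structure(list(mu_a = mu_a, mu_s = mu_s,
                        rd0 = matrix(rd0, n_nodes, n_nodes),
                        rd2 = matrix(rd2, n_nodes, n_nodes),
                        n = n),
                   class = "sfdi_lut")
  check_lut_injective(lut)
  lut
}

# Injectivity audit: bin measurement pairs on a fine lattice; any two nodes
# falling in the same bin must be grid neighbours (within 2 steps), otherwise
# distinct properties map to indistinguishable measurements.
check_lut_injective <- function(lut) {
  na <- length(lut$mu_a); ns <- length(lut$mu_s)
  v0 <- as.vector(lut$rd0); v2 <- as.vector(lut$rd2)
  tol0 <- diff(range(v0)) * 1e-4; tol2 <- diff(range(v2)) * 1e-4
  key <- paste(round(v0 / tol0), round(v2 / tol2))
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup)) {
    ia <- (dup - 1L) %% na + 1L; is <- (dup - 1L) %/% na + 1L
    for (k in split(seq_along(dup), key[dup])) {
      if (max(ia[k]) - min(ia[k]) > 2 || max(is[k]) - min(is[k]) > 2) {
        stop("LUT injectivity failure: non-neighbouring nodes (mu_a idx ",
             paste(range(ia[k]), collapse = "-"), ", mu_s idx ",
             paste(range(is[k]), collapse = "-"),
             ") are indistinguishable in measurement space")
      }
    }
  }
  invisible(TRUE)
}

#' Serialize / load a lookup table
#'
#' Plain-text JSON container holding the grids and tables.
#'
#' @param lut An `sfdi_lut`.
#' @param path File path.
#' @return `write_lut` invisibly returns `path`; `read_lut` returns the LUT.
#' @export
write_lut <- function(lut, path) {
  obj <- list(mu_a = lut$mu_a, mu_s = lut$mu_s, n = lut$n,
              rd0 = as.vector(lut$rd0), rd2 = as.vector(lut$rd2))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  na <- length(obj$mu_a)
  structure(list(mu_a = obj$mu_a, mu_s = obj$mu_s,
                 rd0 = matrix(obj$rd0, na), rd2 = matrix(obj$rd2, na),
                 n = obj$n),
            class = "sfdi_lut")
}

#' Invert reflectance pairs to optical properties
#'
#' Vectorized over pixels. Each `(Rd0, Rd0.2)` pair is inverted by damped
#' Newton iteration on the closed-form forward map, seeded from the nearest
#' LUT node. Results are clamped to the tabulated domain; pixels that fall
#' outside it (or fail to converge) are flagged.
#'
#' @param rd0,rd2 Reflectance at fx = 0 and 0.2 mm^-1 (vectors, same length).
#' @param lut An `sfdi_lut`.
#' @return List with numeric `mu_a`, `mu_s_prime` and logical `flag`.
#' @export
invert_pixel <- function(rd0, rd2, lut) {
  if (any(!is.finite(rd0)) || any(!is.finite(rd2))) {
    stop("non-finite reflectance input to LUT inversion")
  }
  stopifnot(length(rd0) == length(rd2))
  npx <- length(rd0)
  a_lim <- range(lut$mu_a); s_lim <- range(lut$mu_s)
  # nearest-node seed (coarse subsample of the table keeps this cheap)
  sub <- unique(round(seq(1, length(lut$mu_a), length.out = 20)))
  ssub <- unique(round(seq(1, length(lut$mu_s), length.out = 20)))
  cand <- expand.grid(ia = sub, is = ssub)
  c0 <- lut$rd0[cbind(cand$ia, cand$is)]
  c2 <- lut$rd2[cbind(cand$ia, cand$is)]
  sc0 <- diff(range(c0)); sc2 <- diff(range(c2))
  best <- max.col(-(outer(rd0, c0, `-`) / sc0)^2 -
                    (outer(rd2, c2, `-`) / sc2)^2, ties.method = "first")
  mu_a <- lut$mu_a[cand$ia[best]]
  mu_s <- lut$mu_s[cand$is[best]]
  fwd <- function(a, s) {
    pr <- optical_props(a, s, lut$n)
    list(r0 = diffuse_reflectance(pr, LUT_FX[1]),
         r2 = diffuse_reflectance(pr, LUT_FX[2]))
  }
  for (it in 1:15) {
    f <- fwd(mu_a, mu_s)
    e0 <- f$r0 - rd0; e2 <- f$r2 - rd2
    ha <- pmax(mu_a * 1e-4, 1e-8); hs <- mu_s * 1e-4
    fa <- fwd(mu_a + ha, mu_s); fs <- fwd(mu_a, mu_s + hs)
    j11 <- (fa$r0 - f$r0) / ha; j12 <- (fs$r0 - f$r0) / hs
    j21 <- (fa$r2 - f$r2) / ha; j22 <- (fs$r2 - f$r2) / hs
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- 1e-300
    da <- (e0 * j22 - e2 * j12) / det
    ds <- (e2 * j11 - e0 * j21) / det
    # damp steps to a fraction of the domain so iterates stay tame
    da <- pmin(pmax(da, -0.3 * diff(a_lim)), 0.3 * diff(a_lim))
    ds <- pmin(pmax(ds, -0.3 * diff(s_lim)), 0.3 * diff(s_lim))
    mu_a <- mu_a - da
    mu_s <- mu_s - ds
    # keep iterates in a loose halo of the domain
    mu_a <- pmin(pmax(mu_a, a_lim[1] * 0.2), a_lim[2] * 3)
    mu_s <- pmin(pmax(mu_s, s_lim[1] * 0.2), s_lim[2] * 3)
  }
  f <- fwd(mu_a, mu_s)
  resid <- abs(f$r0 - rd0) / pmax(rd0, 1e-6) + abs(f$r2 - rd2) / pmax(rd2, 1e-6)
  out_dom <- mu_a < a_lim[1] | mu_a > a_lim[2] |
    mu_s < s_lim[1] | mu_s > s_lim[2]
  flag <- out_dom | resid > 1e-3 | !is.finite(resid)
  list(mu_a = pmin(pmax(mu_a, a_lim[1]), a_lim[2]),
       mu_s_prime = pmin(pmax(mu_s, s_lim[1]), s_lim[2]),
       flag = flag)
}

#' Per-pixel optical property maps from an SFDI stack
#'
#' Applies [invert_pixel()] to the reflectance frames at fx = 0 and
#' 0.2 mm^-1.
#'
#' @param stack An `sfdi_stack`.
#' @param lut An `sfdi_lut`.
#' @return Object of class `sfdi_propmaps`: matrices `mu_a`, `mu_s_prime`
#'   and logical `flag` (nx x ny).
#' @export
optical_property_maps <- function(stack, lut) {
  stopifnot(inherits(stack, "sfdi_stack"))
  i0 <- which(abs(stack$fx - LUT_FX[1]) < 1e-9)
  i2 <- which(abs(stack$fx - LUT_FX[2]) < 1e-9)
  if (!length(i0) || !length(i2)) {
    stop("stack lacks the reflectance frequencies 0 and 0.2 mm^-1")
  }
  d <- dim(stack$reflectance)[1:2]
  inv <- invert_pixel(as.vector(stack$reflectance[, , i0]),
                      as.vector(stack$reflectance[, , i2]), lut)
  structure(list(mu_a = matrix(inv$mu_a, d[1], d[2]),
                 mu_s_prime = matrix(inv$mu_s_prime, d[1], d[2]),
                 flag = matrix(inv$flag, d[1], d[2])),
            class = "sfdi_propmaps")
}
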