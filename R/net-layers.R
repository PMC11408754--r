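# Convolutional layer primitives for the two-arm depth/concentration network.
# All layers are 3x3 (or 3x3x6 volumetric), stride 1, zero-padded to preserve
# the 101x101 lateral extent. Forward passes gather patches with the C++
# im2col kernel and push the matmul through BLAS; backward passes recompute
# the patch matrix from the cached layer input, obtain dX as a convolution
# with spatially flipped, channel-transposed weights, and dW as
# col(X) %*% dY.

conv2d_fwd <- function(x, w, b, want_col = FALSE) {
  d <- dim(x)
  col <- im2col3(x, d[1], d[2], d[3])
  co <- dim(w)[4]
  y <- crossprod(col, matrix(w, ncol = co))
  y <- y + rep(b, each = nrow(y))
  y <- array(y, dim = c(d[1], d[2], co))
  if (want_col) list(y = y, col = col) else y
}

# col, when supplied, is the patch matrix of x cached from the forward
# pass; want_dx = FALSE skips the input gradient (entry layers).
conv2d_bwd <- function(x, w, dy, col = NULL, want_dx = TRUE) {
  d <- dim(x); co <- dim(w)[4]
  dym <- matrix(dy, ncol = co)
  if (is.null(col)) col <- im2col3(x, d[1], d[2], d[3])
  dw <- array(col %*% dym, dim = dim(w))
  db <- colSums(dym)
  if (!want_dx) return(list(dx = NULL, dw = dw, db = db))
  # dX = dY (*) flip(W)^T : flip both spatial taps, swap in/out channels
  wf <- aperm(w[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  coly <- im2col3(dy, d[1], d[2], co)
  dx <- array(crossprod(coly, matrix(wf, ncol = d[3])), dim = d)
  list(dx = dx, dw = dw, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Volumetric 3x3x6 entry layer over the six-frequency fluorescence stack.
# The frequency axis is zero-padded (2 before, 3 after, stride 1) so the
# output keeps six frequency positions; kernel weights are shared across
# positions, so the layer is materialized as an equivalent 2-D convolution
# with a structured 3x3x6x(6F) weight tensor and per-filter biases
# replicated across positions. Output channel (d-1)*F + f is filter f at
# frequency position d; the caller's reshape-to-channels is this layout.
vol_expand_w <- function(wv) {
  nf <- dim(wv)[4]
  w2 <- array(0, dim = c(3, 3, 6, 6 * nf))
  for (d in 1:6) for (kd in 1:6) {
    ci <- d + kd - 3L
    if (ci >= 1 && ci <= 6) {
      w2[, , ci, (d - 1) * nf + seq_len(nf)] <- wv[, , kd, ]
    }
  }
  w2
}

vol_fwd <- function(x, wv, b, want_col = FALSE) {
  conv2d_fwd(x, vol_expand_w(wv), rep(b, times = 6), want_col)
}

vol_bwd <- function(x, wv, dy, col = NULL) {
  nf <- dim(wv)[4]
  g <- conv2d_bwd(x, vol_expand_w(wv), dy, col, want_dx = FALSE)
  dwv <- array(0, dim = dim(wv))
  for (d in 1:6) for (kd in 1:6) {
    ci <- d + kd - 3L
    if (ci >= 1 && ci <= 6) {
      dwv[, , kd, ] <- dwv[, , kd, ] + g$dw[, , ci, (d - 1) * nf + seq_len(nf)]
    }
  }
  db <- rowSums(matrix(g$db, nrow = nf))  # sum the shared bias over positions
  list(dx = g$dx, dw = dwv, db = db)
}

# Depthwise separable convolution: per-channel 3x3 depthwise stage followed
# by a 1x1 pointwise mix, one bias per output channel. wd is 9 x C (taps by
# channel), wp is C x Cout.
sep_fwd <- function(x, wd, wp, b, want_col = FALSE) {
  d <- dim(x)
  col <- im2col3(x, d[1], d[2], d[3])
  dwout <- matrix(colSums(array(col * as.vector(wd),
                                c(9, d[3] * d[1] * d[2]))), nrow = d[3])
  y <- crossprod(dwout, wp)
  y <- y + rep(b, each = nrow(y))
  y <- array(y, dim = c(d[1], d[2], ncol(wp)))
  if (want_col) list(y = y, col = col) else y
}

sep_bwd <- function(x, wd, wp, dy, col = NULL) {
  d <- dim(x); co <- ncol(wp)
  if (is.null(col)) col <- im2col3(x, d[1], d[2], d[3])
  dwout <- matrix(colSums(array(col * as.vector(wd),
                                c(9, d[3] * d[1] * d[2]))), nrow = d[3])
  dym <- matrix(dy, ncol = co)
  dwp <- dwout %*% dym
  db <- colSums(dym)
  ddwout <- wp %*% t(dym)  # C x HW, gradient into the depthwise output
  dwd <- matrix(rowSums(matrix(as.vector(col) *
                                 rep(as.vector(ddwout), each = 9),
                               nrow = 9 * d[3])), 9, d[3])
  # dX through the depthwise stage: per-channel conv with tap order
  # reversed (t -> 8 - t flips both spatial offsets)
  dd_arr <- array(t(ddwout), dim = d)
  coly <- im2col3(dd_arr, d[1], d[2], d[3])
  wd_flip <- wd[9:1, , drop = FALSE]
  dx_flat <- colSums(array(coly * as.vector(wd_flip),
                           c(9, d[3] * d[1] * d[2])))
  dx <- aperm(array(dx_flat, c(d[3], d[1], d[2])), c(2, 3, 1))
  list(dx = dx, dwd = dwd, dwp = dwp, db = db)
}
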