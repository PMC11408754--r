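# The two-arm ("Siamese") convolutional model: one arm ingests the two
# optical-property maps, the other the six-frequency fluorescence stack via
# a volumetric entry layer; the arms are concatenated, mixed by a separable
# convolution and a residual block, and split into two heads that taper the
# feature maps down to the per-pixel depth and concentration outputs. Every
# layer preserves the 101x101 lateral extent.

#' Network architecture configuration
#'
#' The default filter schedule is the committed architecture whose trainable
#' parameter total is exactly 920,514. Smaller schedules (for quick runs)
#' keep the same topology.
#'
#' @param op_widths Two filter counts of the property-arm convolutions.
#' @param vol_filters Number of 3x3x6 volumetric filters in the
#'   fluorescence-arm entry layer (reshaped to `6 * vol_filters` channels).
#' @param fl_widths Two filter counts of the fluorescence-arm convolutions.
#' @param trunk_width Output width of the separable convolution after
#'   concatenation (its residual block keeps this width).
#' @param head_widths Two filter counts of each head before the final
#'   single-map convolution.
#' @param input_hw Lateral input size.
#' @return Object of class `sfdi_model_config`.
#' @export
model_config <- function(op_widths = c(72, 96), vol_filters = 24,
                         fl_widths = c(96, 96), trunk_width = 96,
                         head_widths = c(64, 16), input_hw = c(101, 101)) {
  structure(list(op_widths = op_widths, vol_filters = vol_filters,
                 fl_widths = fl_widths, trunk_width = trunk_width,
                 head_widths = head_widths, input_hw = input_hw),
            class = "sfdi_model_config")
}

init_conv <- function(ci, co, gain = 2) {
  array(stats::rnorm(9 * ci * co, sd = sqrt(gain / (9 * ci))),
        dim = c(3, 3, ci, co))
}

#' Build the two-arm depth/concentration network
#'
#' Weights use He-normal initialization under the current R random stream.
#' If the configured schedule does not yield 920,514 trainable parameters a
#' warning reports the computed count (an error in strict mode).
#'
#' @param config A [model_config()].
#' @param strict Error (instead of warn) when the parameter count differs
#'   from 920,514.
#' @return Object of class `sfdi_model` with fields `params`, `config`,
#'   `norm` (input/target normalization constants).
#' @export
build_model <- function(config = model_config(), strict = FALSE) {
  a <- config$op_widths[1]; b <- config$op_widths[2]
  nf <- config$vol_filters
  c1 <- config$fl_widths[1]; e <- config$fl_widths[2]
  g <- config$trunk_width
  h1 <- config$head_widths[1]; h2 <- config$head_widths[2]
  cc <- b + e
  p <- list(
    op_c1_w = init_conv(2, a), op_c1_b = numeric(a),
    op_c2_w = init_conv(a, b), op_c2_b = numeric(b),
    op_r1_w = init_conv(b, b), op_r1_b = numeric(b),
    op_r2_w = init_conv(b, b), op_r2_b = numeric(b),
    fl_vol_w = array(stats::rnorm(9 * 6 * nf, sd = sqrt(2 / 54)),
                     dim = c(3, 3, 6, nf)),
    fl_vol_b = numeric(nf),
    fl_c1_w = init_conv(6 * nf, c1), fl_c1_b = numeric(c1),
    fl_c2_w = init_conv(c1, e), fl_c2_b = numeric(e),
    fl_r1_w = init_conv(e, e), fl_r1_b = numeric(e),
    fl_r2_w = init_conv(e, e), fl_r2_b = numeric(e),
    tr_dw = matrix(stats::rnorm(9 * cc, sd = sqrt(2 / 9)), 9, cc),
    tr_pw = matrix(stats::rnorm(cc * g, sd = sqrt(2 / cc)), cc, g),
    tr_b = numeric(g),
    tr_r1_w = init_conv(g, g), tr_r1_b = numeric(g),
    tr_r2_w = init_conv(g, g), tr_r2_b = numeric(g),
    hd_c1_w = init_conv(g, h1), hd_c1_b = numeric(h1),
    hd_c2_w = init_conv(h1, h2), hd_c2_b = numeric(h2),
    hd_c3_w = init_conv(h2, 1), hd_c3_b = 0.05,
    hc_c1_w = init_conv(g, h1), hc_c1_b = numeric(h1),
    hc_c2_w = init_conv(h1, h2), hc_c2_b = numeric(h2),
    hc_c3_w = init_conv(h2, 1), hc_c3_b = 0.05
  )
  model <- structure(list(params = p, config = config,
                          norm = default_norm()),
                     class = "sfdi_model")
  n_par <- parameter_count(model)
  if (n_par != 920514) {
    msg <- sprintf("schedule yields %d trainable parameters (committed full architecture has 920514)",
                   n_par)
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  model
}

#' Trainable parameter count of a model
#'
#' @param model An `sfdi_model`.
#' @return Integer number of trainable scalars.
#' @export
parameter_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

default_norm <- function() {
  list(mu_a_range = TRAIN_MUA, mu_s_range = TRAIN_MUS,
       fluor_scale = 1, fluor_log = FALSE, depth_scale = 10, conc_scale = 10)
}

#' Normalize network inputs
#'
#' Property maps are min-max scaled by the training property ranges. The
#' fluorescence stack is divided by the dataset-level scale (its 99th
#' percentile, fixed at training time). Setting `fluor_log = TRUE` in the
#' model's `norm` additionally passes the scaled stack through
#' `log1p(100 x)` (invertible); in side-by-side runs the linear scaling
#' trained better, so it is the default.
#'
#' @param inputs List with `props` (nx x ny x 2) and `fluorescence`
#'   (nx x ny x 6), as from [load_sample()].
#' @param norm Normalization constants (from a model).
#' @return List of normalized arrays.
#' @export
normalize_inputs <- function(inputs, norm) {
  pr <- inputs$props
  pr[, , 1] <- (pr[, , 1] - norm$mu_a_range[1]) / diff(norm$mu_a_range)
  pr[, , 2] <- (pr[, , 2] - norm$mu_s_range[1]) / diff(norm$mu_s_range)
  fl <- inputs$fluorescence / norm$fluor_scale
  if (isTRUE(norm$fluor_log)) fl <- log1p(100 * pmax(fl, 0))
  list(props = pr, fluorescence = fl)
}

resblock_fwd <- function(x, w1, b1, w2, b2, keep = TRUE) {
  c1 <- conv2d_fwd(x, w1, b1, want_col = keep)
  y1 <- if (keep) c1$y else c1
  a1 <- relu(y1)
  c2 <- conv2d_fwd(a1, w2, b2, want_col = keep)
  y2 <- if (keep) c2$y else c2
  s <- x + y2
  if (!keep) return(list(out = relu(s)))
  list(out = relu(s), y1 = y1, a1 = a1, s = s,
       col1 = c1$col, col2 = c2$col)
}

resblock_bwd <- function(x, w1, w2, cache, dout) {
  ds <- dout * (cache$s > 0)
  g2 <- conv2d_bwd(cache$a1, w2, ds, cache$col2)
  dy1 <- g2$dx * (cache$y1 > 0)
  g1 <- conv2d_bwd(x, w1, dy1, cache$col1)
  list(dx = ds + g1$dx, dw1 = g1$dw, db1 = g1$db, dw2 = g2$dw, db2 = g2$db)
}

# forward pass; with keep = TRUE, activations and patch matrices are cached
# for the backward pass
net_forward <- function(p, xp, xf, keep = TRUE) {
  cv <- function(x, w, b, nm) {
    r <- conv2d_fwd(x, w, b, want_col = keep)
    if (keep) { cc[[paste0("col_", nm)]] <<- r$col; r$y } else r
  }
  cc <- list()
  cc$y_op1 <- cv(xp, p$op_c1_w, p$op_c1_b, "op1"); a_op1 <- relu(cc$y_op1)
  cc$a_op1 <- a_op1
  cc$y_op2 <- cv(a_op1, p$op_c2_w, p$op_c2_b, "op2"); a_op2 <- relu(cc$y_op2)
  cc$a_op2 <- a_op2
  cc$op_res <- resblock_fwd(a_op2, p$op_r1_w, p$op_r1_b, p$op_r2_w, p$op_r2_b,
                            keep)
  op_out <- cc$op_res$out

  rv <- vol_fwd(xf, p$fl_vol_w, p$fl_vol_b, want_col = keep)
  if (keep) { cc$col_vol <- rv$col; cc$y_vol <- rv$y } else cc$y_vol <- rv
  a_vol <- relu(cc$y_vol)
  cc$a_vol <- a_vol
  cc$y_fl1 <- cv(a_vol, p$fl_c1_w, p$fl_c1_b, "fl1"); a_fl1 <- relu(cc$y_fl1)
  cc$a_fl1 <- a_fl1
  cc$y_fl2 <- cv(a_fl1, p$fl_c2_w, p$fl_c2_b, "fl2"); a_fl2 <- relu(cc$y_fl2)
  cc$a_fl2 <- a_fl2
  cc$fl_res <- resblock_fwd(a_fl2, p$fl_r1_w, p$fl_r1_b, p$fl_r2_w, p$fl_r2_b,
                            keep)
  fl_out <- cc$fl_res$out

  d <- dim(op_out)
  cat_in <- array(c(op_out, fl_out), dim = c(d[1], d[2], d[3] + dim(fl_out)[3]))
  cc$cat_in <- cat_in
  rs <- sep_fwd(cat_in, p$tr_dw, p$tr_pw, p$tr_b, want_col = keep)
  if (keep) { cc$col_tr <- rs$col; cc$y_tr <- rs$y } else cc$y_tr <- rs
  a_tr <- relu(cc$y_tr)
  cc$a_tr <- a_tr
  cc$tr_res <- resblock_fwd(a_tr, p$tr_r1_w, p$tr_r1_b, p$tr_r2_w, p$tr_r2_b,
                            keep)
  trunk <- cc$tr_res$out

  cc$y_hd1 <- cv(trunk, p$hd_c1_w, p$hd_c1_b, "hd1"); a_hd1 <- relu(cc$y_hd1)
  cc$a_hd1 <- a_hd1
  cc$y_hd2 <- cv(a_hd1, p$hd_c2_w, p$hd_c2_b, "hd2"); a_hd2 <- relu(cc$y_hd2)
  cc$a_hd2 <- a_hd2
  cc$y_hd3 <- cv(a_hd2, p$hd_c3_w, p$hd_c3_b, "hd3")
  depth <- relu(cc$y_hd3)

  cc$y_hc1 <- cv(trunk, p$hc_c1_w, p$hc_c1_b, "hc1"); a_hc1 <- relu(cc$y_hc1)
  cc$a_hc1 <- a_hc1
  cc$y_hc2 <- cv(a_hc1, p$hc_c2_w, p$hc_c2_b, "hc2"); a_hc2 <- relu(cc$y_hc2)
  cc$a_hc2 <- a_hc2
  cc$y_hc3 <- cv(a_hc2, p$hc_c3_w, p$hc_c3_b, "hc3")
  conc <- relu(cc$y_hc3)

  list(depth = depth[, , 1], conc = conc[, , 1],
       cache = if (keep) cc else NULL, xp = xp, xf = xf)
}

net_backward <- function(p, fw, d_depth, d_conc) {
  cc <- fw$cache
  g <- list()
  dy <- array(d_depth * (cc$y_hd3[, , 1] > 0), dim = c(dim(d_depth), 1))
  gb <- conv2d_bwd(cc$a_hd2, p$hd_c3_w, dy, cc$col_hd3)
  g$hd_c3_w <- gb$dw; g$hd_c3_b <- gb$db
  dy <- gb$dx * (cc$y_hd2 > 0)
  gb <- conv2d_bwd(cc$a_hd1, p$hd_c2_w, dy, cc$col_hd2)
  g$hd_c2_w <- gb$dw; g$hd_c2_b <- gb$db
  dy <- gb$dx * (cc$y_hd1 > 0)
  gb <- conv2d_bwd(cc$tr_res$out, p$hd_c1_w, dy, cc$col_hd1)
  g$hd_c1_w <- gb$dw; g$hd_c1_b <- gb$db
  d_trunk <- gb$dx

  dy <- array(d_conc * (cc$y_hc3[, , 1] > 0), dim = c(dim(d_conc), 1))
  gb <- conv2d_bwd(cc$a_hc2, p$hc_c3_w, dy, cc$col_hc3)
  g$hc_c3_w <- gb$dw; g$hc_c3_b <- gb$db
  dy <- gb$dx * (cc$y_hc2 > 0)
  gb <- conv2d_bwd(cc$a_hc1, p$hc_c2_w, dy, cc$col_hc2)
  g$hc_c2_w <- gb$dw; g$hc_c2_b <- gb$db
  dy <- gb$dx * (cc$y_hc1 > 0)
  gb <- conv2d_bwd(cc$tr_res$out, p$hc_c1_w, dy, cc$col_hc1)
  g$hc_c1_w <- gb$dw; g$hc_c1_b <- gb$db
  d_trunk <- d_trunk + gb$dx

  rb <- resblock_bwd(cc$a_tr, p$tr_r1_w, p$tr_r2_w, cc$tr_res, d_trunk)
  g$tr_r1_w <- rb$dw1; g$tr_r1_b <- rb$db1
  g$tr_r2_w <- rb$dw2; g$tr_r2_b <- rb$db2
  dy <- rb$dx * (cc$y_tr > 0)
  sb <- sep_bwd(cc$cat_in, p$tr_dw, p$tr_pw, dy, cc$col_tr)
  g$tr_dw <- sb$dwd; g$tr_pw <- sb$dwp; g$tr_b <- sb$db
  nb <- dim(cc$op_res$out)[3]
  d_op <- sb$dx[, , seq_len(nb), drop = FALSE]
  d_fl <- sb$dx[, , nb + seq_len(dim(cc$fl_res$out)[3]), drop = FALSE]

  rb <- resblock_bwd(cc$a_op2, p$op_r1_w, p$op_r2_w, cc$op_res, d_op)
  g$op_r1_w <- rb$dw1; g$op_r1_b <- rb$db1
  g$op_r2_w <- rb$dw2; g$op_r2_b <- rb$db2
  dy <- rb$dx * (cc$y_op2 > 0)
  gb <- conv2d_bwd(cc$a_op1, p$op_c2_w, dy, cc$col_op2)
  g$op_c2_w <- gb$dw; g$op_c2_b <- gb$db
  dy <- gb$dx * (cc$y_op1 > 0)
  gb <- conv2d_bwd(fw$xp, p$op_c1_w, dy, cc$col_op1, want_dx = FALSE)
  g$op_c1_w <- gb$dw; g$op_c1_b <- gb$db

  rb <- resblock_bwd(cc$a_fl2, p$fl_r1_w, p$fl_r2_w, cc$fl_res, d_fl)
  g$fl_r1_w <- rb$dw1; g$fl_r1_b <- rb$db1
  g$fl_r2_w <- rb$dw2; g$fl_r2_b <- rb$db2
  dy <- rb$dx * (cc$y_fl2 > 0)
  gb <- conv2d_bwd(cc$a_fl1, p$fl_c2_w, dy, cc$col_fl2)
  g$fl_c2_w <- gb$dw; g$fl_c2_b <- gb$db
  dy <- gb$dx * (cc$y_fl1 > 0)
  gb <- conv2d_bwd(cc$a_vol, p$fl_c1_w, dy, cc$col_fl1)
  g$fl_c1_w <- gb$dw; g$fl_c1_b <- gb$db
  dy <- gb$dx * (cc$y_vol > 0)
  vb <- vol_bwd(fw$xf, p$fl_vol_w, dy, cc$col_vol)
  g$fl_vol_w <- vb$dw; g$fl_vol_b <- vb$db
  g
}

#' Predict depth and concentration maps
#'
#' Pure function of the inputs and weights: normalizes, runs the forward
#' pass, denormalizes, and clamps to non-negative physical units.
#'
#' @param model A trained (or freshly built) `sfdi_model`.
#' @param inputs List with `props` and `fluorescence` arrays (physical
#'   units), e.g. from [load_sample()].
#' @return List of class `sfdi_prediction` with `depth_mm` and
#'   `concentration` matrices.
#' @export
predict_maps <- function(model, inputs) {
  hw <- model$config$input_hw
  if (!identical(dim(inputs$props)[1:2], as.integer(hw)) ||
      dim(inputs$props)[3] != 2 || dim(inputs$fluorescence)[3] != 6) {
    stop("input shape mismatch: expected ", hw[1], "x", hw[2],
         " with 2 property channels and 6 fluorescence frequencies")
  }
  ni <- normalize_inputs(inputs, model$norm)
  fw <- net_forward(model$params, ni$props, ni$fluorescence, keep = FALSE)
  structure(list(depth_mm = pmax(fw$depth, 0) * model$norm$depth_scale,
                 concentration = pmax(fw$conc, 0) * model$norm$conc_scale),
            class = "sfdi_prediction")
}

#' Training configuration
#'
#' Adam with exponentially decaying learning rate, MSE loss on normalized
#' depth plus MSE on normalized concentration (equal weights), early
#' stopping on validation loss with best-weight restore.
#'
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay per epoch.
#' @param epochs Maximum epochs (<= 100 by convention).
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience in epochs.
#' @param seed RNG seed for shuffling.
#' @param crop_px Optional lateral size of random training crops. The model
#'   is fully convolutional, so it can be trained on smaller windows (a
#'   standard data-augmentation/throughput device) and applied to full
#'   101 x 101 frames at inference; validation always runs at full size.
#' @param fp_weight Relative pixel weight of the tumor footprint in the
#'   loss (1 = uniform). Footprint pixels are a small minority of each
#'   frame; up-weighting them concentrates capacity on the clinically
#'   relevant region.
#' @return Object of class `sfdi_train_config`.
#' @export
train_config <- function(lr = 5e-5, lr_decay = 0.95, epochs = 100,
                         batch_size = 16, patience = 10, seed = 1,
                         crop_px = NULL, fp_weight = 1) {
  structure(list(lr = lr, lr_decay = lr_decay, epochs = epochs,
                 batch_size = batch_size, patience = patience, seed = seed,
                 crop_px = crop_px, fp_weight = fp_weight),
            class = "sfdi_train_config")
}

# weighted composite MSE; w is a per-pixel weight map (NULL = uniform)
sample_loss_grad <- function(p, xp, xf, t_depth, t_conc, want_grad = TRUE,
                             w = NULL) {
  fw <- net_forward(p, xp, xf, keep = want_grad)
  ed <- fw$depth - t_depth
  ec <- fw$conc - t_conc
  if (is.null(w)) {
    npx <- length(t_depth)
    loss <- mean(ed^2) + mean(ec^2)
    if (!want_grad) return(list(loss = loss))
    g <- net_backward(p, fw, 2 * ed / npx, 2 * ec / npx)
  } else {
    sw <- sum(w)
    loss <- sum(w * ed^2) / sw + sum(w * ec^2) / sw
    if (!want_grad) return(list(loss = loss))
    g <- net_backward(p, fw, 2 * w * ed / sw, 2 * w * ec / sw)
  }
  list(loss = loss, grad = g)
}

#' Train the network on a simulated dataset
#'
#' Prepares normalized input/target tensors (the fluorescence scale is set
#' to the dataset's 99th percentile), then optimizes the composite MSE with
#' Adam. History records per-epoch train/val losses; the best validation
#' checkpoint is restored on return. Aborts with a diagnostic if the loss
#' goes non-finite.
#'
#' @param model An `sfdi_model`.
#' @param dataset An `sfdi_dataset` with train/val splits.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a `history` data.frame attached.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        verbose = FALSE) {
  set.seed(config$seed)
  splits <- dataset$manifest$split
  idx_tr <- which(splits == "train")
  idx_va <- which(splits == "val")
  if (!length(idx_tr)) stop("dataset has no training split")
  loaded <- lapply(dataset$samples, load_sample)
  fl_all <- unlist(lapply(loaded[idx_tr], function(s) {
    as.vector(s$inputs$fluorescence)
  }))
  model$norm$fluor_scale <- max(stats::quantile(fl_all, 0.99), 1e-12)
  prep <- lapply(loaded, function(s) {
    ni <- normalize_inputs(s$inputs, model$norm)
    td <- s$targets$depth_mm / model$norm$depth_scale
    w <- if (config$fp_weight != 1) {
      1 + (config$fp_weight - 1) * (s$targets$depth_mm > 0)
    } else NULL
    list(xp = ni$props, xf = ni$fluorescence, td = td,
         tc = s$targets$concentration / model$norm$conc_scale, w = w)
  })
  p <- model$params
  mom <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best <- list(loss = Inf, params = p)
  wait <- 0
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr * config$lr_decay^(epoch - 1)
    ord <- sample(idx_tr)
    tr_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      acc <- NULL
      bl <- 0
      for (i in bt) {
        s <- prep[[i]]
        cp <- config$crop_px
        if (!is.null(cp) && cp < dim(s$xp)[1]) {
          ox <- sample.int(dim(s$xp)[1] - cp + 1L, 1) - 1L
          oy <- sample.int(dim(s$xp)[2] - cp + 1L, 1) - 1L
          rx <- ox + seq_len(cp); ry <- oy + seq_len(cp)
          s <- list(xp = s$xp[rx, ry, , drop = FALSE],
                    xf = s$xf[rx, ry, , drop = FALSE],
                    td = s$td[rx, ry], tc = s$tc[rx, ry],
                    w = if (!is.null(s$w)) s$w[rx, ry])
        }
        r <- sample_loss_grad(p, s$xp, s$xf, s$td, s$tc, w = s$w)
        if (!is.finite(r$loss)) {
          stop("non-finite loss at epoch ", epoch, ", sample index ", i,
               " (id ", dataset$manifest$id[i], ")")
        }
        bl <- bl + r$loss
        acc <- if (is.null(acc)) r$grad else
          Map(`+`, acc, r$grad)
      }
      tr_loss <- tr_loss + bl
      nb <- length(bt)
      step <- step + 1
      for (nm in names(p)) {
        gr <- acc[[nm]] / nb
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gr
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gr^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    tr_loss <- tr_loss / length(ord)
    va_loss <- if (length(idx_va)) {
      mean(vapply(idx_va, function(i) {
        s <- prep[[i]]
        sample_loss_grad(p, s$xp, s$xf, s$td, s$tc, want_grad = FALSE,
                         w = s$w)$loss
      }, numeric(1)))
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = va_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, tr_loss, va_loss, lr))
    }
    ref <- if (is.na(va_loss)) tr_loss else va_loss
    if (ref < best$loss - 1e-9) {
      best <- list(loss = ref, params = p)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model
}
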