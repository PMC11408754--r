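# A small cached dataset shared by the training tests.
net_lut <- build_lut(n_nodes = 120)
net_ds <- generate_training_set("cylinder", 8, seed = 77, lut = net_lut,
                                val_frac = 0.25)

test_that("the committed schedule carries exactly 920,514 trainable parameters", {
  set.seed(1)
  m <- build_model()
  expect_identical(parameter_count(m), 920514L)
  expect_error(build_model(tiny_model_config(), strict = TRUE),
               "920514")
})

test_that("changing one layer's filters shifts the count by the analytic delta", {
  set.seed(1)
  suppressWarnings(m1 <- build_model(tiny_model_config()))
  cfg2 <- tiny_model_config()
  h1 <- cfg2$head_widths[1]; h2 <- cfg2$head_widths[2]
  g <- cfg2$trunk_width
  cfg2$head_widths[2] <- 2 * h2
  suppressWarnings(m2 <- build_model(cfg2))
  # each head: conv(h1 -> h2) + conv(h2 -> 1); doubling h2 adds
  # (9 h1 h2 + h2) + 9 h2 per head
  delta <- as.integer(2 * ((9 * h1 * h2 + h2) + 9 * h2))
  expect_identical(parameter_count(m2) - parameter_count(m1), delta)
})

test_that("every layer preserves lateral dimensionality and zero input is safe", {
  set.seed(2)
  suppressWarnings(m <- build_model(tiny_model_config()))
  xp <- array(0, dim = c(101, 101, 2))
  xf <- array(0, dim = c(101, 101, 6))
  fw <- sfdepth:::net_forward(m$params, xp, xf, keep = TRUE)
  for (nm in grep("^(y_|a_)", names(fw$cache), value = TRUE)) {
    expect_identical(dim(fw$cache[[nm]])[1:2], c(101L, 101L))
  }
  expect_identical(dim(fw$depth), c(101L, 101L))
  expect_true(all(is.finite(fw$depth)) && all(fw$depth >= 0))
  expect_true(all(is.finite(fw$conc)) && all(fw$conc >= 0))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  cfg <- model_config(op_widths = c(3, 4), vol_filters = 2,
                      fl_widths = c(4, 4), trunk_width = 4,
                      head_widths = c(3, 2), input_hw = c(9, 9))
  suppressWarnings(m <- build_model(cfg))
  p <- m$params
  # jitter biases so no ReLU argument sits exactly at its kink
  for (nm in grep("_b$|tr_b", names(p), value = TRUE)) {
    p[[nm]] <- p[[nm]] + runif(length(p[[nm]]), 0.01, 0.05)
  }
  xp <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
  xf <- array(rnorm(9 * 9 * 6), c(9, 9, 6))
  td <- matrix(abs(rnorm(81)), 9); tc <- matrix(abs(rnorm(81)), 9)
  slg <- sfdepth:::sample_loss_grad
  r <- slg(p, xp, xf, td, tc)
  h <- 1e-6
  for (nm in names(p)) {
    for (k in sample(length(p[[nm]]), min(2, length(p[[nm]])))) {
      p2 <- p
      p2[[nm]][k] <- p2[[nm]][k] + h
      l2 <- slg(p2, xp, xf, td, tc, want_grad = FALSE)$loss
      p2[[nm]][k] <- p2[[nm]][k] - 2 * h
      l1 <- slg(p2, xp, xf, td, tc, want_grad = FALSE)$loss
      num <- (l2 - l1) / (2 * h)
      expect_lt(abs(num - r$grad[[nm]][k]) /
                  max(1e-8, abs(num) + abs(r$grad[[nm]][k])), 1e-4)
    }
  }
})

test_that("the architecture can overfit a handful of samples", {
  # memorization capacity check on eight fixed 48x48 windows (the model is
  # fully convolutional, so the window size is free)
  ds <- net_ds
  win <- 28:75
  ds$samples <- lapply(ds$samples, function(s) {
    s$stack$fluorescence <- s$stack$fluorescence[win, win, , drop = FALSE]
    s$prop_maps$mu_a <- s$prop_maps$mu_a[win, win]
    s$prop_maps$mu_s_prime <- s$prop_maps$mu_s_prime[win, win]
    s$gt$depth_mm <- s$gt$depth_mm[win, win]
    s$gt$concentration <- s$gt$concentration[win, win]
    s
  })
  set.seed(4)
  cfg <- model_config(op_widths = c(8, 12), vol_filters = 2,
                      fl_widths = c(12, 12), trunk_width = 16,
                      head_widths = c(8, 4))
  suppressWarnings(m <- build_model(cfg))
  tc <- train_config(lr = 2e-3, lr_decay = 1, epochs = 80, batch_size = 1,
                     patience = 100, seed = 4)
  m <- train_model(m, ds, tc)
  h <- m$history
  expect_gte(h$train_loss[1] / min(h$train_loss), 10)
})

test_that("training is deterministic under fixed seeds", {
  run <- function() {
    set.seed(5)
    suppressWarnings(m <- build_model(tiny_model_config()))
    cfg <- train_config(lr = 1e-3, epochs = 2, batch_size = 4, seed = 9,
                        crop_px = 48)
    train_model(m, net_ds, cfg)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$tr_pw, m2$params$tr_pw)
})

test_that("prediction is a pure function with exact unit round-trip", {
  set.seed(6)
  suppressWarnings(m <- build_model(tiny_model_config()))
  m$norm$fluor_scale <- 0.05
  ls <- load_sample(net_ds$samples[[1]])
  p1 <- predict_maps(m, ls$inputs)
  p2 <- predict_maps(m, ls$inputs)
  expect_identical(p1$depth_mm, p2$depth_mm)
  expect_true(all(p1$depth_mm >= 0) && all(p1$concentration >= 0))
  # denormalization is exactly the configured scale
  ni <- normalize_inputs(ls$inputs, m$norm)
  fw <- sfdepth:::net_forward(m$params, ni$props, ni$fluorescence, keep = FALSE)
  expect_identical(p1$depth_mm, pmax(fw$depth, 0) * m$norm$depth_scale)
  bad <- ls$inputs
  bad$fluorescence <- bad$fluorescence[, , 1:3]
  expect_error(predict_maps(m, bad), "shape mismatch")
})
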