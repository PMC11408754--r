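# Camera-image preprocessing chain for phantom measurements: statistical
# padding to the required field of view, exact 5x5 block-mean downsampling
# from camera resolution (0.1 mm/pixel) to the network resolution
# (0.5 mm/pixel), applied identically to every channel.

CAMERA_PIXEL_MM <- 0.1
NETWORK_CROP_PX <- 505L

#' Background intensity statistics of the non-tumor region
#'
#' @param mean,sd Mean and standard deviation of the non-fluorescent
#'   background intensity.
#' @return Object of class `sfdi_bgstats`.
#' @export
background_stats <- function(mean, sd) {
  stopifnot(sd >= 0)
  structure(list(mean = mean, sd = sd), class = "sfdi_bgstats")
}

#' Pad a camera image with background-like values
#'
#' Pads symmetrically to `target_px` per side; pad pixels are i.i.d. uniform
#' draws on `[mean - sd, mean + sd]` (values within one standard deviation
#' of the mean background intensity), using the current R random stream.
#' Set `constant = TRUE` for a deterministic constant-mean pad.
#'
#' @param image Numeric matrix at camera resolution.
#' @param stats A [background_stats()].
#' @param target_px Integer `c(rows, cols)` of the padded image.
#' @param constant Use the mean instead of uniform draws.
#' @return The padded matrix.
#' @export
pad_with_background <- function(image, stats, target_px, constant = FALSE) {
  target_px <- rep(as.integer(target_px), length.out = 2)
  d <- dim(image)
  if (any(target_px < d)) {
    stop("target extent ", paste(target_px, collapse = "x"),
         " is smaller than the image ", paste(d, collapse = "x"))
  }
  if (all(target_px == d)) return(image)
  out <- matrix(0, target_px[1], target_px[2])
  pad_mask <- matrix(TRUE, target_px[1], target_px[2])
  r0 <- (target_px[1] - d[1]) %/% 2
  c0 <- (target_px[2] - d[2]) %/% 2
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- image
  pad_mask[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- FALSE
  npad <- sum(pad_mask)
  out[pad_mask] <- if (constant) stats$mean else
    stats::runif(npad, stats$mean - stats$sd, stats$mean + stats$sd)
  out
}

#' Box-downsample a 505x505 camera image to 101x101
#'
#' Exact non-overlapping 5x5 block means: 0.1 mm/pixel to 0.5 mm/pixel.
#'
#' @param image Numeric 505 x 505 matrix.
#' @return 101 x 101 matrix.
#' @export
box_downsample <- function(image) {
  d <- dim(image)
  if (is.null(d) || any(d != NETWORK_CROP_PX)) {
    stop("box_downsample expects a 505x505 camera-resolution image, got ",
         paste(d, collapse = "x"))
  }
  n <- NETWORK_CROP_PX / 5L
  # block means via two reshape-and-average passes
  m <- matrix(colMeans(matrix(image, nrow = 5)), nrow = n)      # rows pooled
  t(matrix(colMeans(matrix(t(m), nrow = 5)), nrow = n))         # cols pooled
}

#' Preprocess a multi-channel camera stack into network inputs
#'
#' Each channel is cropped with the shared crop box, padded with background
#' statistics when the crop is smaller than 505 x 505 (all channels of a
#' group share the random pad stream via `pad_seed`), and box-downsampled
#' to 101 x 101. The crop box is recorded in the output metadata.
#'
#' @param images Named list of camera-resolution matrices (e.g. reflectance
#'   and fluorescence frames at each frequency, absorption, scattering).
#' @param crop_box Integer `c(x0, y0, x1, y1)` (inclusive pixel indices), or
#'   `NULL` to use each full image.
#' @param stats A [background_stats()].
#' @param pad_seed Seed for the padding draws.
#' @param constant_pad Use constant-mean padding.
#' @return List with `channels` (named list of 101 x 101 matrices) and
#'   `meta` (crop box, pad seed, background stats).
#' @export
preprocess_stack <- function(images, crop_box = NULL, stats, pad_seed = 1,
                             constant_pad = FALSE) {
  stopifnot(is.list(images), length(images) >= 1)
  d1 <- dim(images[[1]])
  if (!all(vapply(images, function(im) identical(dim(im), d1), TRUE))) {
    stop("channel shape disagreement: all channels must share the crop box")
  }
  out <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (!is.null(crop_box)) {
      im <- im[crop_box[1]:crop_box[3], crop_box[2]:crop_box[4], drop = FALSE]
    }
    set.seed(pad_seed)  # all channels of a group share the pad pattern
    im <- pad_with_background(im, stats, NETWORK_CROP_PX,
                              constant = constant_pad)
    box_downsample(im)
  })
  names(out) <- names(images)
  list(channels = out,
       meta = list(crop_box = crop_box, pad_seed = pad_seed,
                   bg_mean = stats$mean, bg_sd = stats$sd,
                   camera_pixel_mm = CAMERA_PIXEL_MM))
}
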