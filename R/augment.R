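# Training-time augmentation with cross-modality synchronization.
#
# Each transform fires independently once per sample with its configured
# probability.  Spatial transforms (crop, flip, rotation) use identical
# parameters for every modality and mask of the sample — the modalities are
# co-registered views of one lesion and desynchronising them would destroy
# the cross-modal signal.  Color jitter draws its factors per modality.
# Augmentation is applied to the training split only; validation and test
# see resize + normalize.

#' Augmentation configuration
#'
#' Defaults follow the training recipe: color jitter of brightness,
#' contrast and saturation in \[0.8, 1.2\] with probability 0.2; random
#' crop with probability 0.3 at aspect ratio 0.93 (resized back); random
#' flip with probability 0.1; random rotation in \[-20, 20\] degrees with
#' probability 0.2.
#'
#' @param jitter_range multiplicative jitter range for brightness, contrast
#'   and saturation.
#' @param jitter_prob probability that color jitter fires for a sample.
#' @param crop_prob probability of the random crop.
#' @param crop_aspect width/height aspect ratio of the crop window.
#' @param flip_prob probability of the random flip.
#' @param flip_mode `"either"` picks horizontal or vertical uniformly;
#'   `"both"` applies both reflections.
#' @param rotate_range rotation range in degrees.
#' @param rotate_prob probability of the random rotation.
#' @param enabled master switch; `FALSE` makes [augment_sample()] the
#'   identity.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(jitter_range = c(0.8, 1.2), jitter_prob = 0.2,
                                crop_prob = 0.3, crop_aspect = 0.93,
                                flip_prob = 0.1,
                                flip_mode = c("either", "both"),
                                rotate_range = c(-20, 20), rotate_prob = 0.2,
                                enabled = TRUE) {
  flip_mode <- match.arg(flip_mode)
  probs <- c(jitter_prob, crop_prob, flip_prob, rotate_prob)
  stopifnot(all(probs >= 0), all(probs <= 1),
            jitter_range[1] <= jitter_range[2],
            rotate_range[1] <= rotate_range[2])
  structure(list(jitter_range = jitter_range, jitter_prob = jitter_prob,
                 crop_prob = crop_prob, crop_aspect = crop_aspect,
                 flip_prob = flip_prob, flip_mode = flip_mode,
                 rotate_range = rotate_range, rotate_prob = rotate_prob,
                 enabled = enabled),
            class = "augmentation_config")
}

arr_to_ebi <- function(x) EBImage::Image(aperm(x, c(2, 1, 3)) / 255,
                                         colormode = "Color")
ebi_to_arr <- function(img) aperm(EBImage::imageData(img), c(2, 1, 3)) * 255

resize_arr <- function(x, h, w, bilinear = TRUE) {
  img <- EBImage::resize(arr_to_ebi(x), w = w, h = h,
                         filter = if (bilinear) "bilinear" else "none")
  ebi_to_arr(img)
}

resize_mask <- function(msk, h, w) {
  img <- EBImage::resize(EBImage::Image(t(msk)), w = w, h = h, filter = "none")
  (t(EBImage::imageData(img)) > 0.5) * 1
}

rotate_arr <- function(x, angle, bilinear = TRUE) {
  d <- dim(x)
  img <- EBImage::rotate(arr_to_ebi(x), angle,
                         filter = if (bilinear) "bilinear" else "none",
                         output.dim = c(d[2], d[1]), bg.col = "black")
  pmin(pmax(ebi_to_arr(img), 0), 255)
}

rotate_mask <- function(msk, angle) {
  d <- dim(msk)
  img <- EBImage::rotate(EBImage::Image(t(msk)), angle, filter = "none",
                         output.dim = c(d[2], d[1]), bg.col = 0)
  (t(EBImage::imageData(img)) > 0.5) * 1
}

flip_arr <- function(x, axis) {
  if (axis %in% c("horizontal", "both")) x <- x[, dim(x)[2]:1, , drop = FALSE]
  if (axis %in% c("vertical", "both")) x <- x[dim(x)[1]:1, , , drop = FALSE]
  x
}

flip_mask <- function(msk, axis) {
  if (axis %in% c("horizontal", "both")) msk <- msk[, ncol(msk):1, drop = FALSE]
  if (axis %in% c("vertical", "both")) msk <- msk[nrow(msk):1, , drop = FALSE]
  msk
}

color_jitter <- function(x, range) {
  f <- stats::runif(3, range[1], range[2])
  # brightness
  x <- x * f[1]
  # contrast: blend with the grayscale mean
  gmean <- mean(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  x <- (x - gmean) * f[2] + gmean
  # saturation: blend each pixel with its own grayscale value
  gray <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  for (ch in 1:3) x[, , ch] <- gray + (x[, , ch] - gray) * f[3]
  pmin(pmax(x, 0), 255)
}

#' Resize all modality images (and masks) of a sample
#'
#' Bilinear for images, nearest-neighbor for masks.
#'
#' @param sample list with `images` (list of (H, W, 3) arrays) and optional
#'   `masks`.
#' @param size target square side, >= 16.
#' @return the resized sample.
#' @export
resize_sample <- function(sample, size) {
  if (size < 16) stop("size must be at least 16")
  sample$images <- lapply(sample$images, resize_arr, h = size, w = size)
  if (!is.null(sample$masks)) {
    sample$masks <- lapply(sample$masks, resize_mask, h = size, w = size)
  }
  sample
}

#' Apply the augmentation pipeline to one multi-modal sample
#'
#' Fires each transform once per sample with its configured probability.
#' Spatial parameters (crop window, flip axis, rotation angle) are shared
#' by all modalities and masks; color jitter factors are drawn per
#' modality.  Uses R's RNG — seed the stream before calling for
#' reproducibility.
#'
#' @param sample list with `images` and optional `masks`.
#' @param config an [augmentation_config()].
#' @return the augmented sample.
#' @export
augment_sample <- function(sample, config) {
  if (!config$enabled) return(sample)
  d <- dim(sample$images[[1]])
  h <- d[1]; w <- d[2]
  # one Bernoulli draw per transform per sample
  fire <- stats::runif(4) < c(config$jitter_prob, config$crop_prob,
                              config$flip_prob, config$rotate_prob)
  if (fire[1]) {
    sample$images <- lapply(sample$images, color_jitter,
                            range = config$jitter_range)
  }
  if (fire[2]) {
    # crop window at aspect w/h = crop_aspect, maximal size, random offset
    ch_ <- h
    cw_ <- max(1L, min(w, as.integer(round(config$crop_aspect * h))))
    if (cw_ > w) { cw_ <- w; ch_ <- as.integer(round(w / config$crop_aspect)) }
    y0 <- if (h > ch_) sample.int(h - ch_ + 1L, 1) else 1L
    x0 <- if (w > cw_) sample.int(w - cw_ + 1L, 1) else 1L
    crop <- function(x) x[y0:(y0 + ch_ - 1), x0:(x0 + cw_ - 1), , drop = FALSE]
    cropm <- function(msk) msk[y0:(y0 + ch_ - 1), x0:(x0 + cw_ - 1), drop = FALSE]
    sample$images <- lapply(sample$images, function(x) resize_arr(crop(x), h, w))
    if (!is.null(sample$masks)) {
      sample$masks <- lapply(sample$masks, function(msk) {
        resize_mask(cropm(msk), h, w)
      })
    }
  }
  if (fire[3]) {
    axis <- if (config$flip_mode == "both") "both" else
      sample(c("horizontal", "vertical"), 1)
    sample$images <- lapply(sample$images, flip_arr, axis = axis)
    if (!is.null(sample$masks)) {
      sample$masks <- lapply(sample$masks, flip_mask, axis = axis)
    }
  }
  if (fire[4]) {
    angle <- stats::runif(1, config$rotate_range[1], config$rotate_range[2])
    sample$images <- lapply(sample$images, rotate_arr, angle = angle)
    if (!is.null(sample$masks)) {
      sample$masks <- lapply(sample$masks, rotate_mask, angle = angle)
    }
  }
  sample
}
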