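# Grad-CAM interpretability.
#
# For a chosen class and stage, channel weights are the spatial means of the
# gradient of that class's logit with respect to the post-exchange feature
# map of each modality; the weighted channel sum is rectified, upsampled to
# input resolution and max-normalised.  Lesion outlines come from
# border-following on the thresholded heatmap; agreement with ground-truth
# masks is scored as intersection-over-union.

#' Grad-CAM heatmaps for one sample
#'
#' @param fit a `switchnet_fit` (or loaded checkpoint).
#' @param sample a loaded sample ([load_sample()]).
#' @param target_class class index in 0..C-1; `NULL` uses the predicted
#'   class.
#' @param stage backbone stage whose (post-exchange) features are
#'   attributed, 1..8 (default 8, the features the head consumes).
#' @return a `switchnet_cam`: per-modality heatmaps in \[0, 1\] at input
#'   resolution, `target_class`, `stage`, `degenerate` flags (all-zero
#'   activation before normalization), predicted probabilities.
#' @export
grad_cam <- function(fit, sample, target_class = NULL, stage = 8L) {
  model <- fit$model
  stopifnot(stage >= 1, stage <= length(model$config$backbone$stages))
  size <- fit$config$image_size
  if (dim(sample$images[[1]])[1] != size) sample <- resize_sample(sample, size)
  inputs <- lapply(seq_along(sample$images), function(j) {
    x <- normalize_image(sample$images[[j]], fit$stats$modalities[[j]])
    array(x, dim = c(dim(x), 1))
  })
  fw <- interleaved_forward(model, inputs, training = FALSE, keep_cache = TRUE)
  probs <- fw$probs[, 1]
  if (is.null(target_class)) target_class <- which.max(probs) - 1L
  cc <- model$config$n_classes
  dlogits <- matrix(0, cc, 1)
  dlogits[target_class + 1L, 1] <- 1
  bw <- model_backward(model, fw, dlogits, record_stage = stage)
  feats <- stage_features_from_cache(fw, stage)
  n_mod <- model$config$n_modalities
  heatmaps <- vector("list", n_mod)
  degenerate <- logical(n_mod)
  for (i in seq_len(n_mod)) {
    z <- feats[[i]][, , , 1, drop = FALSE]
    dz <- bw$recorded[[i]][, , , 1, drop = FALSE]
    d <- dim(z)
    wts <- apply(dz, 3, mean)                      # spatial mean per channel
    cam <- matrix(0, d[1], d[2])
    for (ch in seq_len(d[3])) cam <- cam + wts[ch] * z[, , ch, 1]
    cam <- pmax(cam, 0)                            # rectify
    cam_up <- if (d[1] == size && d[2] == size) cam else {
      up <- EBImage::resize(EBImage::Image(t(cam)), w = size, h = size,
                            filter = "bilinear")
      t(EBImage::imageData(up))
    }
    cam_up <- pmax(cam_up, 0)
    mx <- max(cam_up)
    if (mx > 0) cam_up <- cam_up / mx else degenerate[i] <- TRUE
    heatmaps[[i]] <- cam_up
  }
  names(heatmaps) <- fit$modality_names
  structure(list(heatmaps = heatmaps, target_class = target_class,
                 stage = stage, degenerate = degenerate, probs = probs,
                 sample_id = sample$sample_id),
            class = "switchnet_cam")
}

# pull the post-exchange stage features for all modalities out of a cached
# forward pass (re-deriving them from the caches of the following stage
# would be brittle; instead we recompute stage outputs cheaply)
stage_features_from_cache <- function(fw, stage) {
  if (stage == length(fw$cache$stage)) return(fw$z8)
  # post-ISM features of intermediate stages are the (combined-batch)
  # inputs cached by the next stage's first block
  comb <- first_block_input(fw$cache$stage[[stage + 1]][[1]])
  split_modalities(comb, fw$cache$n, fw$cache$nb)
}

# recover a block's input from its first convolution cache: regular convs
# store the padded input permuted to (H, W, N, C), depthwise convs store it
# unpermuted
first_block_input <- function(cache) {
  cc <- if (!is.null(cache$conv)) cache$conv else
    if (!is.null(cache$exc)) cache$exc else NULL
  if (!is.null(cc)) {
    d <- cc$in_dim
    return(unpad_hw(aperm(cc$xpp, c(1, 2, 4, 3)), cc$pad, d[1], d[2]))
  }
  cc <- cache$dw
  d <- cc$in_dim
  unpad_hw(cc$xp, cc$pad, d[1], d[2])
}

#' Extract lesion contours from a heatmap
#'
#' Binarises the heatmap at `threshold_fraction * max`, labels connected
#' components, drops components below `min_area_frac` of the image and
#' returns the boundary polygon of each remaining component
#' (border-following).
#'
#' @param heatmap matrix in \[0, 1\].
#' @param threshold_fraction threshold as a fraction of the heatmap max.
#' @param min_area_frac minimum component area as a fraction of all pixels.
#' @return list of polygons, each an n x 2 matrix of (row, col) pixel
#'   coordinates; empty when nothing exceeds the threshold.
#' @export
extract_lesion_contours <- function(heatmap, threshold_fraction = 0.5,
                                    min_area_frac = 0.001) {
  mx <- max(heatmap)
  if (mx <= 0) return(list())
  bin <- heatmap >= threshold_fraction * mx
  if (!any(bin)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(t(bin * 1)))
  areas <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  keep <- as.integer(names(areas[areas >= min_area_frac * length(heatmap)]))
  if (length(keep) == 0) return(list())
  oc <- EBImage::ocontour(lab)
  polys <- lapply(keep, function(k) {
    p <- oc[[k]]
    # ocontour returns (x, y) in EBImage's transposed frame -> (row, col)
    cbind(row = p[, 2] + 1, col = p[, 1] + 1)
  })
  polys
}

#' Intersection-over-union of a thresholded heatmap and a mask
#'
#' @param heatmap matrix in \[0, 1\].
#' @param mask binary matrix of the same size.
#' @param threshold_fraction threshold as a fraction of the heatmap max.
#' @return IoU in \[0, 1\]; `NA` with a warning for an empty mask.
#' @export
cam_roi_overlap <- function(heatmap, mask, threshold_fraction = 0.5) {
  stopifnot(all(dim(heatmap) == dim(mask)))
  if (sum(mask) == 0) {
    warning("empty reference mask; IoU undefined (NA)")
    return(NA_real_)
  }
  region <- heatmap >= threshold_fraction * max(heatmap) & max(heatmap) > 0
  inter <- sum(region & mask == 1)
  union <- sum(region | mask == 1)
  if (union == 0) return(0)
  inter / union
}

# simple blue->red colormap for heatmap rendering
cam_colors <- function(v) {
  r <- pmin(1, pmax(0, 1.5 * v - 0.25))
  g <- pmin(1, pmax(0, 1 - abs(2 * v - 1)))
  b <- pmin(1, pmax(0, 1.25 - 1.5 * v))
  list(r = r, g = g, b = b)
}

#' Render heatmap overlay panels
#'
#' Writes one PNG per modality with three rows: the original image, the
#' heatmap overlay with lesion contours, and (when masks are available)
#' the ground-truth region. Output is deterministic for fixed inputs.
#'
#' @param sample the loaded sample used for [grad_cam()].
#' @param cam a `switchnet_cam`.
#' @param out_dir output directory.
#' @param threshold_fraction contour threshold fraction.
#' @return character vector of written file paths.
#' @export
render_overlay <- function(sample, cam, out_dir, threshold_fraction = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  size <- dim(cam$heatmaps[[1]])[1]
  if (dim(sample$images[[1]])[1] != size) sample <- resize_sample(sample, size)
  paths <- character(length(cam$heatmaps))
  for (i in seq_along(cam$heatmaps)) {
    img <- sample$images[[i]] / 255
    hm <- cam$heatmaps[[i]]
    cols <- cam_colors(hm)
    overlay <- img
    overlay[, , 1] <- 0.5 * img[, , 1] + 0.5 * cols$r
    overlay[, , 2] <- 0.5 * img[, , 2] + 0.5 * cols$g
    overlay[, , 3] <- 0.5 * img[, , 3] + 0.5 * cols$b
    for (poly in extract_lesion_contours(hm, threshold_fraction)) {
      idx <- cbind(pmin(pmax(poly[, 1], 1), size), pmin(pmax(poly[, 2], 1), size))
      for (ch in 1:3) {
        overlay[cbind(idx, ch)] <- c(0, 0, 1)[ch]   # blue lesion edges
      }
    }
    rows <- list(img, overlay)
    if (!is.null(sample$masks)) {
      mask_rgb <- array(0, dim = dim(img))
      for (ch in 1:3) mask_rgb[, , ch] <- sample$masks[[i]] * c(1, 0, 0)[ch]
      rows[[3]] <- mask_rgb
    }
    panel <- do.call(abind_rows, rows)
    paths[i] <- file.path(out_dir,
                          sprintf("%s_%s_cam.png", cam$sample_id,
                                  names(cam$heatmaps)[i]))
    png::writePNG(pmin(pmax(panel, 0), 1), paths[i])
  }
  paths
}

# stack (H, W, 3) arrays vertically without abind
abind_rows <- function(...) {
  mats <- list(...)
  h <- sum(vapply(mats, function(m) dim(m)[1], numeric(1)))
  w <- dim(mats[[1]])[2]
  out <- array(0, dim = c(h, w, 3))
  at <- 1
  for (m in mats) {
    out[at:(at + dim(m)[1] - 1), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}
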