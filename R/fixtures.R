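# Synthetic multi-modal fixture generators.
#
# Each sample carries one planted elliptical (or shaped) lesion, co-registered
# across modalities.  Every modality encodes a binary lesion attribute (its
# "bit") through a modality-specific appearance (color palette, shape or
# texture); the class label is a parity function of the bits across
# modalities, so no single modality determines the label but all modalities
# jointly determine it exactly.  This is the property the information-
# switching ablation relies on: a model that fuses modalities only through
# a final linear head is additively separable across modalities and cannot
# represent parity, while cross-modal feature exchange can.
#
# Ground truth (per-modality lesion masks and the bit string) is written
# alongside the images: masks as 0/255 PNG, bits in the manifest.

# two lesion colors (rows: bit 0 / bit 1) and a background color per modality
dd_palettes <- function() {
  list(
    spots       = list(bg = c(205, 175, 150), col = rbind(c(150, 75, 60), c(75, 110, 160))),
    red_marks   = list(bg = c(195, 150, 140), col = rbind(c(185, 60, 55), c(90, 160, 90))),
    uv_spots    = list(bg = c(60, 60, 75),    col = rbind(c(160, 150, 60), c(70, 150, 170))),
    porphyrins  = list(bg = c(40, 40, 55),    col = rbind(c(190, 80, 160), c(80, 190, 120))),
    brown_spots = list(bg = c(190, 165, 135), col = rbind(c(110, 70, 40), c(60, 90, 150)))
  )
}

derm7pt_palettes <- function() {
  list(
    clinical    = list(bg = c(210, 170, 150), col = rbind(c(170, 60, 50), c(60, 80, 150))),
    dermoscopic = list(bg = c(200, 160, 130), col = rbind(c(180, 140, 90), c(95, 60, 45)))
  )
}

# planted lesion geometry, shared across a sample's modalities
draw_lesion_geometry <- function(size) {
  r <- stats::runif(2, 0.16, 0.26) * size
  cx <- stats::runif(1, max(r) + 1, size - max(r) - 1)
  cy <- stats::runif(1, max(r) + 1, size - max(r) - 1)
  theta <- stats::runif(1, 0, pi)
  list(cx = cx, cy = cy, rx = r[1], ry = r[2], theta = theta)
}

lesion_mask <- function(size, geo, shape = "ellipse") {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  dx <- xs - geo$cx
  dy <- ys - geo$cy
  if (shape == "square") {
    return((abs(dx) <= geo$rx & abs(dy) <= geo$rx) * 1)
  }
  u <- dx * cos(geo$theta) + dy * sin(geo$theta)
  v <- -dx * sin(geo$theta) + dy * cos(geo$theta)
  ((u / geo$rx)^2 + (v / geo$ry)^2 <= 1) * 1
}

# render one modality image: background + lesion colored by its bit,
# optional texture stripes, Gaussian pixel noise; values clipped to 0..255
render_modality <- function(size, geo, pal, bit, noise_sd = 8,
                            shape = "ellipse", stripes = FALSE) {
  mask <- lesion_mask(size, geo, shape)
  base <- pal$col[bit + 1L, ] + stats::rnorm(3, 0, 4)
  bands <- if (stripes && bit == 1L) {
    # horizontal bands of period 6 px, centred around the base color
    (((matrix(rep(seq_len(size), times = size), size, size) %/% 3) %% 2) - 0.5) * 45
  } else {
    matrix(0, size, size)
  }
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    layer <- matrix(pal$bg[ch], size, size)
    layer[mask == 1] <- base[ch] + bands[mask == 1]
    img[, , ch] <- layer
  }
  img <- img + array(stats::rnorm(size * size * 3, 0, noise_sd),
                     dim = c(size, size, 3))
  list(image = pmin(pmax(img, 0), 255), mask = mask)
}

write_png_255 <- function(img, path) {
  png::writePNG(round(img) / 255, path)
}

# deterministic label vector matching requested proportions within +/- 1
labels_from_proportions <- function(n, proportions) {
  counts <- allocate_lr(proportions * n, rep(n, length(proportions)), n)
  sample(rep(seq_along(proportions) - 1L, counts))
}

generate_fixture <- function(n_samples, image_size, labels, bits_for_label,
                             palettes, shapes, stripes_flags, out_dir,
                             class_names, noise_sd = 8) {
  if (image_size < 16) stop("image_size must be at least 16")
  img_dir <- file.path(out_dir, "images")
  mask_dir <- file.path(out_dir, "masks")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) |
    dir.exists(img_dir)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(mask_dir)) {
    stop("cannot create output directories under: ", out_dir)
  }
  modality_names <- names(palettes)
  n_mod <- length(modality_names)
  ids <- sprintf("s%04d", seq_len(n_samples))
  images_col <- vector("list", n_samples)
  masks_col <- vector("list", n_samples)
  bit_strings <- character(n_samples)
  for (i in seq_len(n_samples)) {
    bits <- bits_for_label(labels[i])
    geo <- draw_lesion_geometry(image_size)
    img_paths <- character(n_mod)
    mask_paths <- character(n_mod)
    for (j in seq_len(n_mod)) {
      r <- render_modality(image_size, geo, palettes[[j]], bits[j],
                           noise_sd = noise_sd, shape = shapes[[j]](bits[j]),
                           stripes = stripes_flags[j])
      img_paths[j] <- file.path("images",
                                sprintf("%s_%s.png", ids[i], modality_names[j]))
      mask_paths[j] <- file.path("masks",
                                 sprintf("%s_%s_mask.png", ids[i], modality_names[j]))
      write_png_255(r$image, file.path(out_dir, img_paths[j]))
      png::writePNG(r$mask, file.path(out_dir, mask_paths[j]))
    }
    names(img_paths) <- modality_names
    names(mask_paths) <- modality_names
    images_col[[i]] <- img_paths
    masks_col[[i]] <- mask_paths
    bit_strings[i] <- paste(bits, collapse = "")
  }
  rec <- tibble::tibble(sample_id = ids, label = as.integer(labels),
                        images = images_col, masks = masks_col,
                        bits = bit_strings)
  m <- manifest(modality_names, class_names, rec, root = out_dir)
  write_manifest(m, file.path(out_dir, "manifest.json"))
  m
}

#' Generate a synthetic 5-modality, 3-class fixture
#'
#' Emulates a VISIA-style disfiguring-dermatosis dataset: five co-registered
#' modalities (spots, red marks, UV spots, porphyrins, brown spots) and
#' three classes.  Each modality's lesion takes one of two modality-specific
#' colors (its bit); the class label is `sum(bits) mod 3`, so the label is
#' decodable only by combining modalities.  Writes `n_samples * 5` images,
#' the per-modality lesion masks, and a JSON/CSV manifest recording labels
#' and ground-truth bits.
#'
#' @param n_samples number of samples (>= number of classes).
#' @param image_size square image side, >= 16.
#' @param class_proportions length-3 proportions of the classes.
#' @param seed integer seed; the fixture is fully deterministic given it.
#' @param out_dir output directory (created if needed).
#' @param noise_sd Gaussian pixel-noise standard deviation (0..255 units).
#' @return the written `switchnet_manifest`.
#' @export
generate_dd_fixture <- function(n_samples, image_size = 32,
                                class_proportions = c(1, 1, 1) / 3,
                                seed = 1L, out_dir, noise_sd = 8) {
  stopifnot(n_samples >= 3)
  set.seed(seed)
  labels <- labels_from_proportions(n_samples, class_proportions)
  bits_for_label <- function(lab) {
    repeat {
      bits <- sample(0:1, 5, replace = TRUE)
      if (sum(bits) %% 3 == lab) return(bits)
    }
  }
  pals <- dd_palettes()
  generate_fixture(n_samples, image_size, labels, bits_for_label, pals,
                   shapes = rep(list(function(b) "ellipse"), 5),
                   stripes_flags = rep(FALSE, 5), out_dir = out_dir,
                   class_names = c("dermatitis", "melasma", "acne"),
                   noise_sd = noise_sd)
}

#' Generate a synthetic two-modality melanoma-style fixture
#'
#' Emulates a clinical + dermoscopic pair dataset with a binary label
#' (melanoma vs non-melanoma skin cancer) and the reference class imbalance
#' by default.  The clinical modality carries a global shape-and-color cue
#' (round red vs square blue lesion); the dermoscopic modality a
#' texture-and-color cue (smooth tan vs striped dark lesion).  The label is
#' the XOR of the two bits, so neither modality alone predicts it.
#'
#' @param n_samples number of samples.
#' @param image_size square image side, >= 16.
#' @param positive_fraction fraction of melanoma (label 1) samples; the
#'   melanoma count is `round(positive_fraction * n_samples)`.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @return the written `switchnet_manifest`.
#' @export
generate_derm7pt_fixture <- function(n_samples, image_size = 32,
                                     positive_fraction = 252 / 1011,
                                     seed = 1L, out_dir, noise_sd = 8) {
  stopifnot(positive_fraction > 0, positive_fraction < 1, n_samples >= 2)
  set.seed(seed)
  n_pos <- round(positive_fraction * n_samples)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n_samples - n_pos)))
  bits_for_label <- function(lab) {
    b1 <- sample(0:1, 1)
    c(b1, bitwXor(b1, lab))
  }
  pals <- derm7pt_palettes()
  generate_fixture(n_samples, image_size, labels, bits_for_label, pals,
                   shapes = list(function(b) if (b == 1) "square" else "ellipse",
                                 function(b) "ellipse"),
                   stripes_flags = c(FALSE, TRUE), out_dir = out_dir,
                   class_names = c("nmsc", "mm"), noise_sd = noise_sd)
}

#' Decode fixture bits from rendered images (construction oracle)
#'
#' Recovers each modality's planted bit by comparing the mean lesion color
#' (inside the stored mask) against the two palette colors, then re-derives
#' the label from the parity rule.  Used to verify that the cross-modal
#' signal is intact: the oracle must reach accuracy 1 while any
#' single-modality readout stays near chance.
#'
#' @param m a fixture manifest (must carry masks and bits).
#' @param preset `"dd"` or `"derm7pt"` (selects palettes and parity rule).
#' @return tibble: sample_id, label, decoded_label, decoded_bits.
#' @export
decode_fixture_oracle <- function(m, preset = c("dd", "derm7pt")) {
  preset <- match.arg(preset)
  pals <- if (preset == "dd") dd_palettes() else derm7pt_palettes()
  n_mod <- length(m$modality_names)
  res <- purrr::map_dfr(m$records$sample_id, function(sid) {
    s <- load_sample(m, sid)
    bits <- integer(n_mod)
    for (j in seq_len(n_mod)) {
      msk <- s$masks[[j]] == 1
      mc <- vapply(1:3, function(ch) mean(s$images[[j]][, , ch][msk]), numeric(1))
      dists <- apply(pals[[j]]$col, 1, function(col) sum((mc - col)^2))
      bits[j] <- which.min(dists) - 1L
    }
    lab <- if (preset == "dd") sum(bits) %% 3 else bitwXor(bits[1], bits[2])
    tibble::tibble(sample_id = sid, label = s$label,
                   decoded_label = as.integer(lab),
                   decoded_bits = paste(bits, collapse = ""))
  })
  res
}
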