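# Per-modality z-score normalization.
#
# Each modality i is standardised with channel-wise statistics fitted over
# all training-split pixels of that modality:
#
#   Z_i = (X_i - mu_i) / sigma_i
#
# with mu_i the per-channel mean and sigma_i the population (1/N) standard
# deviation, N being the total pixel count of the modality across the
# training split.  Statistics are dataset-level, not per-image, so relative
# brightness between images remains informative.

#' Fit normalization statistics on the training split
#'
#' @param m a `switchnet_manifest`.
#' @param split a `switchnet_split` (its `train_ids` are used); `NULL` uses
#'   all records.
#' @param modalities indices of modalities to fit (default: all).
#' @return a `switchnet_norm_stats` object: per modality, channel `mean`,
#'   `std` (floored at 1e-6) and `pixel_count`.
#' @export
fit_normalization_stats <- function(m, split = NULL, modalities = NULL) {
  ids <- if (is.null(split)) m$records$sample_id else split$train_ids
  if (length(ids) == 0) stop("training split is empty")
  if (is.null(modalities)) modalities <- seq_along(m$modality_names)
  stats_list <- vector("list", length(m$modality_names))
  names(stats_list) <- m$modality_names
  acc <- lapply(modalities, function(j) list(s = rep(0, 3), s2 = rep(0, 3), n = 0))
  names(acc) <- as.character(modalities)
  for (sid in ids) {
    s <- load_sample(m, sid)
    for (j in modalities) {
      x <- s$images[[j]]
      npix <- dim(x)[1] * dim(x)[2]
      a <- acc[[as.character(j)]]
      for (ch in 1:3) {
        a$s[ch] <- a$s[ch] + sum(x[, , ch])
        a$s2[ch] <- a$s2[ch] + sum(x[, , ch]^2)
      }
      a$n <- a$n + npix
      acc[[as.character(j)]] <- a
    }
  }
  for (j in modalities) {
    a <- acc[[as.character(j)]]
    mu <- a$s / a$n
    v <- a$s2 / a$n - mu^2          # population variance, 1/N
    v[v < 0] <- 0
    sd_ <- sqrt(v)
    if (any(sd_ < 1e-6)) {
      warning("zero-variance channel in modality '", m$modality_names[j],
              "'; std floored at 1e-6")
      sd_ <- pmax(sd_, 1e-6)
    }
    stats_list[[j]] <- list(mean = mu, std = sd_, pixel_count = a$n)
  }
  structure(list(modalities = stats_list,
                 modality_names = m$modality_names),
            class = "switchnet_norm_stats")
}

#' @export
print.switchnet_norm_stats <- function(x, ...) {
  cat("<switchnet_norm_stats>\n")
  for (nm in names(x$modalities)) {
    s <- x$modalities[[nm]]
    if (is.null(s)) next
    cat(sprintf("  %-12s mean (%.1f, %.1f, %.1f)  std (%.1f, %.1f, %.1f)\n",
                nm, s$mean[1], s$mean[2], s$mean[3],
                s$std[1], s$std[2], s$std[3]))
  }
  invisible(x)
}

#' Z-score normalize one image with one modality's statistics
#'
#' @param img (H, W, 3) array in pixel units.
#' @param stats_mod one element of `switchnet_norm_stats$modalities`.
#' @return normalized array of the same shape.
#' @export
normalize_image <- function(img, stats_mod) {
  if (length(dim(img)) != 3 || dim(img)[3] != length(stats_mod$mean)) {
    stop("image channel count does not match the normalization stats")
  }
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- (img[, , ch] - stats_mod$mean[ch]) / stats_mod$std[ch]
  }
  out
}

#' Invert z-score normalization
#' @inheritParams normalize_image
#' @export
denormalize_image <- function(img, stats_mod) {
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- img[, , ch] * stats_mod$std[ch] + stats_mod$mean[ch]
  }
  out
}

#' Write / read normalization stats as JSON
#'
#' @param stats a `switchnet_norm_stats`.
#' @param path JSON file path.
#' @return `path` (write) or the stats object (read).
#' @export
write_norm_stats <- function(stats, path) {
  out <- lapply(stats$modalities, function(s) {
    list(mean = s$mean, std = s$std, pixel_count = s$pixel_count)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mods <- lapply(j, function(s) {
    list(mean = as.numeric(s$mean), std = as.numeric(s$std),
         pixel_count = s$pixel_count)
  })
  structure(list(modalities = mods, modality_names = names(mods)),
            class = "switchnet_norm_stats")
}
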