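stats_of <- function(mu, sd_) list(mean = mu, std = sd_, pixel_count = NA)

test_that("normalization stats match a direct per-pixel accumulation oracle", {
  m <- dd_small_manifest()
  sp <- split_dataset(m$records$sample_id, seed = 2, labels = m$records$label)
  st <- fit_normalization_stats(m, sp)
  # brute force: gather every training pixel of modality 1 and reduce
  px <- lapply(1:3, function(ch) {
    unlist(lapply(sp$train_ids, function(sid) {
      as.vector(load_sample(m, sid)$images[[1]][, , ch])
    }))
  })
  mu <- vapply(px, mean, numeric(1))
  sd_pop <- vapply(px, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  expect_equal(st$modalities[[1]]$mean, mu, tolerance = 1e-9)
  expect_equal(st$modalities[[1]]$std, sd_pop, tolerance = 1e-9)
  expect_equal(st$modalities[[1]]$pixel_count, 24 * 24 * length(sp$train_ids))
})

test_that("two-point and degenerate statistics behave as defined", {
  # two 1x1 images with red values 0 and 100: population mean 50, std 50
  td <- file.path(tempdir(), "normfix")
  dir.create(td, showWarnings = FALSE)
  png::writePNG(array(c(0, 0, 0) / 255, dim = c(1, 1, 3)),
                file.path(td, "a.png"))
  png::writePNG(array(c(100, 0, 0) / 255, dim = c(1, 1, 3)),
                file.path(td, "b.png"))
  rec <- tibble::tibble(sample_id = c("a", "b"), label = c(0L, 0L),
                        images = list(c(mod = "a.png"), c(mod = "b.png")))
  m <- manifest("mod", c("only", "other"), rec, root = td)
  st <- suppressWarnings(fit_normalization_stats(m))
  expect_equal(st$modalities[[1]]$mean[1], 50)
  expect_equal(st$modalities[[1]]$std[1], 50)
  # constant channels floor sigma at 1e-6 with a warning
  expect_warning(fit_normalization_stats(m), "floored")
  expect_equal(st$modalities[[1]]$std[2], 1e-6)
  expect_equal(st$modalities[[1]]$mean[2], 0)
})

test_that("z-scoring maps mu to 0, mu+sigma to 1, and inverts cleanly", {
  sm <- stats_of(c(10, 20, 30), c(2, 4, 8))
  img <- array(rep(c(10, 20, 30), each = 4), dim = c(2, 2, 3))
  z <- normalize_image(img, sm)
  expect_equal(max(abs(z)), 0)
  img1 <- array(rep(c(12, 24, 38), each = 4), dim = c(2, 2, 3))
  expect_equal(as.vector(normalize_image(img1, sm)[1, 1, ]), c(1, 1, 1))

  set.seed(1)
  x <- array(runif(4 * 4 * 3, 0, 255), dim = c(4, 4, 3))
  expect_equal(denormalize_image(normalize_image(x, sm), sm), x,
               tolerance = 1e-6)
  expect_error(normalize_image(array(0, dim = c(2, 2, 1)), sm), "channel")
})

test_that("fitted stats close the loop: normalized training split is ~N(0,1)", {
  m <- xor_manifest()
  sp <- split_dataset(m$records$sample_id, seed = 3, labels = m$records$label)
  st <- fit_normalization_stats(m, sp)
  for (j in 1:2) {
    px <- lapply(1:3, function(ch) {
      unlist(lapply(sp$train_ids, function(sid) {
        z <- normalize_image(load_sample(m, sid)$images[[j]],
                             st$modalities[[j]])
        as.vector(z[, , ch])
      }))
    })
    for (v in px) {
      expect_lt(abs(mean(v)), 1e-5)
      expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-5)
    }
  }
})

test_that("stats survive a JSON round trip", {
  m <- dd_small_manifest()
  st <- fit_normalization_stats(m)
  p <- tempfile(fileext = ".json")
  write_norm_stats(st, p)
  st2 <- read_norm_stats(p)
  expect_equal(st2$modalities[[3]]$mean, st$modalities[[3]]$mean)
  expect_equal(st2$modalities[[3]]$std, st$modalities[[3]]$std)
})

test_that("resize contracts: output dims, identity, mask area scaling", {
  m <- dd_small_manifest()
  s <- load_sample(m, m$records$sample_id[2])
  r <- resize_sample(s, 48)
  expect_equal(dim(r$images[[1]]), c(48, 48, 3))
  expect_equal(dim(r$masks[[1]]), c(48, 48))
  # 64 -> 32 halves each dimension: mask area ratio ~ 1/4
  big <- resize_sample(s, 64)
  small <- resize_sample(big, 32)
  ratio <- sum(small$masks[[1]]) / sum(big$masks[[1]])
  expect_lt(abs(ratio - 0.25), 0.08)
  expect_error(resize_sample(s, 8), "at least 16")
})

test_that("disabled augmentation and zero probabilities are the identity", {
  m <- dd_small_manifest()
  s <- load_sample(m, m$records$sample_id[1])
  off <- augmentation_config(enabled = FALSE)
  expect_identical(augment_sample(s, off), s)
  zero <- augmentation_config(jitter_prob = 0, crop_prob = 0, flip_prob = 0,
                              rotate_prob = 0)
  set.seed(1)
  expect_equal(augment_sample(s, zero), s)
})

test_that("each transform fires at its configured probability", {
  # detect firing through the transform's observable effect, one transform
  # enabled at a time; empirical rate must sit within 3 standard errors
  m <- xor_manifest()
  s <- resize_sample(load_sample(m, m$records$sample_id[1]), 16)
  rate_of <- function(cfg, n_trials, changed) {
    hits <- 0
    for (i in seq_len(n_trials)) {
      a <- augment_sample(s, cfg)
      if (changed(a)) hits <- hits + 1
    }
    hits / n_trials
  }
  img_changed <- function(a) !isTRUE(all.equal(a$images[[1]], s$images[[1]]))

  set.seed(42)
  n <- 4000   # cheap array-level transforms
  p <- rate_of(augmentation_config(jitter_prob = 0.2, crop_prob = 0,
                                   flip_prob = 0, rotate_prob = 0),
               n, img_changed)
  expect_lt(abs(p - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  p <- rate_of(augmentation_config(jitter_prob = 0, crop_prob = 0,
                                   flip_prob = 0.1, rotate_prob = 0),
               n, img_changed)
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  n <- 500    # interpolation-backed transforms
  p <- rate_of(augmentation_config(jitter_prob = 0, crop_prob = 0.3,
                                   flip_prob = 0, rotate_prob = 0),
               n, img_changed)
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  p <- rate_of(augmentation_config(jitter_prob = 0, crop_prob = 0,
                                   flip_prob = 0, rotate_prob = 0.2),
               n, img_changed)
  expect_lt(abs(p - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("spatial transforms stay synchronized across modalities", {
  m <- dd_small_manifest()
  s <- load_sample(m, m$records$sample_id[3])
  centroid <- function(msk) {
    idx <- which(msk == 1, arr.ind = TRUE)
    colMeans(idx)
  }
  # force a flip; all modality masks must reflect identically
  cfg <- augmentation_config(jitter_prob = 0, crop_prob = 0, flip_prob = 1,
                             rotate_prob = 0)
  set.seed(9)
  a <- augment_sample(s, cfg)
  cents <- t(vapply(a$masks, centroid, numeric(2)))
  expect_lt(max(apply(cents, 2, function(v) diff(range(v)))), 1e-9)
  # and relate to the original by the same reflection in every modality
  orig <- t(vapply(s$masks, centroid, numeric(2)))
  flipped_h <- abs(orig[, 2] - (24 + 1 - cents[, 2])) < 1e-9
  flipped_v <- abs(orig[, 1] - (24 + 1 - cents[, 1])) < 1e-9
  expect_true(all(flipped_h) || all(flipped_v))

  # forced rotation keeps masks co-registered across modalities
  cfg <- augmentation_config(jitter_prob = 0, crop_prob = 0, flip_prob = 0,
                             rotate_prob = 1)
  set.seed(10)
  a <- augment_sample(s, cfg)
  ref <- a$masks[[1]]
  for (j in 2:5) expect_identical(a$masks[[j]], ref)
})
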