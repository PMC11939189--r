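disk_heatmap <- function(size, cx, cy, r, value = 1) {
  hm <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) hm[i, j] <- value
    }
  }
  hm
}

test_that("heatmaps are rectified, max-normalised and logit-shift invariant", {
  fit <- tiny_fit()
  m <- xor_manifest()
  s <- load_sample(m, fit$split$train_ids[1])
  cam <- grad_cam(fit, s, target_class = s$label, stage = 3)
  for (j in 1:2) {
    hm <- cam$heatmaps[[j]]
    expect_true(all(hm >= 0))
    if (!cam$degenerate[j]) expect_equal(max(hm), 1)
    expect_equal(dim(hm), c(32, 32))
  }
  # adding a constant to every logit cannot change a single logit's gradient
  shifted <- fit
  shifted$model$params[["head.fc.b"]] <-
    shifted$model$params[["head.fc.b"]] + 7
  cam2 <- grad_cam(shifted, s, target_class = s$label, stage = 3)
  for (j in 1:2) {
    expect_equal(cam2$heatmaps[[j]], cam$heatmaps[[j]], tolerance = 1e-10)
  }
})

test_that("a linear single-conv model recovers the closed-form activation map", {
  # one modality, one 1x1-conv "backbone" equivalent: use the head alone.
  # cam = relu(sum_c w_c * z_c) with w_c the pooled gradient; for a linear
  # head on GAP features the gradient of logit k wrt z_c is constant over
  # space: W_fc[k, ] %*% W_conv[, c] / (h * w), so the cam is proportional
  # to that fixed channel weighting of the feature map.
  set.seed(31)
  cc <- 4; r <- 3; h <- 4
  params <- list(
    head.conv.W = array(rnorm(cc * r), dim = c(1, 1, cc, r)),
    head.conv.b = rnorm(r),
    head.fc.W = matrix(rnorm(2 * r), 2, r),
    head.fc.b = rnorm(2)
  )
  z <- array(rnorm(h * h * cc), dim = c(h, h, cc, 1))
  hd <- head_fwd(params, list(z), NULL)
  # emulate grad-cam at the head input
  dlog <- matrix(c(1, 0), 2, 1)
  gacc <- new.env(); gacc$g <- list()
  dz <- head_bwd(gacc, hd$cache, dlog)[[1]]
  wts <- apply(dz, 3, mean)
  cam <- matrix(0, h, h)
  for (ch in seq_len(cc)) cam <- cam + wts[ch] * z[, , ch, 1]
  cam <- pmax(cam, 0)
  # closed form: channel weights = W_fc[1, ] %*% conv weights / (h*h)
  wconv <- params[["head.conv.W"]][1, 1, , ]            # cc x r
  wfc <- params[["head.fc.W"]][1, seq_len(r)]
  wts_ref <- as.vector(wconv %*% wfc) / (h * h)
  cam_ref <- matrix(0, h, h)
  for (ch in seq_len(cc)) cam_ref <- cam_ref + wts_ref[ch] * z[, , ch, 1]
  cam_ref <- pmax(cam_ref, 0)
  expect_equal(cam, cam_ref, tolerance = 1e-5)
})

test_that("contour extraction finds planted components", {
  hm <- disk_heatmap(40, 20, 20, 8)
  ct <- extract_lesion_contours(hm, 0.5)
  expect_length(ct, 1)
  expect_true(all(ct[[1]][, 1] >= 1 & ct[[1]][, 1] <= 40))
  # polygon encloses approximately the disk area
  expect_lt(abs(nrow(ct[[1]]) - 2 * pi * 8) / (2 * pi * 8), 0.35)

  expect_length(extract_lesion_contours(matrix(0, 8, 8)), 0)

  two <- disk_heatmap(40, 10, 10, 5) + disk_heatmap(40, 30, 30, 5)
  ct2 <- extract_lesion_contours(two, 0.5)
  expect_length(ct2, 2)
  # enclosed areas match the blobs within discretisation slack
  for (poly in ct2) {
    area <- 0.5 * abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                            poly[, 2] * c(poly[-1, 1], poly[1, 1])))
    expect_lt(abs(area - pi * 25) / (pi * 25), 0.35)
  }
  # tiny specks below the area floor are dropped
  speck <- matrix(0, 40, 40); speck[5, 5] <- 1
  expect_length(extract_lesion_contours(speck, 0.5, min_area_frac = 0.01), 0)
})

test_that("region overlap scoring follows set arithmetic", {
  msk <- matrix(0, 10, 10); msk[3:6, 3:6] <- 1
  expect_equal(cam_roi_overlap(msk, msk), 1)
  other <- matrix(0, 10, 10); other[8:9, 8:9] <- 1
  expect_equal(cam_roi_overlap(msk, other), 0)
  half <- matrix(0, 10, 10); half[3:6, 3:4] <- 1   # nested, half the area
  expect_equal(cam_roi_overlap(half, msk), 0.5)
  expect_warning(iou <- cam_roi_overlap(msk, matrix(0, 10, 10)), "empty")
  expect_true(is.na(iou))
})

test_that("heatmaps localise planted lesions better than a permuted null", {
  fit <- tiny_fit()
  m <- xor_manifest()
  ids <- fit$split$train_ids[1:12]
  ious <- c()
  cams <- list()
  samples <- list()
  for (k in seq_along(ids)) {
    s <- load_sample(m, ids[k])
    cam <- grad_cam(fit, s, target_class = s$label, stage = 3)
    samples[[k]] <- s; cams[[k]] <- cam
    for (j in 1:2) {
      ious <- c(ious, cam_roi_overlap(cam$heatmaps[[j]], s$masks[[j]]))
    }
  }
  # permuted-mask null, three seeded repetitions
  null_means <- vapply(1:3, function(rep) {
    set.seed(rep)
    perm <- sample(seq_along(ids))
    while (any(perm == seq_along(ids))) perm <- sample(seq_along(ids))
    mean(unlist(lapply(seq_along(ids), function(k) {
      vapply(1:2, function(j) {
        cam_roi_overlap(cams[[k]]$heatmaps[[j]], samples[[perm[k]]]$masks[[j]])
      }, numeric(1))
    })))
  }, numeric(1))
  expect_gt(mean(ious), max(null_means))
})

test_that("overlays are written deterministically, one file per modality", {
  fit <- tiny_fit()
  m <- xor_manifest()
  s <- load_sample(m, fit$split$train_ids[2])
  cam <- grad_cam(fit, s, target_class = s$label, stage = 3)
  d1 <- file.path(tempdir(), "ov1"); d2 <- file.path(tempdir(), "ov2")
  p1 <- render_overlay(s, cam, d1)
  p2 <- render_overlay(s, cam, d2)
  expect_length(p1, 2)
  expect_true(all(file.exists(p1)))
  expect_identical(readBin(p1[1], "raw", file.size(p1[1])),
                   readBin(p2[1], "raw", file.size(p2[1])))
  panel <- png::readPNG(p1[1])
  expect_equal(dim(panel)[2], 32)            # width = input width
  expect_equal(dim(panel)[1] %% 32, 0)       # stacked full-size rows
  unlink(c(d1, d2), recursive = TRUE)
})
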