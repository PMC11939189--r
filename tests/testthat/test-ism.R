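test_that("token sequencing and its inverse are exact", {
  xs <- random_maps(3, 4, 4, 6, batch = 2, seed = 1)
  seqs <- stack_and_sequence(xs)
  expect_equal(dim(seqs), c(6, 3, 4 * 4 * 2))
  back <- sequence_to_maps(seqs)
  for (i in 1:3) expect_identical(back[[i]], xs[[i]])

  # n = 2, 1x1 spatial, c = 3: tokens are the channel vectors in order
  a <- array(c(1, 2, 3), dim = c(1, 1, 3, 1))
  b <- array(c(4, 5, 6), dim = c(1, 1, 3, 1))
  sq <- stack_and_sequence(list(a, b))
  expect_equal(as.vector(sq[, 1, 1]), c(1, 2, 3))
  expect_equal(as.vector(sq[, 2, 1]), c(4, 5, 6))

  # batch 2, 2x2 spatial -> 8 sequences
  xs <- random_maps(2, 2, 2, 5, batch = 2, seed = 2)
  expect_equal(dim(stack_and_sequence(xs))[3], 8)
  expect_error(stack_and_sequence(list(a, array(0, dim = c(2, 2, 3, 1)))),
               "share one shape")
})

test_that("attention obeys its closed forms", {
  # n = 1: softmax of a scalar is 1, so H = V
  set.seed(3)
  q <- array(rnorm(4 * 1 * 6), dim = c(4, 1, 6))
  v <- array(rnorm(4 * 1 * 6), dim = c(4, 1, 6))
  expect_equal(attention(q, q, v, 4)$out, v)

  # identical K rows: uniform weights, every output row is the V column mean
  n <- 3
  k <- array(rep(rnorm(2), times = n * 5), dim = c(2, n, 5))
  for (t in 1:5) k[, , t] <- k[, , 1]
  set.seed(4)
  q2 <- array(rnorm(2 * n * 5), dim = c(2, n, 5))
  v2 <- array(rnorm(2 * n * 5), dim = c(2, n, 5))
  h <- attention(q2, k, v2, 2)
  for (t in 1:5) {
    mean_v <- rowMeans(matrix(v2[, , t], nrow = 2))
    for (a in 1:n) expect_equal(h$out[, a, t], mean_v, tolerance = 1e-12)
  }

  # hand-enumerated 2x2 softmax: Q = K = (1, 2), V = (0, 1), d = 1
  q3 <- array(c(1, 2), dim = c(1, 2, 1))
  h3 <- attention(q3, q3, array(c(0, 1), dim = c(1, 2, 1)), 1)
  expect_equal(as.vector(h3$out[1, , 1]),
               c(1 / (1 + exp(-1)), 1 / (1 + exp(-2))), tolerance = 1e-12)
  expect_error(attention(q3, q3, q3, 0), "positive")
})

test_that("attention rows are a probability distribution", {
  set.seed(5)
  for (n in c(2, 5)) {
    q <- array(rnorm(3 * n * 20, sd = 3), dim = c(3, n, 20))
    k <- array(rnorm(3 * n * 20, sd = 3), dim = c(3, n, 20))
    v <- array(rnorm(3 * n * 20), dim = c(3, n, 20))
    at <- attention(q, k, v, 3)
    expect_true(all(at$attn >= 0))
    sums <- apply(at$attn, c(1, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
})

test_that("vectorised multi-head switch equals the explicit loop oracle", {
  cfgs <- list(list(n = 3, cc = 8, m = 2, d = 2, hw = 2),
               list(n = 5, cc = 6, m = 2, d = 3, hw = 4),
               list(n = 2, cc = 4, m = 1, d = 4, hw = 3))
  for (cf in cfgs) {
    set.seed(cf$n * 100 + cf$cc)
    params <- list()
    stage <- 1
    for (j in seq_len(cf$m)) {
      for (nm in c("q", "k", "v")) {
        params[[sprintf("ism.s1.W%s.%d", nm, j)]] <-
          matrix(rnorm(cf$d * cf$cc, sd = 0.5), cf$d, cf$cc)
        params[[sprintf("ism.s1.b%s.%d", nm, j)]] <- rnorm(cf$d, sd = 0.2)
      }
    }
    params[["ism.s1.Wo"]] <- matrix(rnorm(cf$cc * cf$m * cf$d, sd = 0.5),
                                    cf$cc, cf$m * cf$d)
    params[["ism.s1.bo"]] <- rnorm(cf$cc, sd = 0.2)
    xs <- random_maps(cf$n, cf$hw, cf$hw, cf$cc)
    seqs <- stack_and_sequence(xs)
    fast <- multi_head_switch(seqs, params, 1, cf$m, cf$d)$out
    slow <- naive_multi_head_switch(seqs, params, 1, cf$m, cf$d)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("zero output projection collapses the switch to its bias", {
  set.seed(6)
  cc <- 4; m <- 2; d <- 2
  params <- list()
  for (j in 1:m) {
    for (nm in c("q", "k", "v")) {
      params[[sprintf("ism.s1.W%s.%d", nm, j)]] <- matrix(rnorm(d * cc), d, cc)
      params[[sprintf("ism.s1.b%s.%d", nm, j)]] <- rnorm(d)
    }
  }
  params[["ism.s1.Wo"]] <- matrix(0, cc, m * d)
  params[["ism.s1.bo"]] <- c(1, -2, 3, 4)
  seqs <- stack_and_sequence(random_maps(2, 2, 2, cc))
  out <- multi_head_switch(seqs, params, 1, m, d)$out
  for (t in seq_len(dim(out)[3])) {
    for (i in 1:2) expect_equal(as.vector(out[, i, t]), c(1, -2, 3, 4))
  }
})

test_that("feature blending follows the printed formula and its variants", {
  ones <- function(v) array(v, dim = c(2, 2, 1, 1))
  xs <- lapply(c(1, 2, 3), ones)
  ys <- lapply(c(10, 20, 30), ones)
  # alpha = 1 returns the inputs bit-exactly in every mode
  for (mode in c("sum_others", "self", "mean_others")) {
    z <- mix_features(xs, ys, alpha = 1, mix_mode = mode)
    for (i in 1:3) expect_identical(z[[i]], xs[[i]])
  }
  # alpha = 0 with mode self returns the switched features
  z <- mix_features(xs, ys, alpha = 0, mix_mode = "self")
  for (i in 1:3) expect_identical(z[[i]], ys[[i]])
  # n = 3, alpha = 0.5, sum over others: Z1 = 0.5*1 + 0.5*(20+30) = 25.5
  z <- mix_features(xs, ys, alpha = 0.5, mix_mode = "sum_others")
  expect_equal(unique(as.vector(z[[1]])), 25.5)
  expect_equal(unique(as.vector(z[[2]])), 21)
  expect_equal(unique(as.vector(z[[3]])), 16.5)
  # mean over others divides by n - 1
  z <- mix_features(xs, ys, alpha = 0.5, mix_mode = "mean_others")
  expect_equal(unique(as.vector(z[[1]])), 0.5 * 1 + 0.5 * 25)
  # n = 1 with sum_others: the empty sum is the zero map
  z1 <- mix_features(xs[1], ys[1], alpha = 0.5, mix_mode = "sum_others")
  expect_equal(unique(as.vector(z1[[1]])), 0.5)
})

test_that("the switch is equivariant to modality permutation", {
  model <- build_model(backbone_config("tiny"), ism_config(),
                       n_modalities = 3, n_classes = 2, seed = 11)
  xs <- random_maps(3, 4, 4, model$config$backbone$stages[[3]]$channels,
                    seed = 12)
  for (mode in c("sum_others", "self", "mean_others")) {
    cfg <- model$config$ism
    cfg$mix_mode <- mode
    out <- ism_stage_fwd(model$params, model$config$backbone, cfg, 3, xs)$out
    perm <- c(3, 1, 2)
    out_p <- ism_stage_fwd(model$params, model$config$backbone, cfg, 3,
                           xs[perm])$out
    for (i in seq_along(perm)) {
      expect_lt(max(abs(out_p[[i]] - out[[perm[i]]])), 1e-5)
    }
  }
})

test_that("alpha pinned at 1 reduces the interleaved pass to the backbone", {
  model <- build_model(backbone_config("tiny"), ism_config(),
                       n_modalities = 2, n_classes = 2, seed = 13)
  for (s in 1:8) model$params[[sprintf("ism.s%d.alpha_raw", s)]] <- Inf
  set.seed(14)
  inputs <- random_maps(2, 32, 32, 3, batch = 1)
  fw <- interleaved_forward(model, inputs)
  senv <- new.env(); senv$s <- model$state
  for (i in 1:2) {
    solo <- extract_all_stages(model$params, senv, model$config$backbone,
                               inputs[[i]])
    # the interleaved pass runs all modalities as one combined batch, so
    # BLAS summation order can differ from a single-modality pass in the
    # last ulp; the blend itself is exact (alpha = 1 keeps X bit-for-bit)
    expect_equal(fw$z8[[i]], solo[[8]], tolerance = 1e-12)
  }
})

test_that("identical inputs with self-mixing give identical outputs per modality", {
  cfg <- ism_config(mix_mode = "self")
  model <- build_model(backbone_config("tiny"), cfg,
                       n_modalities = 3, n_classes = 2, seed = 15)
  set.seed(16)
  x <- array(rnorm(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  fw <- interleaved_forward(model, list(x, x, x))
  expect_equal(fw$z8[[1]], fw$z8[[2]], tolerance = 1e-10)
  expect_equal(fw$z8[[2]], fw$z8[[3]], tolerance = 1e-10)
})

test_that("gradients reach the blending weights", {
  model <- build_model(backbone_config("tiny"), ism_config(),
                       n_modalities = 2, n_classes = 2, seed = 17)
  set.seed(18)
  inputs <- random_maps(2, 32, 32, 3, batch = 2)
  fw <- interleaved_forward(model, inputs, training = TRUE, keep_cache = TRUE)
  lr <- wce_from_logits(fw$logits, c(0L, 1L))
  bw <- model_backward(model, fw, lr$dlogits)
  agrads <- vapply(1:8, function(s) {
    bw$grads[[sprintf("ism.s%d.alpha_raw", s)]]
  }, numeric(1))
  expect_true(all(is.finite(agrads)))
  expect_gt(max(abs(agrads)), 0)
})
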