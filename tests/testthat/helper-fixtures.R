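# Shared, memoised fixtures so expensive artifacts (generated image sets and
# one trained tiny model) are built once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 96-sample two-modality parity fixture: the ablation / training workhorse
xor_manifest <- function() {
  memo("xor_manifest", function() {
    out <- file.path(tempdir(), "switchnet-xor-fixture")
    generate_derm7pt_fixture(96, 32, positive_fraction = 0.5, seed = 11,
                             out_dir = out)
  })
}

# small 5-modality, 3-class fixture for data-layer tests
dd_small_manifest <- function() {
  memo("dd_small_manifest", function() {
    out <- file.path(tempdir(), "switchnet-dd-fixture")
    generate_dd_fixture(30, 24, seed = 5, out_dir = out)
  })
}

# the standard tiny training recipe used by the harness experiments:
# augmentation off to isolate the optimisation path (augmentation has its
# own tests), everything else at the tiny-preset defaults
tiny_recipe <- function(epochs = 40, seed = 3, ...) {
  train_config("tiny", epochs = epochs, seed = seed,
               augment = augmentation_config(enabled = FALSE), ...)
}

# one converged interleaved-ISM fit on the parity fixture (restart-selected,
# the same protocol the ablation experiment uses)
tiny_fit <- function() {
  memo("tiny_fit", function() {
    train_restarts(xor_manifest(), ablation_config(seed = 3), restarts = 2)
  })
}

# independent brute-force multi-head attention switch: explicit loops over
# sequences and heads, used as the oracle against the vectorised path
naive_multi_head_switch <- function(seqs, params, stage, m, d) {
  cs <- dim(seqs)[1]; n <- dim(seqs)[2]; tt <- dim(seqs)[3]
  prefix <- sprintf("ism.s%d", stage)
  out <- array(0, dim = dim(seqs))
  wo <- params[[paste0(prefix, ".Wo")]]
  bo <- params[[paste0(prefix, ".bo")]]
  for (t in seq_len(tt)) {
    x <- matrix(seqs[, , t], nrow = cs)            # cs x n
    hs <- NULL
    for (j in seq_len(m)) {
      q <- params[[sprintf("%s.Wq.%d", prefix, j)]] %*% x +
        params[[sprintf("%s.bq.%d", prefix, j)]]
      k <- params[[sprintf("%s.Wk.%d", prefix, j)]] %*% x +
        params[[sprintf("%s.bk.%d", prefix, j)]]
      v <- params[[sprintf("%s.Wv.%d", prefix, j)]] %*% x +
        params[[sprintf("%s.bv.%d", prefix, j)]]
      sc <- crossprod(q, k) / sqrt(d)              # n x n
      a <- exp(sc - apply(sc, 1, max))
      a <- a / rowSums(a)
      h <- v %*% t(a)                              # d x n
      hs <- rbind(hs, h)
    }
    out[, , t] <- wo %*% hs + bo
  }
  out
}

# independent per-class metric enumeration from raw label vectors
naive_prf <- function(truth, pred, n_classes, averaging) {
  per <- lapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    list(p = p, r = r, f = f, support = sum(truth == k), tp = tp,
         fp = fp, fn = fn)
  })
  acc <- mean(truth == pred)
  if (averaging == "micro") {
    tp <- sum(sapply(per, `[[`, "tp"))
    fp <- sum(sapply(per, `[[`, "fp"))
    fn <- sum(sapply(per, `[[`, "fn"))
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    list(precision = p, recall = r, accuracy = acc,
         f1 = 2 * p * r / (p + r))
  } else {
    w <- if (averaging == "weighted") {
      sapply(per, `[[`, "support") / length(truth)
    } else rep(1 / n_classes, n_classes)
    list(precision = sum(sapply(per, `[[`, "p") * w),
         recall = sum(sapply(per, `[[`, "r") * w),
         accuracy = acc,
         f1 = sum(sapply(per, `[[`, "f") * w))
  }
}

random_maps <- function(n, h, w, cc, batch = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    array(stats::rnorm(h * w * cc * batch), dim = c(h, w, cc, batch))
  })
}

# internal entry points exercised directly by the white-box tests
softmax_cols <- switchnet:::softmax_cols
wce_from_logits <- switchnet:::wce_from_logits
head_fwd <- switchnet:::head_fwd
head_bwd <- switchnet:::head_bwd
gap_fwd <- switchnet:::gap_fwd
init_block <- switchnet:::init_block
ism_stage_fwd <- switchnet:::ism_stage_fwd
ism_stage_dims <- switchnet:::ism_stage_dims
build_batch <- switchnet:::build_batch
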