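test_that("confusion matrices count truth/prediction pairs", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(unname(diag(cm)), c(1L, 1L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2))

  set.seed(1)
  truth <- sample(0:3, 200, replace = TRUE)
  pred <- sample(0:3, 200, replace = TRUE)
  cm <- confusion_matrix(truth, pred, 4)
  expect_equal(unname(rowSums(cm)),
               vapply(0:3, function(k) sum(truth == k), integer(1)))
  expect_error(confusion_matrix(0:2, 0:1, 3), "equal length")
})

test_that("precision/recall/accuracy/f1 match the binary hand computation", {
  # truth rows, prediction columns; class 0 one-vs-rest: TP=2 FP=1 FN=0 TN=1
  cm <- matrix(c(2L, 1L, 0L, 1L), 2, 2)
  r <- prf_accuracy(cm, "macro")
  cls0 <- r$per_class[1, ]
  expect_equal(cls0$precision, 2 / 3)
  expect_equal(cls0$recall, 1)
  expect_equal(r$accuracy, 0.75)
  expect_equal(cls0$f1, 0.8)

  perfect <- diag(c(5L, 3L, 2L))
  for (avg in c("macro", "weighted", "micro")) {
    p <- prf_accuracy(perfect, avg)
    expect_equal(c(p$precision, p$recall, p$accuracy, p$f1), rep(1, 4))
  }
  expect_error(prf_accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("aggregate metrics equal an independent enumeration on random data", {
  set.seed(2)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    cm <- confusion_matrix(truth, pred, 3)
    for (avg in c("macro", "weighted", "micro")) {
      got <- suppressWarnings(prf_accuracy(cm, avg))
      ref <- naive_prf(truth, pred, 3, avg)
      expect_equal(got$precision, ref$precision, tolerance = 1e-12)
      expect_equal(got$recall, ref$recall, tolerance = 1e-12)
      expect_equal(got$accuracy, ref$accuracy, tolerance = 1e-12)
      expect_equal(got$f1, ref$f1, tolerance = 1e-12)
    }
  }
})

test_that("micro averaging collapses to accuracy for single-label data", {
  set.seed(3)
  truth <- sample(0:4, 300, replace = TRUE)
  pred <- sample(0:4, 300, replace = TRUE)
  r <- suppressWarnings(prf_accuracy(confusion_matrix(truth, pred, 5), "micro"))
  expect_equal(r$precision, r$accuracy, tolerance = 1e-12)
  expect_equal(r$recall, r$accuracy, tolerance = 1e-12)
})

test_that("average precision follows the rank enumeration", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(average_precision(c(0.3, 0.9, 0.1), c(0, 1, 0)), 1)
  expect_equal(average_precision(4:1, c(1, 1, 0, 0)), 1)
  # invariant under strictly monotone score transformations
  set.seed(4)
  sc <- runif(50); lb <- rbinom(50, 1, 0.4)
  expect_equal(average_precision(sc, lb), average_precision(exp(3 * sc), lb),
               tolerance = 1e-12)
  expect_warning(ap <- average_precision(c(0.2, 0.1), c(0, 0)), "no positive")
  expect_true(is.na(ap))
})

test_that("mAP averages one-vs-rest APs and sits at prevalence under the null", {
  # perfectly confident correct predictions
  probs <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(mean_average_precision(probs, c(0, 1, 2, 0))$mAP, 1)
  # two-class symmetry: mAP is the mean of the two APs
  set.seed(5)
  p1 <- runif(40)
  probs2 <- cbind(p1, 1 - p1)
  truth2 <- rbinom(40, 1, 0.5)
  mr <- mean_average_precision(probs2, truth2)
  expect_equal(mr$mAP, mean(mr$ap), tolerance = 1e-12)
  expect_equal(mr$ap[1], average_precision(p1, as.integer(truth2 == 0)))

  # permutation null: random scores on balanced labels concentrate at 0.5
  set.seed(6)
  n <- 1000
  truth <- rep(0:1, n / 2)
  nulls <- replicate(60, {
    sc <- runif(n)
    mean_average_precision(cbind(sc, 1 - sc), sample(truth))$mAP
  })
  obs <- mean_average_precision(cbind(runif(n), runif(n)), truth)$mAP
  expect_lt(abs(obs - 0.5), 3 * stats::sd(nulls) + abs(mean(nulls) - 0.5))
})

test_that("relabeling classes leaves mAP unchanged", {
  set.seed(7)
  probs <- t(softmax_cols(matrix(rnorm(3 * 80), 3, 80)))
  truth <- sample(0:2, 80, replace = TRUE)
  perm <- c(2L, 0L, 1L)          # new label of old class k is perm[k + 1]
  probs2 <- probs
  probs2[, perm + 1L] <- probs   # new class perm[k] carries old class k scores
  m1 <- mean_average_precision(probs, truth)$mAP
  m2 <- mean_average_precision(probs2, perm[truth + 1L])$mAP
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("evaluation reports are deterministic, bounded and serialisable", {
  fit <- tiny_fit()
  m <- xor_manifest()
  ids <- fit$split$val_ids
  e1 <- evaluate(fit$model, m, fit$stats, ids, 32)
  e2 <- evaluate(fit$model, m, fit$stats, ids, 32)
  expect_identical(glance(e1), glance(e2))
  g <- glance(e1)
  for (v in c(g$mAP, g$accuracy, g$precision, g$recall, g$f1)) {
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_equal(sum(e1$confusion), length(ids))
  p <- tempfile(fileext = ".json")
  write_eval_report(e1, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$aggregate$accuracy, g$accuracy)
  expect_equal(Reduce(`+`, lapply(j$confusion_matrix, function(r) sum(unlist(r)))),
               length(ids))
})

test_that("embedding export has one fused vector per sample", {
  fit <- tiny_fit()
  m <- xor_manifest()
  ids <- fit$split$test_ids
  emb <- export_embeddings(fit$model, m, fit$stats, ids, 32)
  expect_equal(nrow(emb), length(ids))
  r <- fit$model$config$reduced_dim
  expect_equal(ncol(emb) - 2, 2 * r)   # n_modalities * reduced_dim
  # identical inputs give identical vectors
  twice <- export_embeddings(fit$model, m, fit$stats, rep(ids[1], 2), 32)
  expect_equal(unlist(twice[1, -1]), unlist(twice[2, -1]), tolerance = 1e-12)
})
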