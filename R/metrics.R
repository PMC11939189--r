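# Evaluation: confusion matrix, precision / recall / accuracy / f1 with
# one-vs-rest averaging, rank-based average precision and mAP.

#' Confusion matrix
#'
#' Entry (a, b) counts samples with true class a predicted as b (0-based
#' class indices map to rows/columns 1..C).
#'
#' @param truth,pred integer vectors of class indices in 0..C-1.
#' @param n_classes number of classes C.
#' @return C x C integer matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  stopifnot(all(truth >= 0), all(truth < n_classes),
            all(pred >= 0), all(pred < n_classes))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  dimnames(cm) <- list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1))
  cm
}

# one-vs-rest TP/FP/FN/TN per class from a confusion matrix
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  tibble::tibble(class = seq_len(nrow(cm)) - 1L, tp = tp, fp = fp,
                 fn = fn, tn = tn, support = rowSums(cm))
}

safe_ratio <- function(num, den) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) warning("undefined ratio (0/0) reported as 0")
  out
}

#' Precision, recall, accuracy and f1 from a confusion matrix
#'
#' Per-class one-vs-rest precision = TP/(TP+FP), recall = TP/(TP+FN), and
#' f1 = harmonic mean, averaged macro (unweighted), weighted (by class
#' support) or micro (pooled counts).  Accuracy is trace/total, the
#' multi-class reading of (TP+TN)/(TP+TN+FP+FN).  Undefined per-class
#' ratios (0/0) count as 0 with a warning.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param averaging `"weighted"` (default), `"macro"` or `"micro"`.
#' @return list with `precision`, `recall`, `accuracy`, `f1`, `averaging`
#'   and the `per_class` tibble.
#' @export
prf_accuracy <- function(cm, averaging = c("weighted", "macro", "micro")) {
  averaging <- match.arg(averaging)
  if (sum(cm) == 0) stop("empty confusion matrix")
  oc <- ovr_counts(cm)
  per <- dplyr::mutate(
    oc,
    precision = safe_ratio(.data$tp, .data$tp + .data$fp),
    recall = safe_ratio(.data$tp, .data$tp + .data$fn),
    f1 = ifelse(.data$precision + .data$recall > 0,
                2 * .data$precision * .data$recall /
                  (.data$precision + .data$recall), 0)
  )
  accuracy <- sum(diag(cm)) / sum(cm)
  if (averaging == "micro") {
    p <- sum(per$tp) / sum(per$tp + per$fp)
    r <- sum(per$tp) / sum(per$tp + per$fn)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  } else {
    wts <- if (averaging == "weighted") per$support / sum(per$support) else
      rep(1 / nrow(per), nrow(per))
    p <- sum(per$precision * wts)
    r <- sum(per$recall * wts)
    f <- sum(per$f1 * wts)
  }
  list(precision = p, recall = r, accuracy = accuracy, f1 = f,
       averaging = averaging, per_class = per)
}

#' Rank-based average precision
#'
#' Ranks by decreasing score (ties broken by stable original order) and
#' averages the precision at each positive's rank over the number of
#' positives — the non-interpolated AP estimator.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 relevance labels.
#' @return AP in \[0, 1\]; `NA` with a warning when there are no positives.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1) == 0) {
    warning("no positive labels; AP undefined (NA)")
    return(NA_real_)
  }
  ord <- order(-scores)         # stable: ties keep original order
  lab <- labels[ord]
  ranks <- seq_along(lab)
  cum_pos <- cumsum(lab)
  prec_at <- cum_pos / ranks
  mean(prec_at[lab == 1])
}

#' Mean average precision over one-vs-rest classes
#'
#' Uses each class's predicted probability as the ranking score for that
#' class's one-vs-rest problem; mAP is the unweighted mean of the
#' per-class APs (classes without positives are excluded with a warning).
#'
#' @param probs N x C matrix of class probabilities (rows sum to 1).
#' @param truth integer class labels in 0..C-1.
#' @return list(mAP, per_class AP vector).
#' @export
mean_average_precision <- function(probs, truth) {
  cc <- ncol(probs)
  aps <- vapply(seq_len(cc), function(k) {
    average_precision(probs[, k], as.integer(truth == (k - 1L)))
  }, numeric(1))
  list(mAP = mean(aps, na.rm = TRUE), ap = aps)
}

#' Evaluate a trained model on a manifest split
#'
#' Deterministically scores every sample of the chosen set with the model
#' in inference mode and assembles the confusion matrix, per-class AP and
#' aggregate metrics.
#'
#' @param model a `switchnet_model` (or a fit / checkpoint via
#'   [predict_manifest()]).
#' @param m a `switchnet_manifest`.
#' @param stats `switchnet_norm_stats` fitted on the training split.
#' @param ids sample ids to evaluate (e.g. `split$test_ids`).
#' @param image_size input side length the model expects.
#' @param averaging averaging mode for the aggregate metrics.
#' @param batch_size evaluation batch size.
#' @return a `switchnet_eval` object.
#' @export
evaluate <- function(model, m, stats, ids, image_size,
                     averaging = "weighted", batch_size = 16L) {
  pr <- predict_manifest(model, m, stats, ids, image_size, batch_size)
  cc <- model$config$n_classes
  cm <- confusion_matrix(pr$truth, pr$pred, cc)
  agg <- prf_accuracy(cm, averaging)
  prob_mat <- as.matrix(pr[, paste0("prob_", seq_len(cc) - 1L)])
  map_res <- mean_average_precision(prob_mat, pr$truth)
  structure(list(confusion = cm, predictions = pr,
                 per_class = dplyr::mutate(agg$per_class, ap = map_res$ap),
                 precision = agg$precision, recall = agg$recall,
                 accuracy = agg$accuracy, f1 = agg$f1, mAP = map_res$mAP,
                 averaging = averaging,
                 class_names = m$class_names),
            class = "switchnet_eval")
}

#' @export
print.switchnet_eval <- function(x, ...) {
  cat("<switchnet_eval>", sum(x$confusion), "samples,",
      nrow(x$confusion), "classes (", x$averaging, "averaging )\n")
  cat(sprintf("  mAP %.3f  accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f\n",
              x$mAP, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.switchnet_eval <- function(x, ...) {
  dplyr::mutate(x$per_class,
                class_name = x$class_names[.data$class + 1L],
                .after = "class")
}

#' @rdname glance
#' @export
glance.switchnet_eval <- function(x, ...) {
  tibble::tibble(mAP = x$mAP, accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, averaging = x$averaging,
                 n = sum(x$confusion))
}

#' Write an evaluation report as JSON
#'
#' @param ev a `switchnet_eval`.
#' @param path output path.
#' @export
write_eval_report <- function(ev, path) {
  out <- list(confusion_matrix = unname(apply(ev$confusion, 1, as.list)),
              per_class = tidy(ev),
              aggregate = as.list(glance(ev)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Export fused feature vectors for downstream projection
#'
#' Writes one row per sample: id, label and the components of the fused
#' feature vector M (per-modality reduced + pooled features concatenated in
#' modality order).  Downstream 2-D projection (e.g. t-SNE) is out of
#' scope and delegated to dedicated tools.
#'
#' @inheritParams evaluate
#' @param path optional CSV output path.
#' @return tibble of embeddings (invisibly written to `path` when given).
#' @export
export_embeddings <- function(model, m, stats, ids, image_size,
                              path = NULL, batch_size = 16L) {
  rows <- list()
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    batch <- build_batch(m, chunk, stats, image_size)
    fw <- interleaved_forward(model, batch$inputs, training = FALSE)
    emb <- t(fw$fused)
    colnames(emb) <- paste0("m", seq_len(ncol(emb)))
    rows[[length(rows) + 1]] <-
      dplyr::bind_cols(tibble::tibble(sample_id = chunk, label = batch$labels),
                       tibble::as_tibble(emb))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
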