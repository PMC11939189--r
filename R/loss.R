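# Weighted cross-entropy loss and class weighting.

#' Inverse-frequency class weights
#'
#' Computes w_k = (N / C) / count_k, i.e. inverse frequency normalised so
#' that sum_k w_k * count_k = N.  Balanced counts give all weights 1.
#'
#' @param class_counts positive integer vector of per-class training counts.
#' @return numeric weight vector, one entry per class.
#' @export
class_weights_from_counts <- function(class_counts) {
  if (any(class_counts <= 0)) {
    stop("every class needs a positive count; supply manual weights for ",
         "classes absent from the training split")
  }
  n <- sum(class_counts)
  c_k <- length(class_counts)
  (n / c_k) / class_counts
}

#' Weighted cross-entropy
#'
#' Per sample with true class y: L = -w_y * log P_y, reduced by mean or sum
#' over the batch.  Uniform weights recover standard cross-entropy.
#' Probabilities are floored at 1e-12 before the log.
#'
#' @param probs C x N matrix of predicted class probabilities (columns are
#'   probability vectors).
#' @param labels integer vector of true class indices in 0..C-1.
#' @param weights per-class weight vector (length C); default all 1.
#' @param reduction `"mean"` or `"sum"`.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights = NULL,
                                   reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  cc <- nrow(probs)
  nb <- ncol(probs)
  stopifnot(length(labels) == nb, all(labels >= 0), all(labels < cc))
  if (is.null(weights)) weights <- rep(1, cc)
  stopifnot(length(weights) == cc, any(weights > 0), all(weights >= 0))
  py <- probs[cbind(labels + 1L, seq_len(nb))]
  if (any(py < 1e-12)) {
    warning("predicted probability below 1e-12 clamped before log")
    py <- pmax(py, 1e-12)
  }
  l <- -weights[labels + 1L] * log(py)
  if (reduction == "mean") mean(l) else sum(l)
}

# loss + gradient wrt logits, computed from log-softmax for stability.
# dL/dlogit_c = w_y * (p_c - [c == y]) (scaled by 1/N under mean reduction)
wce_from_logits <- function(logits, labels, weights = NULL,
                            reduction = "mean") {
  cc <- nrow(logits)
  nb <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, cc)
  z <- logits - rep(apply(logits, 2, max), each = cc)
  lse <- log(colSums(exp(z)))
  logp <- z - rep(lse, each = cc)
  idx <- cbind(labels + 1L, seq_len(nb))
  wy <- weights[labels + 1L]
  l <- -wy * logp[idx]
  loss <- if (reduction == "mean") mean(l) else sum(l)
  probs <- exp(logp)
  onehot <- matrix(0, cc, nb)
  onehot[idx] <- 1
  dlogits <- (probs - onehot) * rep(wy, each = cc)
  if (reduction == "mean") dlogits <- dlogits / nb
  list(loss = loss, dlogits = dlogits, probs = probs)
}
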