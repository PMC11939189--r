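# Deterministic train/validation/test splitting.
#
# Rounding rule: |train| = floor(f_train * N), |test| = floor(f_test * N),
# |val| = N - |train| - |test|.  For the 0.70/0.15/0.15 fractions this
# reproduces the clinical dataset allocations exactly: N = 2005 -> (1403, 302,
# 300) and N = 1011 -> (707, 153, 151).  Stratified assignment (the default
# when labels are given) keeps class proportions while matching those
# global sizes exactly via largest-remainder allocation.

split_sizes <- function(n, fractions) {
  n_train <- floor(fractions[1] * n)
  n_test <- floor(fractions[3] * n)
  c(train = n_train, val = n - n_train - n_test, test = n_test)
}

# largest-remainder integer allocation of `total` across targets
allocate_lr <- function(targets, capacity, total) {
  base <- pmin(floor(targets), capacity)
  left <- total - sum(base)
  if (left > 0) {
    pref <- order(targets - floor(targets), decreasing = TRUE)
    for (k in pref) {
      if (left == 0) break
      if (base[k] < capacity[k]) {
        base[k] <- base[k] + 1
        left <- left - 1
      }
    }
    # still short (remainder ties with full classes): fill anywhere possible
    k <- 1
    while (left > 0 && k <= length(base)) {
      room <- capacity[k] - base[k]
      take <- min(room, left)
      base[k] <- base[k] + take
      left <- left - take
      k <- k + 1
    }
  }
  base
}

#' Split sample ids into train/validation/test sets
#'
#' Membership is a seeded uniform permutation; with `labels` supplied and
#' `stratify = TRUE` the permutation is per class and per-class counts are
#' chosen by largest remainder so that the global sizes still follow the
#' floor/floor/remainder rule exactly.
#'
#' @param ids character or integer vector of unique sample ids.
#' @param fractions length-3 numeric (train, val, test) summing to 1.
#' @param seed integer seed; the same seed always yields the same split.
#' @param labels optional per-id class labels enabling stratification.
#' @param stratify stratify by class when labels are available.
#' @return a `switchnet_split`: list(train_ids, val_ids, test_ids,
#'   fractions, seed).
#' @export
split_dataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                          labels = NULL, stratify = !is.null(labels)) {
  if (length(ids) == 0) stop("ids must be non-empty")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3) {
    stop("fractions must be three values summing to 1")
  }
  n <- length(ids)
  sz <- split_sizes(n, fractions)
  set.seed(seed)
  if (stratify && !is.null(labels)) {
    stopifnot(length(labels) == n)
    classes <- sort(unique(labels))
    nc <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
    tr_alloc <- allocate_lr(fractions[1] * nc, nc, sz["train"])
    te_alloc <- allocate_lr(fractions[3] * nc, nc - tr_alloc, sz["test"])
    train_ids <- c(); val_ids <- c(); test_ids <- c()
    for (k in seq_along(classes)) {
      cl_ids <- sample(ids[labels == classes[k]])
      t1 <- tr_alloc[k]; t2 <- te_alloc[k]
      train_ids <- c(train_ids, cl_ids[seq_len(t1)])
      if (t2 > 0) test_ids <- c(test_ids, cl_ids[t1 + seq_len(t2)])
      rest <- length(cl_ids) - t1 - t2
      if (rest > 0) val_ids <- c(val_ids, cl_ids[t1 + t2 + seq_len(rest)])
    }
  } else {
    perm <- sample(ids)
    train_ids <- perm[seq_len(sz["train"])]
    val_ids <- perm[sz["train"] + seq_len(sz["val"])]
    test_ids <- perm[sz["train"] + sz["val"] + seq_len(sz["test"])]
  }
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, fractions = fractions, seed = seed),
            class = "switchnet_split")
}

#' @export
print.switchnet_split <- function(x, ...) {
  cat("<switchnet_split> train:", length(x$train_ids),
      " val:", length(x$val_ids), " test:", length(x$test_ids), "\n")
  invisible(x)
}

#' Tabular view of a split
#' @param x a `switchnet_split`.
#' @param ... unused.
#' @return tibble with columns sample_id, set.
#' @export
tidy.switchnet_split <- function(x, ...) {
  tibble::tibble(
    sample_id = c(x$train_ids, x$val_ids, x$test_ids),
    set = rep(c("train", "val", "test"),
              c(length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  )
}
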