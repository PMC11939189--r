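# Information-Switching Module (ISM).
#
# At every backbone stage the n per-modality feature vectors at each spatial
# location form a length-n token sequence.  Multi-head self-attention over
# that sequence exchanges information between modalities; the switched
# features are blended back with the originals through a learnable per-stage
# weight alpha in [0, 1]:
#
#   Z_i = alpha * X_i + (1 - alpha) * sum_{j != i} Y_j      (mix_mode "sum_others")
#
# with "self" (Y_i instead of the sum) and "mean_others" (sum / (n - 1))
# variants.  Projections are token-shared and there is no positional or
# modality embedding, so the module is equivariant to modality permutation.
#
# Token tensors are stored as (d_or_c, n, T) arrays where T = h*w*batch is
# the number of sequences; attention is vectorised over T with n x n loops
# (n is 2 or 5 in practice).

#' ISM configuration
#'
#' @param heads number of attention heads (per-stage head count is reduced
#'   automatically when a stage has few channels).
#' @param head_dim per-head dimension; `NULL` means `ceiling(channels /
#'   heads)` capped at `head_dim_cap`.
#' @param head_dim_cap cap on the per-head dimension (keeps the 1280-channel
#'   stage affordable).
#' @param mix_mode `"sum_others"` (printed formula), `"self"`, or
#'   `"mean_others"`.
#' @param alpha_init initial blending weight in (0, 1); stored internally on
#'   the logit scale so it stays in \[0, 1\] while remaining learnable.
#' @param qk_gain multiplier on the query/key initialisation scale.  At 1 the
#'   dot-product scores start near zero, the softmax is almost uniform and
#'   the exchange behaves linearly; a larger gain activates the attention
#'   gating from the start, which matters for learning label rules that only
#'   exist in the interaction between modalities.
#' @param placement `"interleaved"` (exchange at all 8 stages, feeding the
#'   next stage), `"head_only"` (exchange stage-8 features only), or
#'   `"off"` (no exchange; the ablation baseline).
#' @return an `ism_config` list.
#' @export
ism_config <- function(heads = 4L, head_dim = NULL, head_dim_cap = 64L,
                       mix_mode = c("sum_others", "self", "mean_others"),
                       alpha_init = 0.5,
                       placement = c("interleaved", "head_only", "off"),
                       qk_gain = 4) {
  mix_mode <- match.arg(mix_mode)
  placement <- match.arg(placement)
  stopifnot(alpha_init > 0, alpha_init < 1, heads >= 1, qk_gain > 0)
  structure(list(heads = as.integer(heads), head_dim = head_dim,
                 head_dim_cap = as.integer(head_dim_cap), mix_mode = mix_mode,
                 alpha_init = alpha_init, placement = placement,
                 qk_gain = qk_gain),
            class = "ism_config")
}

# per-stage head layout: fewer heads for narrow stages, m*d bounded
ism_stage_dims <- function(channels, cfg) {
  m <- cfg$heads
  if (channels < 8) m <- 1L else if (channels < 32) m <- min(m, 2L)
  d <- cfg$head_dim
  if (is.null(d)) d <- min(as.integer(ceiling(channels / m)), cfg$head_dim_cap)
  list(m = as.integer(m), d = as.integer(d))
}

init_ism_params <- function(params, config, cfg) {
  logit <- function(p) log(p / (1 - p))
  gain <- cfg$qk_gain %||% 1
  for (s in seq_along(config$stages)) {
    cs <- config$stages[[s]]$channels
    hd <- ism_stage_dims(cs, cfg)
    prefix <- sprintf("ism.s%d", s)
    for (j in seq_len(hd$m)) {
      params[[sprintf("%s.Wq.%d", prefix, j)]] <- gain * he_init(c(hd$d, cs), cs)
      params[[sprintf("%s.bq.%d", prefix, j)]] <- rep(0, hd$d)
      params[[sprintf("%s.Wk.%d", prefix, j)]] <- gain * he_init(c(hd$d, cs), cs)
      params[[sprintf("%s.bk.%d", prefix, j)]] <- rep(0, hd$d)
      params[[sprintf("%s.Wv.%d", prefix, j)]] <- he_init(c(hd$d, cs), cs)
      params[[sprintf("%s.bv.%d", prefix, j)]] <- rep(0, hd$d)
    }
    params[[paste0(prefix, ".Wo")]] <- he_init(c(cs, hd$m * hd$d), hd$m * hd$d)
    params[[paste0(prefix, ".bo")]] <- rep(0, cs)
    params[[paste0(prefix, ".alpha_raw")]] <- logit(cfg$alpha_init)
  }
  params
}

#' Stack per-modality maps into per-location token sequences
#'
#' Token t of sequence p is the channel vector of modality t at spatial
#' position p; the inverse operation restores the maps exactly.
#'
#' @param xs list of n arrays, all (H, W, C, N).
#' @return array (C, n, T) with T = H*W*N, plus the dims needed to invert.
#' @export
stack_and_sequence <- function(xs) {
  d <- dim(xs[[1]])
  for (x in xs) {
    if (!identical(dim(x), d)) stop("all modality maps must share one shape")
  }
  n <- length(xs)
  tt <- d[1] * d[2] * d[4]
  seqs <- array(0, dim = c(d[3], n, tt))
  for (i in seq_len(n)) {
    # (H, W, C, N) -> (C, H*W*N) with hw fastest, then batch
    seqs[, i, ] <- t(hwn_by_c(xs[[i]]))
  }
  attr(seqs, "map_dim") <- d
  seqs
}

#' Restore per-modality maps from a token tensor
#'
#' @param seqs array (C, n, T) as produced by [stack_and_sequence()].
#' @param map_dim the original (H, W, C, N) dims (defaults to the attribute
#'   recorded by [stack_and_sequence()]).
#' @return list of n arrays (H, W, C, N).
#' @export
sequence_to_maps <- function(seqs, map_dim = attr(seqs, "map_dim")) {
  n <- dim(seqs)[2]
  lapply(seq_len(n), function(i) {
    c_to_hwn(t(seqs[, i, , drop = TRUE]), map_dim[1], map_dim[2],
             map_dim[3], map_dim[4])
  })
}

#' Scaled dot-product attention over modality tokens
#'
#' H = softmax(Q K^T / sqrt(d)) V per sequence, no masking.
#'
#' @param q,k,v arrays (d, n, T): per-head query/key/value tokens.
#' @param d head dimension used for the 1/sqrt(d) scaling.
#' @return list(out = (d, n, T) array, attn = (n, n, T) attention weights).
#' @export
attention <- function(q, k, v, d) {
  if (d <= 0) stop("head dimension d must be positive")
  n <- dim(q)[2]; tt <- dim(q)[3]
  dd <- dim(q)[1]
  scores <- array(0, dim = c(n, n, tt))
  for (a in seq_len(n)) {
    qa <- q[, a, ]
    dim(qa) <- c(dd, tt)
    for (b in seq_len(n)) {
      kb <- k[, b, ]
      dim(kb) <- c(dd, tt)
      scores[a, b, ] <- colSums(qa * kb)
    }
  }
  scores <- scores / sqrt(d)
  # softmax over b (dim 2), stabilised; mx/tot are (n, T) slices
  mx <- scores[, 1, ]
  if (n > 1) for (b in 2:n) mx <- pmax(mx, scores[, b, ])
  attn <- scores
  tot <- 0
  for (b in seq_len(n)) {
    attn[, b, ] <- exp(scores[, b, ] - mx)
    tot <- tot + attn[, b, ]
  }
  for (b in seq_len(n)) attn[, b, ] <- attn[, b, ] / tot
  out <- array(0, dim = dim(v))
  for (a in seq_len(n)) {
    acc <- matrix(0, dd, tt)
    for (b in seq_len(n)) {
      vb <- v[, b, ]
      dim(vb) <- c(dd, tt)
      acc <- acc + vb * rep(attn[a, b, ], each = dd)
    }
    out[, a, ] <- acc
  }
  list(out = out, attn = attn)
}

attention_bwd <- function(q, k, v, d, attn, dout) {
  n <- dim(q)[2]; dd <- dim(q)[1]; tt <- dim(q)[3]
  dv <- array(0, dim = dim(v))
  dattn <- array(0, dim = dim(attn))
  for (a in seq_len(n)) {
    da <- matrix(dout[, a, ], nrow = dd)
    for (b in seq_len(n)) {
      dv[, b, ] <- dv[, b, ] + da * rep(attn[a, b, ], each = dd)
      dattn[a, b, ] <- colSums(da * matrix(v[, b, ], nrow = dd))
    }
  }
  # softmax backward over b per (a, t): dS = A * (dA - sum_b A dA)
  dot <- 0
  for (b in seq_len(n)) dot <- dot + dattn[, b, ] * attn[, b, ]
  dscores <- array(0, dim = dim(attn))
  for (b in seq_len(n)) {
    dscores[, b, ] <- attn[, b, ] * (dattn[, b, ] - dot)
  }
  dscores <- dscores / sqrt(d)
  dq <- array(0, dim = dim(q))
  dk <- array(0, dim = dim(k))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      sab <- rep(dscores[a, b, ], each = dd)
      dq[, a, ] <- dq[, a, ] + matrix(k[, b, ], nrow = dd) * sab
      dk[, b, ] <- dk[, b, ] + matrix(q[, a, ], nrow = dd) * sab
    }
  }
  list(dq = dq, dk = dk, dv = dv)
}

#' Multi-head information switch over one token tensor
#'
#' Per head: project tokens to Q/K/V, attend across the n modalities,
#' concatenate the head outputs and project back to the channel dimension.
#' Output shape equals input shape.
#'
#' @param seqs array (C, n, T) of modality token sequences.
#' @param params flat parameter list holding the stage's projections.
#' @param stage stage index (selects the `ism.s<stage>.*` parameters).
#' @param m,d head count and head dimension for this stage.
#' @return list(out, cache).
#' @export
multi_head_switch <- function(seqs, params, stage, m, d) {
  cs <- dim(seqs)[1]; n <- dim(seqs)[2]; tt <- dim(seqs)[3]
  prefix <- sprintf("ism.s%d", stage)
  xmat <- matrix(seqs, nrow = cs)               # C x (n*T)
  heads <- vector("list", m)
  hcat <- matrix(0, m * d, n * tt)
  for (j in seq_len(m)) {
    qm <- params[[sprintf("%s.Wq.%d", prefix, j)]] %*% xmat +
      params[[sprintf("%s.bq.%d", prefix, j)]]
    km <- params[[sprintf("%s.Wk.%d", prefix, j)]] %*% xmat +
      params[[sprintf("%s.bk.%d", prefix, j)]]
    vm <- params[[sprintf("%s.Wv.%d", prefix, j)]] %*% xmat +
      params[[sprintf("%s.bv.%d", prefix, j)]]
    q <- array(qm, dim = c(d, n, tt))
    k <- array(km, dim = c(d, n, tt))
    v <- array(vm, dim = c(d, n, tt))
    at <- attention(q, k, v, d)
    heads[[j]] <- list(q = q, k = k, v = v, attn = at$attn)
    hcat[((j - 1) * d + 1):(j * d), ] <- matrix(at$out, nrow = d)
  }
  ymat <- params[[paste0(prefix, ".Wo")]] %*% hcat + params[[paste0(prefix, ".bo")]]
  out <- array(ymat, dim = dim(seqs))
  attr(out, "map_dim") <- attr(seqs, "map_dim")
  list(out = out,
       cache = list(xmat = xmat, hcat = hcat, heads = heads, stage = stage,
                    m = m, d = d, n = n, tt = tt, cs = cs,
                    map_dim = attr(seqs, "map_dim")))
}

multi_head_switch_bwd <- function(gacc, params, cache, dout) {
  prefix <- sprintf("ism.s%d", cache$stage)
  m <- cache$m; d <- cache$d; n <- cache$n; tt <- cache$tt; cs <- cache$cs
  dymat <- matrix(dout, nrow = cs)
  g_add(gacc, paste0(prefix, ".Wo"), tcrossprod(dymat, cache$hcat))
  g_add(gacc, paste0(prefix, ".bo"), rowSums(dymat))
  dhcat <- crossprod(params[[paste0(prefix, ".Wo")]], dymat)
  dxmat <- matrix(0, cs, n * tt)
  for (j in seq_len(m)) {
    hd <- cache$heads[[j]]
    dh <- array(dhcat[((j - 1) * d + 1):(j * d), ], dim = c(d, n, tt))
    ab <- attention_bwd(hd$q, hd$k, hd$v, d, hd$attn, dh)
    for (nmv in c("q", "k", "v")) {
      dproj <- matrix(ab[[paste0("d", nmv)]], nrow = d)
      wname <- sprintf("%s.W%s.%d", prefix, nmv, j)
      bname <- sprintf("%s.b%s.%d", prefix, nmv, j)
      g_add(gacc, wname, tcrossprod(dproj, cache$xmat))
      g_add(gacc, bname, rowSums(dproj))
      dxmat <- dxmat + crossprod(params[[wname]], dproj)
    }
  }
  dseqs <- array(dxmat, dim = c(cs, n, tt))
  attr(dseqs, "map_dim") <- cache$map_dim
  dseqs
}

#' Blend original and switched modality features
#'
#' Implements Z_i = alpha X_i + (1 - alpha) S_i where S_i is, depending on
#' `mix_mode`, the sum of the other modalities' switched features
#' (`"sum_others"`, the printed formula), the modality's own switched
#' features (`"self"`), or the mean over others (`"mean_others"`).  With a
#' single modality the empty "others" sum is the zero map.
#'
#' @param xs,ys lists of n matching arrays: original and switched features.
#' @param alpha blending weight in \[0, 1\].
#' @param mix_mode one of `"sum_others"`, `"self"`, `"mean_others"`.
#' @return list of n blended arrays.
#' @export
mix_features <- function(xs, ys, alpha, mix_mode = "sum_others") {
  n <- length(xs)
  stopifnot(length(ys) == n)
  switched <- switch_component(ys, mix_mode)
  lapply(seq_len(n), function(i) alpha * xs[[i]] + (1 - alpha) * switched[[i]])
}

switch_component <- function(ys, mix_mode) {
  n <- length(ys)
  if (mix_mode == "self") return(ys)
  tot <- Reduce(`+`, ys)
  denom <- if (mix_mode == "mean_others") max(n - 1, 1) else 1
  lapply(seq_len(n), function(i) {
    s <- tot - ys[[i]]
    if (n == 1) s <- array(0, dim = dim(ys[[i]]))  # empty sum
    s / denom
  })
}

# full ISM pass at one stage: tokens -> attention -> maps -> blend
ism_stage_fwd <- function(params, config, cfg, stage, xs) {
  hd <- ism_stage_dims(config$stages[[stage]]$channels, cfg)
  seqs <- stack_and_sequence(xs)
  sw <- multi_head_switch(seqs, params, stage, hd$m, hd$d)
  ys <- sequence_to_maps(sw$out)
  araw <- params[[sprintf("ism.s%d.alpha_raw", stage)]]
  alpha <- sigmoid(araw)
  zs <- mix_features(xs, ys, alpha, cfg$mix_mode)
  list(out = zs,
       cache = list(sw = sw$cache, xs = xs, ys = ys, alpha = alpha,
                    araw = araw, stage = stage, mix_mode = cfg$mix_mode,
                    map_dim = dim(xs[[1]])))
}

ism_stage_bwd <- function(gacc, params, cache, dzs) {
  n <- length(dzs)
  alpha <- cache$alpha
  mode <- cache$mix_mode
  switched <- switch_component(cache$ys, mode)
  # d alpha: sum_i <dZ_i, X_i - S_i>
  dalpha <- 0
  for (i in seq_len(n)) {
    dalpha <- dalpha + sum(dzs[[i]] * (cache$xs[[i]] - switched[[i]]))
  }
  g_add(gacc, sprintf("ism.s%d.alpha_raw", cache$stage),
        dalpha * alpha * (1 - alpha))
  dxs <- lapply(dzs, function(dz) alpha * dz)
  # gradient wrt ys through the switch component
  dys <- if (mode == "self") {
    lapply(dzs, function(dz) (1 - alpha) * dz)
  } else {
    denom <- if (mode == "mean_others") max(n - 1, 1) else 1
    tot <- Reduce(`+`, dzs)
    lapply(seq_len(n), function(j) {
      s <- tot - dzs[[j]]
      if (n == 1) s <- array(0, dim = dim(dzs[[j]]))
      (1 - alpha) * s / denom
    })
  }
  dseq <- stack_and_sequence(dys)
  dseq_in <- multi_head_switch_bwd(gacc, params, cache$sw, dseq)
  dx_att <- sequence_to_maps(dseq_in, cache$map_dim)
  lapply(seq_len(n), function(i) dxs[[i]] + dx_att[[i]])
}
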