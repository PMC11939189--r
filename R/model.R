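# Full model: shared backbone + per-stage ISM + aggregation head.
#
# Head: per modality a shared 1x1 reduction conv, global average pooling,
# concatenation in modality order, then a single linear map and softmax.

#' Build a full multi-modal classifier
#'
#' @param backbone a [backbone_config()].
#' @param ism an [ism_config()].
#' @param n_modalities number of co-registered modalities n.
#' @param n_classes number of classes C.
#' @param reduced_dim output channels r of the head's 1x1 reduction conv
#'   (`NULL`: 256 for the full preset, 16 for tiny).
#' @param seed seed for parameter initialisation.
#' @param pretrained_file optional RDS parameter file for the backbone hook.
#' @return a `switchnet_model` list: `params`, `state`, and `config`.
#' @export
build_model <- function(backbone = backbone_config("tiny"),
                        ism = ism_config(),
                        n_modalities = 2L, n_classes = 2L,
                        reduced_dim = NULL, seed = 1L,
                        pretrained_file = NULL) {
  if (is.null(reduced_dim)) {
    reduced_dim <- if (backbone$preset == "full") 256L else 16L
  }
  bb <- build_backbone(backbone, seed = seed, pretrained_file = pretrained_file)
  params <- bb$params
  c8 <- backbone$stages[[8]]$channels
  # head before ISM so matched ablation variants share backbone + head init
  params[["head.conv.W"]] <- he_init(c(1, 1, c8, reduced_dim), c8)
  params[["head.conv.b"]] <- rep(0, reduced_dim)
  params[["head.fc.W"]] <- he_init(c(n_classes, n_modalities * reduced_dim),
                                   n_modalities * reduced_dim)
  params[["head.fc.b"]] <- rep(0, n_classes)
  if (ism$placement != "off") params <- init_ism_params(params, backbone, ism)
  structure(list(params = params, state = bb$state,
                 config = list(backbone = backbone, ism = ism,
                               n_modalities = as.integer(n_modalities),
                               n_classes = as.integer(n_classes),
                               reduced_dim = as.integer(reduced_dim))),
            class = "switchnet_model")
}

#' @export
print.switchnet_model <- function(x, ...) {
  cat("<switchnet_model>\n")
  cat("  backbone preset:", x$config$backbone$preset, "\n")
  cat("  modalities:", x$config$n_modalities,
      " classes:", x$config$n_classes, "\n")
  cat("  ISM placement:", x$config$ism$placement,
      " mix mode:", x$config$ism$mix_mode, "\n")
  cat("  parameters:", format(count_parameters(x$params), big.mark = ","), "\n")
  invisible(x)
}

#' Current per-stage blending weights
#'
#' @param model a `switchnet_model`.
#' @return numeric vector of the 8 per-stage alpha values (squashed to
#'   \[0, 1\]), or `NULL` when the ISM is off.
#' @export
ism_alphas <- function(model) {
  if (model$config$ism$placement == "off") return(NULL)
  sapply(seq_along(model$config$backbone$stages), function(s) {
    sigmoid(model$params[[sprintf("ism.s%d.alpha_raw", s)]])
  })
}

#' Interleaved forward pass
#'
#' Runs all 8 backbone stages on every modality with the shared weights,
#' applying the ISM after each stage (placement `"interleaved"`), only after
#' stage 8 (`"head_only"`), or never (`"off"`).  With all blending weights
#' at 1 the result equals n independent backbone passes.
#'
#' @param model a `switchnet_model`.
#' @param inputs list of n normalized arrays (H, W, 3, N).
#' @param training logical; use batch statistics and update running stats.
#' @param keep_cache retain layer caches for a backward pass.
#' @return list with `z8` (per-modality final features), `logits`, `probs`
#'   (C x N), and `fused` (the concatenated feature vector M, n*r x N);
#'   caches when requested.
#' @export
interleaved_forward <- function(model, inputs, training = FALSE,
                                keep_cache = FALSE) {
  cfg <- model$config
  n <- cfg$n_modalities
  if (length(inputs) != n) {
    stop(sprintf("model expects %d modalities, got %d", n, length(inputs)))
  }
  senv <- new.env(parent = emptyenv())
  senv$s <- model$state
  params <- model$params
  placement <- cfg$ism$placement
  # the backbone is fully shared, so all modalities travel through each
  # stage as one combined batch (modality-major along the batch axis);
  # batch-norm statistics therefore pool over modalities as well
  comb <- combine_modalities(inputs)
  nb <- dim(inputs[[1]])[4]
  stage_caches <- list()
  ism_caches <- list()
  n_stage <- length(cfg$backbone$stages)
  for (s in seq_len(n_stage)) {
    r <- forward_stage(params, senv, cfg$backbone, s, comb, training)
    do_ism <- (placement == "interleaved") ||
      (placement == "head_only" && s == n_stage)
    if (do_ism) {
      ir <- ism_stage_fwd(params, cfg$backbone, cfg$ism, s,
                          split_modalities(r$out, n, nb))
      comb <- combine_modalities(ir$out)
      if (keep_cache) ism_caches[[s]] <- ir$cache
    } else {
      comb <- r$out
    }
    if (keep_cache) stage_caches[[s]] <- r$caches
  }
  zs <- split_modalities(comb, n, nb)
  hd <- head_fwd(params, zs, cfg)
  out <- list(z8 = zs, logits = hd$logits, probs = hd$probs, fused = hd$fused,
              state = senv$s)
  if (keep_cache) {
    out$cache <- list(stage = stage_caches, ism = ism_caches, head = hd$cache,
                      n_stage = n_stage, placement = placement, n = n,
                      nb = nb)
  }
  out
}

combine_modalities <- function(xs) {
  n <- length(xs)
  if (n == 1) return(xs[[1]])
  d <- dim(xs[[1]])
  out <- array(0, dim = c(d[1], d[2], d[3], d[4] * n))
  for (i in seq_len(n)) out[, , , (i - 1) * d[4] + seq_len(d[4])] <- xs[[i]]
  out
}

split_modalities <- function(x, n, nb) {
  if (n == 1) return(list(x))
  lapply(seq_len(n), function(i) {
    x[, , , (i - 1) * nb + seq_len(nb), drop = FALSE]
  })
}

head_fwd <- function(params, zs, cfg) {
  n <- length(zs)
  pooled <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- conv2d_fwd(zs[[i]], params[["head.conv.W"]], params[["head.conv.b"]],
                     stride = 1L, pad = 0L)
    gp <- gap_fwd(cv$out)
    pooled[[i]] <- gp$out                      # r x N
    caches[[i]] <- list(conv = cv$cache, gap = gp$cache)
  }
  fused <- do.call(rbind, pooled)              # (n*r) x N
  fc <- linear_fwd(fused, params[["head.fc.W"]], params[["head.fc.b"]])
  probs <- softmax_cols(fc$out)
  list(logits = fc$out, probs = probs, fused = fused,
       cache = list(mods = caches, fc = fc$cache, r = nrow(pooled[[1]])))
}

head_bwd <- function(gacc, cache, dlogits) {
  fb <- linear_bwd(cache$fc, dlogits)
  g_add(gacc, "head.fc.W", fb$dw)
  g_add(gacc, "head.fc.b", fb$db)
  r <- cache$r
  n <- length(cache$mods)
  dzs <- vector("list", n)
  for (i in seq_len(n)) {
    dpool <- fb$dx[((i - 1) * r + 1):(i * r), , drop = FALSE]
    dcv <- gap_bwd(cache$mods[[i]]$gap, dpool)
    cb <- conv2d_bwd(cache$mods[[i]]$conv, dcv)
    g_add(gacc, "head.conv.W", cb$dw)
    g_add(gacc, "head.conv.b", cb$db)
    dzs[[i]] <- cb$dx
  }
  dzs
}

#' Backward pass through the whole model
#'
#' Propagates a gradient on the logits back through head, ISM stages and
#' shared backbone, accumulating parameter gradients (backbone gradients sum
#' over modalities).  Optionally records the gradient with respect to the
#' post-ISM features of a chosen stage, which is what Grad-CAM consumes.
#'
#' @param model a `switchnet_model`.
#' @param fwd result of [interleaved_forward()] with `keep_cache = TRUE`.
#' @param dlogits gradient on the logits (C x N).
#' @param record_stage optional stage index whose post-ISM feature gradient
#'   should be returned.
#' @return list(grads = named list, recorded = list of per-modality dZ at
#'   `record_stage` or NULL).
#' @export
model_backward <- function(model, fwd, dlogits, record_stage = NULL) {
  cache <- fwd$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache = TRUE")
  gacc <- new.env(parent = emptyenv())
  gacc$g <- list()
  n <- cache$n
  nb <- cache$nb
  dzs <- head_bwd(gacc, cache$head, dlogits)
  recorded <- NULL
  if (!is.null(record_stage) && record_stage == cache$n_stage) recorded <- dzs
  dcomb <- NULL
  for (s in rev(seq_len(cache$n_stage))) {
    if (length(cache$ism) >= s && !is.null(cache$ism[[s]])) {
      if (is.null(dzs)) dzs <- split_modalities(dcomb, n, nb)
      dxs <- ism_stage_bwd(gacc, model$params, cache$ism[[s]], dzs)
      dcomb <- combine_modalities(dxs)
    } else if (!is.null(dzs)) {
      dcomb <- combine_modalities(dzs)
    }
    dzs <- NULL
    dcomb <- backward_stage(gacc, cache$stage[[s]], dcomb)
    if (!is.null(record_stage) && record_stage == s - 1) {
      recorded <- split_modalities(dcomb, n, nb)
    }
  }
  list(grads = gacc$g, dinput = split_modalities(dcomb, n, nb),
       recorded = recorded)
}
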