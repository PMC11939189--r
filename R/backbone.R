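# Multi-scale fully-shared convolutional backbone.
#
# Eight stages of conv / Fused-MBConv / MBConv blocks produce feature maps at
# eight scales.  One parameter set is shared by every modality.  The "full"
# preset is the EfficientNetV2-B0-style table used for the full-size model;
# the "tiny" preset shrinks widths and depths so the whole pipeline trains in
# seconds on one CPU while exercising exactly the same code paths.

#' Backbone stage table
#'
#' Returns the 8-stage configuration of the shared feature extractor.
#'
#' @param preset `"full"` for the full-size stage table (stem conv stride 2,
#'   Fused-MBConv and MBConv stages, 1x1 conv head stage; output channels
#'   32, 16, 32, 48, 96, 112, 192, 1280) or `"tiny"` for a width-0.25,
#'   depth-1 profile suitable for CPU tests.
#' @param width_mult channel width multiplier; channels are rounded to
#'   multiples of 8 (minimum 8). Ignored for `preset = "full"`.
#' @param max_layers per-stage layer count cap (`1` for the tiny preset).
#' @param se_ratio squeeze-and-excitation reduction ratio relative to the
#'   block's input channels.
#' @return A `backbone_config` object: list of 8 stage records plus metadata.
#' @export
backbone_config <- function(preset = c("full", "tiny"), width_mult = NULL,
                            max_layers = NULL, se_ratio = 0.25) {
  preset <- match.arg(preset)
  base <- list(
    list(op = "conv",   kernel = 3L, stride = 2L, expand = 1L, channels = 32L,   layers = 1L),
    list(op = "fused",  kernel = 3L, stride = 1L, expand = 1L, channels = 16L,   layers = 1L),
    list(op = "fused",  kernel = 3L, stride = 2L, expand = 4L, channels = 32L,   layers = 2L),
    list(op = "fused",  kernel = 3L, stride = 2L, expand = 4L, channels = 48L,   layers = 2L),
    list(op = "mbconv", kernel = 3L, stride = 2L, expand = 4L, channels = 96L,   layers = 3L),
    list(op = "mbconv", kernel = 3L, stride = 1L, expand = 6L, channels = 112L,  layers = 5L),
    list(op = "mbconv", kernel = 3L, stride = 2L, expand = 6L, channels = 192L,  layers = 8L),
    list(op = "conv",   kernel = 1L, stride = 1L, expand = 1L, channels = 1280L, layers = 1L)
  )
  if (preset == "tiny") {
    if (is.null(width_mult)) width_mult <- 0.25
    if (is.null(max_layers)) max_layers <- 1L
  } else {
    width_mult <- 1
    max_layers <- .Machine$integer.max
  }
  round8 <- function(x) max(8L, as.integer(round(x / 8) * 8))
  stages <- lapply(base, function(st) {
    if (width_mult != 1) st$channels <- round8(st$channels * width_mult)
    st$layers <- min(st$layers, max_layers)
    st
  })
  structure(list(stages = stages, preset = preset, se_ratio = se_ratio,
                 width_mult = width_mult),
            class = "backbone_config")
}

#' @export
print.backbone_config <- function(x, ...) {
  cat("<backbone_config> preset:", x$preset, "\n")
  df <- stage_table(x)
  print(as.data.frame(df))
  invisible(x)
}

#' Stage summary of a backbone configuration
#'
#' @param config a [backbone_config()].
#' @return A tibble with one row per stage: operation, kernel, stride,
#'   expand ratio, output channels and layer count.
#' @export
stage_table <- function(config) {
  tibble::tibble(
    stage = seq_along(config$stages),
    operation = purrr::map_chr(config$stages, "op"),
    kernel = purrr::map_int(config$stages, "kernel"),
    stride = purrr::map_int(config$stages, "stride"),
    expand_ratio = purrr::map_int(config$stages, "expand"),
    channels = purrr::map_int(config$stages, "channels"),
    layers = purrr::map_int(config$stages, "layers")
  )
}

#' Expected spatial size after each stage
#'
#' Cumulative-stride contract: stage s halves resolution once per stride-2
#' stage, so size_s = input_size / prod(strides through s).
#'
#' @param config a [backbone_config()].
#' @param input_size input image side length (must be divisible by the total
#'   stride product, 32 for the shipped presets).
#' @return integer vector of 8 per-stage spatial sizes.
#' @export
stage_spatial_sizes <- function(config, input_size) {
  strides <- cumprod(purrr::map_int(config$stages, "stride"))
  as.integer(input_size / strides)
}

se_hidden <- function(cin, se_ratio) max(1L, as.integer(round(cin * se_ratio)))

# per-block parameter construction ------------------------------------------

init_bn <- function(params, state, prefix, ch) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, ch)
  params[[paste0(prefix, ".beta")]] <- rep(0, ch)
  state[[paste0(prefix, ".rmean")]] <- rep(0, ch)
  state[[paste0(prefix, ".rvar")]] <- rep(1, ch)
  list(params = params, state = state)
}

init_block <- function(params, state, prefix, op, k, cin, cout, expand, se_ratio) {
  add_bn <- function(p, s, nm, ch) init_bn(p, s, paste0(prefix, ".", nm), ch)
  if (op == "conv" || (op == "fused" && expand == 1)) {
    params[[paste0(prefix, ".conv.W")]] <- he_init(c(k, k, cin, cout), k * k * cin)
    r <- add_bn(params, state, "bn1", cout); params <- r$params; state <- r$state
  } else if (op == "fused") {
    cexp <- cin * expand
    params[[paste0(prefix, ".conv.W")]] <- he_init(c(k, k, cin, cexp), k * k * cin)
    r <- add_bn(params, state, "bn1", cexp); params <- r$params; state <- r$state
    params[[paste0(prefix, ".proj.W")]] <- he_init(c(1, 1, cexp, cout), cexp)
    r <- add_bn(params, state, "bn2", cout); params <- r$params; state <- r$state
  } else { # mbconv
    cexp <- cin * expand
    bn_i <- 1
    if (expand > 1) {
      params[[paste0(prefix, ".expand.W")]] <- he_init(c(1, 1, cin, cexp), cin)
      r <- add_bn(params, state, paste0("bn", bn_i), cexp)
      params <- r$params; state <- r$state
      bn_i <- bn_i + 1
    }
    params[[paste0(prefix, ".dw.W")]] <- he_init(c(k, k, cexp), k * k)
    r <- add_bn(params, state, paste0("bn", bn_i), cexp)
    params <- r$params; state <- r$state
    bn_i <- bn_i + 1
    hid <- se_hidden(cin, se_ratio)
    params[[paste0(prefix, ".se.W1")]] <- he_init(c(hid, cexp), cexp)
    params[[paste0(prefix, ".se.b1")]] <- rep(0, hid)
    params[[paste0(prefix, ".se.W2")]] <- he_init(c(cexp, hid), hid)
    params[[paste0(prefix, ".se.b2")]] <- rep(0, cexp)
    params[[paste0(prefix, ".proj.W")]] <- he_init(c(1, 1, cexp, cout), cexp)
    r <- add_bn(params, state, paste0("bn", bn_i), cout)
    params <- r$params; state <- r$state
  }
  list(params = params, state = state)
}

#' Build backbone parameters
#'
#' Creates one randomly initialised (seeded) parameter set shared by all
#' modalities.  Pretrained initialisation loads a parameter list from an RDS
#' file previously produced by this package (an optional hook; nothing is
#' downloaded).
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for the random initialisation.
#' @param pretrained_file optional path to an RDS file holding a named
#'   parameter list to start from.
#' @return list with `params` (named flat list) and `state` (batch-norm
#'   running statistics).
#' @export
build_backbone <- function(config, seed = 1L, pretrained_file = NULL) {
  set.seed(seed)
  params <- list(); state <- list()
  cin <- 3L
  for (s in seq_along(config$stages)) {
    st <- config$stages[[s]]
    for (b in seq_len(st$layers)) {
      prefix <- sprintf("st%d.b%d", s, b)
      bc_in <- if (b == 1) cin else st$channels
      r <- init_block(params, state, prefix, st$op, st$kernel, bc_in,
                      st$channels, st$expand, config$se_ratio)
      params <- r$params; state <- r$state
    }
    cin <- st$channels
  }
  if (!is.null(pretrained_file)) {
    pre <- readRDS(pretrained_file)
    for (nm in names(pre$params)) {
      if (!nm %in% names(params))
        stop("pretrained file holds unknown parameter: ", nm)
      if (!identical(dim(params[[nm]]), dim(pre$params[[nm]])) &&
          length(params[[nm]]) != length(pre$params[[nm]]))
        stop("pretrained parameter shape mismatch at: ", nm)
      params[[nm]] <- pre$params[[nm]]
    }
    if (!is.null(pre$state)) state[names(pre$state)] <- pre$state
  }
  list(params = params, state = state)
}

# block forward / backward ----------------------------------------------------

bn_apply <- function(params, senv, prefix, x, training) {
  r <- bn_fwd(x, params[[paste0(prefix, ".gamma")]],
              params[[paste0(prefix, ".beta")]],
              senv$s[[paste0(prefix, ".rmean")]],
              senv$s[[paste0(prefix, ".rvar")]], training)
  if (training) {
    senv$s[[paste0(prefix, ".rmean")]] <- r$rmean
    senv$s[[paste0(prefix, ".rvar")]] <- r$rvar
  }
  r
}

bn_back <- function(gacc, prefix, cache, dout) {
  r <- bn_bwd(cache, dout)
  g_add(gacc, paste0(prefix, ".gamma"), r$dgamma)
  g_add(gacc, paste0(prefix, ".beta"), r$dbeta)
  r$dx
}

g_add <- function(gacc, name, val) {
  cur <- gacc$g[[name]]
  gacc$g[[name]] <- if (is.null(cur)) val else cur + val
}

block_fwd <- function(params, senv, prefix, op, stride, expand, x, training) {
  cin <- dim(x)[3]
  cache <- list(op = op, prefix = prefix, expand = expand)
  if (op == "conv" || (op == "fused" && expand == 1)) {
    cv <- conv2d_fwd(x, params[[paste0(prefix, ".conv.W")]], stride = stride)
    bn <- bn_apply(params, senv, paste0(prefix, ".bn1"), cv$out, training)
    ac <- silu_fwd(bn$out)
    out <- ac$out
    cache$conv <- cv$cache; cache$bn1 <- bn$cache; cache$act <- ac$cache
  } else if (op == "fused") {
    cv <- conv2d_fwd(x, params[[paste0(prefix, ".conv.W")]], stride = stride)
    bn1 <- bn_apply(params, senv, paste0(prefix, ".bn1"), cv$out, training)
    ac <- silu_fwd(bn1$out)
    pj <- conv2d_fwd(ac$out, params[[paste0(prefix, ".proj.W")]], stride = 1L, pad = 0L)
    bn2 <- bn_apply(params, senv, paste0(prefix, ".bn2"), pj$out, training)
    out <- bn2$out
    cache$conv <- cv$cache; cache$bn1 <- bn1$cache; cache$act <- ac$cache
    cache$proj <- pj$cache; cache$bn2 <- bn2$cache
  } else { # mbconv
    h <- x
    bn_i <- 1
    if (expand > 1) {
      ex <- conv2d_fwd(h, params[[paste0(prefix, ".expand.W")]], stride = 1L, pad = 0L)
      bne <- bn_apply(params, senv, sprintf("%s.bn%d", prefix, bn_i), ex$out, training)
      ace <- silu_fwd(bne$out)
      h <- ace$out
      cache$exc <- ex$cache; cache$bne <- bne$cache; cache$ace <- ace$cache
      cache$bne_i <- bn_i
      bn_i <- bn_i + 1
    }
    dw <- dwconv2d_fwd(h, params[[paste0(prefix, ".dw.W")]], stride = stride)
    bnd <- bn_apply(params, senv, sprintf("%s.bn%d", prefix, bn_i), dw$out, training)
    acd <- silu_fwd(bnd$out)
    cache$bnd_i <- bn_i
    bn_i <- bn_i + 1
    se <- se_fwd(acd$out, params[[paste0(prefix, ".se.W1")]],
                 params[[paste0(prefix, ".se.b1")]],
                 params[[paste0(prefix, ".se.W2")]],
                 params[[paste0(prefix, ".se.b2")]])
    pj <- conv2d_fwd(se$out, params[[paste0(prefix, ".proj.W")]], stride = 1L, pad = 0L)
    bnp <- bn_apply(params, senv, sprintf("%s.bn%d", prefix, bn_i), pj$out, training)
    out <- bnp$out
    cache$dw <- dw$cache; cache$bnd <- bnd$cache; cache$acd <- acd$cache
    cache$se <- se$cache; cache$proj <- pj$cache; cache$bnp <- bnp$cache
    cache$bnp_i <- bn_i
  }
  residual <- stride == 1L && cin == dim(out)[3]
  if (residual) out <- out + x
  cache$residual <- residual
  list(out = out, cache = cache)
}

block_bwd <- function(gacc, cache, dout) {
  prefix <- cache$prefix
  op <- cache$op
  dres <- if (cache$residual) dout else NULL
  if (op == "conv" || (op == "fused" && cache$expand == 1)) {
    d <- silu_bwd(cache$act, dout)
    d <- bn_back(gacc, paste0(prefix, ".bn1"), cache$bn1, d)
    cb <- conv2d_bwd(cache$conv, d)
    g_add(gacc, paste0(prefix, ".conv.W"), cb$dw)
    dx <- cb$dx
  } else if (op == "fused") {
    d <- bn_back(gacc, paste0(prefix, ".bn2"), cache$bn2, dout)
    pb <- conv2d_bwd(cache$proj, d)
    g_add(gacc, paste0(prefix, ".proj.W"), pb$dw)
    d <- silu_bwd(cache$act, pb$dx)
    d <- bn_back(gacc, paste0(prefix, ".bn1"), cache$bn1, d)
    cb <- conv2d_bwd(cache$conv, d)
    g_add(gacc, paste0(prefix, ".conv.W"), cb$dw)
    dx <- cb$dx
  } else {
    d <- bn_back(gacc, sprintf("%s.bn%d", prefix, cache$bnp_i), cache$bnp, dout)
    pb <- conv2d_bwd(cache$proj, d)
    g_add(gacc, paste0(prefix, ".proj.W"), pb$dw)
    sb <- se_bwd(cache$se, pb$dx)
    g_add(gacc, paste0(prefix, ".se.W1"), sb$dw1)
    g_add(gacc, paste0(prefix, ".se.b1"), sb$db1)
    g_add(gacc, paste0(prefix, ".se.W2"), sb$dw2)
    g_add(gacc, paste0(prefix, ".se.b2"), sb$db2)
    d <- silu_bwd(cache$acd, sb$dx)
    d <- bn_back(gacc, sprintf("%s.bn%d", prefix, cache$bnd_i), cache$bnd, d)
    db <- dwconv2d_bwd(cache$dw, d)
    g_add(gacc, paste0(prefix, ".dw.W"), db$dw)
    d <- db$dx
    if (cache$expand > 1) {
      d <- silu_bwd(cache$ace, d)
      d <- bn_back(gacc, sprintf("%s.bn%d", prefix, cache$bne_i), cache$bne, d)
      eb <- conv2d_bwd(cache$exc, d)
      g_add(gacc, paste0(prefix, ".expand.W"), eb$dw)
      d <- eb$dx
    }
    dx <- d
  }
  if (!is.null(dres)) dx <- dx + dres
  dx
}

#' Run one backbone stage
#'
#' Applies all blocks of stage `stage_index` to a feature map.  The first
#' block carries the stage stride; later blocks use stride 1 and a residual
#' connection when input and output shapes match.
#'
#' @param params flat named parameter list (from [build_backbone()]).
#' @param senv environment holding `s`, the batch-norm state list.
#' @param config a [backbone_config()].
#' @param stage_index stage number, 1..8.
#' @param x input array (H, W, C, N).
#' @param training logical; batch statistics and state updates when `TRUE`.
#' @return list(out, caches).
#' @export
forward_stage <- function(params, senv, config, stage_index, x, training = FALSE) {
  st <- config$stages[[stage_index]]
  expected_cin <- if (stage_index == 1) 3L else config$stages[[stage_index - 1]]$channels
  if (dim(x)[3] != expected_cin) {
    stop(sprintf("stage %d expects %d input channels, got %d",
                 stage_index, expected_cin, dim(x)[3]))
  }
  caches <- vector("list", st$layers)
  for (b in seq_len(st$layers)) {
    stride <- if (b == 1) st$stride else 1L
    r <- block_fwd(params, senv, sprintf("st%d.b%d", stage_index, b),
                   st$op, stride, st$expand, x, training)
    x <- r$out
    caches[[b]] <- r$cache
  }
  list(out = x, caches = caches)
}

backward_stage <- function(gacc, caches, dout) {
  for (b in rev(seq_along(caches))) {
    dout <- block_bwd(gacc, caches[[b]], dout)
  }
  dout
}

#' Extract all 8 stage feature maps for one modality
#'
#' Runs the shared backbone without any cross-modal exchange — the ablation
#' baseline path and the shape-contract entry point.
#'
#' @inheritParams forward_stage
#' @param x normalized input batch (H, W, 3, N).
#' @return list of 8 arrays, one per stage.
#' @export
extract_all_stages <- function(params, senv, config, x, training = FALSE) {
  out <- vector("list", length(config$stages))
  for (s in seq_along(config$stages)) {
    r <- forward_stage(params, senv, config, s, x, training)
    x <- r$out
    out[[s]] <- x
  }
  out
}

#' Count parameters in a flat parameter list
#' @param params named list of arrays.
#' @return total number of scalar parameters.
#' @export
count_parameters <- function(params) sum(vapply(params, length, numeric(1)))
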