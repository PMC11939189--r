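# Low-level tensor operations for the network core.
#
# Feature maps are dense arrays with dim = c(H, W, C, N) (spatial rows,
# spatial cols, channels, batch).  All convolutions are expressed as k^2
# shifted 1x1 convolutions so the inner loop is a BLAS matmul; channel-wise
# broadcasts exploit R's column-major recycling: a vector of length H*W*C
# recycles exactly once per batch element over an (H, W, C, N) array.
#
# Every op comes as a `*_fwd()` returning list(out, cache) and a `*_bwd()`
# taking (cache, dout) and returning input/parameter gradients.  Shapes are
# trusted internally; user-facing entry points validate.

zeros <- function(...) array(0, dim = c(...))

# broadcast a per-channel vector over an (H, W, C, N) array via recycling
chan_vec <- function(v, h, w) rep(v, each = h * w)

# per-channel reduction over (H, W, N) of an (H, W, C, N) array
chan_sum <- function(x) {
  d <- dim(x)
  m <- colSums(matrix(x, nrow = d[1] * d[2], ncol = d[3] * d[4]))
  rowSums(matrix(m, nrow = d[3], ncol = d[4]))
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- zeros(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4])
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  xp
}

unpad_hw <- function(xp, p, h, w) {
  if (p == 0) return(xp)
  xp[(p + 1):(p + h), (p + 1):(p + w), , , drop = FALSE]
}

# flatten (H, W, C, N) -> matrix (H*W*N, C); inverse restores the array
hwn_by_c <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  x
}

c_to_hwn <- function(m, h, w, cc, n) {
  dim(m) <- c(h * w, n, cc)
  m <- aperm(m, c(1, 3, 2))
  dim(m) <- c(h, w, cc, n)
  m
}

conv_out_size <- function(len, k, stride, pad) (len + 2 * pad - k) %/% stride + 1

# "same"-style padding used throughout: for kernel k, pad (k - 1) / 2
same_pad <- function(k) (k - 1L) %/% 2L

# The padded input is permuted once to (H, W, N, C) so that each kernel
# offset's patch matrix is a plain reshape of a slice (no per-offset aperm).
#' @noRd
conv2d_fwd <- function(x, w, b = NULL, stride = 1L, pad = same_pad(dim(w)[1])) {
  d <- dim(x)
  k <- dim(w)[1]
  cin <- dim(w)[3]
  cout <- dim(w)[4]
  stopifnot(d[3] == cin)
  ho <- conv_out_size(d[1], k, stride, pad)
  wo <- conv_out_size(d[2], k, stride, pad)
  xpp <- aperm(pad_hw(x, pad), c(1, 2, 4, 3))     # (Hp, Wp, N, C)
  nr <- ho * wo * d[4]
  if (k == 1L && stride == 1L && pad == 0L) {
    xm <- xpp
    dim(xm) <- c(nr, cin)
    ymat <- xm %*% w[1, 1, , ]
  } else {
    ymat <- matrix(0, nr, cout)
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        rows <- seq(ki, by = stride, length.out = ho)
        cols <- seq(kj, by = stride, length.out = wo)
        xm <- xpp[rows, cols, , , drop = FALSE]
        dim(xm) <- c(nr, cin)
        ymat <- ymat + xm %*% w[ki, kj, , ]
      }
    }
  }
  if (!is.null(b)) ymat <- ymat + rep(b, each = nr)
  out <- c_to_hwn(ymat, ho, wo, cout, d[4])
  list(out = out, cache = list(xpp = xpp, w = w, stride = stride, pad = pad,
                               in_dim = d, ho = ho, wo = wo, has_bias = !is.null(b)))
}

#' @noRd
conv2d_bwd <- function(cache, dout) {
  xpp <- cache$xpp; w <- cache$w
  k <- dim(w)[1]; stride <- cache$stride
  d <- cache$in_dim; ho <- cache$ho; wo <- cache$wo
  dymat <- hwn_by_c(dout)
  nr <- nrow(dymat)
  dw <- array(0, dim = dim(w))
  if (k == 1L && stride == 1L && cache$pad == 0L) {
    xm <- xpp
    dim(xm) <- c(nr, dim(w)[3])
    dw[1, 1, , ] <- crossprod(xm, dymat)
    dxm <- tcrossprod(dymat, w[1, 1, , ])
    dim(dxm) <- dim(xpp)
    dxpp <- dxm
  } else {
    dxpp <- array(0, dim = dim(xpp))
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        rows <- seq(ki, by = stride, length.out = ho)
        cols <- seq(kj, by = stride, length.out = wo)
        xm <- xpp[rows, cols, , , drop = FALSE]
        dim(xm) <- c(nr, dim(w)[3])
        dw[ki, kj, , ] <- crossprod(xm, dymat)
        dxm <- tcrossprod(dymat, w[ki, kj, , ])
        dim(dxm) <- c(ho, wo, d[4], dim(w)[3])
        dxpp[rows, cols, , ] <- dxpp[rows, cols, , , drop = FALSE] + dxm
      }
    }
  }
  dxp <- aperm(dxpp, c(1, 2, 4, 3))
  db <- if (cache$has_bias) colSums(dymat) else NULL
  list(dx = unpad_hw(dxp, cache$pad, d[1], d[2]), dw = dw, db = db)
}

#' @noRd
dwconv2d_fwd <- function(x, w, stride = 1L, pad = same_pad(dim(w)[1])) {
  d <- dim(x); k <- dim(w)[1]; cc <- d[3]
  stopifnot(dim(w)[3] == cc)
  xp <- pad_hw(x, pad)
  ho <- conv_out_size(d[1], k, stride, pad)
  wo <- conv_out_size(d[2], k, stride, pad)
  out <- zeros(ho, wo, cc, d[4])
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      rows <- seq(ki, by = stride, length.out = ho)
      cols <- seq(kj, by = stride, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      out <- out + xs * chan_vec(w[ki, kj, ], ho, wo)
    }
  }
  list(out = out, cache = list(xp = xp, w = w, stride = stride, pad = pad,
                               in_dim = d, ho = ho, wo = wo))
}

#' @noRd
dwconv2d_bwd <- function(cache, dout) {
  xp <- cache$xp; w <- cache$w
  k <- dim(w)[1]; stride <- cache$stride
  d <- cache$in_dim; ho <- cache$ho; wo <- cache$wo
  dw <- array(0, dim = dim(w))
  dxp <- array(0, dim = dim(xp))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      rows <- seq(ki, by = stride, length.out = ho)
      cols <- seq(kj, by = stride, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      dw[ki, kj, ] <- chan_sum(dout * xs)
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
        dout * chan_vec(w[ki, kj, ], ho, wo)
    }
  }
  list(dx = unpad_hw(dxp, cache$pad, d[1], d[2]), dw = dw)
}

#' @noRd
bn_fwd <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.9,
                   eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  nred <- hw * d[4]
  if (training) {
    mu <- chan_sum(x) / nred
    xc <- x - chan_vec(mu, d[1], d[2])
    v <- chan_sum(xc * xc) / nred
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * chan_vec(invstd, d[1], d[2])
    rmean_new <- momentum * rmean + (1 - momentum) * mu
    rvar_new <- momentum * rvar + (1 - momentum) * v
  } else {
    invstd <- 1 / sqrt(rvar + eps)
    xhat <- (x - chan_vec(rmean, d[1], d[2])) * chan_vec(invstd, d[1], d[2])
    rmean_new <- rmean; rvar_new <- rvar
  }
  out <- xhat * chan_vec(gamma, d[1], d[2]) + chan_vec(beta, d[1], d[2])
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    training = training, dims = d, nred = nred),
       rmean = rmean_new, rvar = rvar_new)
}

#' @noRd
bn_bwd <- function(cache, dout) {
  d <- cache$dims
  xhat <- cache$xhat
  dgamma <- chan_sum(dout * xhat)
  dbeta <- chan_sum(dout)
  g <- chan_vec(cache$gamma * cache$invstd, d[1], d[2])
  if (!cache$training) {
    return(list(dx = dout * g, dgamma = dgamma, dbeta = dbeta))
  }
  nred <- cache$nred
  dxhat <- dout * chan_vec(cache$gamma, d[1], d[2])
  m1 <- chan_sum(dxhat) / nred
  m2 <- chan_sum(dxhat * xhat) / nred
  dx <- (dxhat - chan_vec(m1, d[1], d[2]) - xhat * chan_vec(m2, d[1], d[2])) *
    chan_vec(cache$invstd, d[1], d[2])
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
silu_fwd <- function(x) {
  s <- sigmoid(x)
  list(out = x * s, cache = list(x = x, s = s))
}

#' @noRd
silu_bwd <- function(cache, dout) {
  s <- cache$s
  dout * (s + cache$x * s * (1 - s))
}

# squeeze-and-excitation: GAP -> FC reduce -> SiLU -> FC expand -> sigmoid gate
#' @noRd
se_fwd <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  hw <- d[1] * d[2]
  z <- matrix(colMeans(matrix(x, nrow = hw)), nrow = d[3])   # C x N
  h <- w1 %*% z + b1
  a <- silu_fwd(h)
  u <- w2 %*% a$out + b2
  g <- sigmoid(u)                                            # C x N
  gfull <- array(g[rep(seq_len(d[3]), each = hw), ], dim = d)
  list(out = x * gfull,
       cache = list(x = x, z = z, a = a, g = g, gfull = gfull,
                    w1 = w1, w2 = w2, dims = d))
}

#' @noRd
se_bwd <- function(cache, dout) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dx_direct <- dout * cache$gfull
  dg <- matrix(colSums(matrix(dout * cache$x, nrow = hw)), nrow = d[3])  # C x N
  du <- dg * cache$g * (1 - cache$g)
  dw2 <- tcrossprod(du, cache$a$out)
  db2 <- rowSums(du)
  da <- crossprod(cache$w2, du)
  dh <- silu_bwd(cache$a$cache, da)
  dw1 <- tcrossprod(dh, cache$z)
  db1 <- rowSums(dh)
  dz <- crossprod(cache$w1, dh)                                # C x N
  dx_pool <- array(dz[rep(seq_len(d[3]), each = hw), ] / hw, dim = d)
  list(dx = dx_direct + dx_pool, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# global average pool (H, W, C, N) -> (C, N)
#' @noRd
gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  list(out = matrix(colMeans(matrix(x, nrow = hw)), nrow = d[3]),
       cache = list(dims = d))
}

#' @noRd
gap_bwd <- function(cache, dout) {
  d <- cache$dims
  hw <- d[1] * d[2]
  array(dout[rep(seq_len(d[3]), each = hw), ] / hw, dim = d)
}

#' @noRd
linear_fwd <- function(x, w, b) {
  list(out = w %*% x + b, cache = list(x = x, w = w))
}

#' @noRd
linear_bwd <- function(cache, dout) {
  list(dx = crossprod(cache$w, dout),
       dw = tcrossprod(dout, cache$x),
       db = rowSums(dout))
}

# column-wise softmax of a C x N logit matrix, numerically stabilised
#' @noRd
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# seeded He-normal initialisation for conv / linear weights
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}
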