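# Minimal dense-prediction network engine: 2-D convolution and transposed
# convolution via im2col on base matrix algebra, ReLU, and Adam.  All shapes
# are (H, W, C) arrays, column-major as R stores them.  Gradients are exact
# (verified by finite differences in the test suite).

.im2col_cache <- new.env(parent = emptyenv())

# Index matrix mapping a padded (Hp, Wp, C) array to patch-columns.
# Rows enumerate output positions (oy fastest), columns enumerate
# (ky, kx, c).  Within any single column all indices are distinct, which
# makes scatter-accumulation in the backward pass a plain vectorized add.
im2col_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- rep.int(seq_len(Ho), Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  base_y <- (oy - 1L) * stride          # length Ho*Wo
  base_x <- (ox - 1L) * stride
  ky <- rep.int(seq_len(k), k * C)
  kx <- rep.int(rep(seq_len(k), each = k), C)
  kc <- rep(seq_len(C), each = k * k)
  # idx[r, j] = (base_y + ky) + (base_x + kx - 1)*Hp + (c-1)*Hp*Wp
  idx <- outer(base_y, ky, "+") +
    outer(base_x, kx - 1L, "+") * Hp +
    matrix((kc - 1L) * Hp * Wp, nrow = Ho * Wo, ncol = k * k * C, byrow = TRUE)
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

pad_array <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- X
  Xp
}

unpad_array <- function(Xp, pad, H, W) {
  if (pad == 0L) return(Xp)
  Xp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

as_hwc <- function(X) {
  if (is.matrix(X)) dim(X) <- c(dim(X), 1L)
  X
}

#' @keywords internal
conv_fwd <- function(X, W, b, stride, pad) {
  X <- as_hwc(X)
  d <- dim(X)
  k <- as.integer(round(sqrt(nrow(W) / d[3])))
  ii <- im2col_idx(d[1], d[2], d[3], k, stride, pad)
  Xp <- pad_array(X, pad)
  # as.vector: force linear indexing (a 3-column index matrix would
  # otherwise be read as (i,j,k) coordinate rows)
  cols <- matrix(Xp[as.vector(ii$idx)], nrow = ii$Ho * ii$Wo)
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(ii$Ho, ii$Wo, ncol(W))
  list(Y = Y, cols = cols, in_dim = d, k = k)
}

conv_bwd <- function(dY, fwd, W, stride, pad, need_dx = TRUE) {
  d <- fwd$in_dim; k <- fwd$k
  ii <- im2col_idx(d[1], d[2], d[3], k, stride, pad)
  dYm <- matrix(dY, nrow = ii$Ho * ii$Wo)
  dW <- crossprod(fwd$cols, dYm)
  db <- colSums(dYm)
  dX <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dYm, W)
    dXp <- numeric(ii$Hp * ii$Wp * d[3])
    for (j in seq_len(ncol(dcols))) {
      jj <- ii$idx[, j]
      dXp[jj] <- dXp[jj] + dcols[, j]
    }
    dim(dXp) <- c(ii$Hp, ii$Wp, d[3])
    dX <- unpad_array(dXp, pad, d[1], d[2])
  }
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution: maps (H, W, Cin) up to (Ho, Wo, Cout) with
# Ho = (H-1)*stride + k - 2*pad.  W is (k*k*Cout) x Cin, i.e. the weight
# of the conv whose adjoint this is.
deconv_fwd <- function(X, W, b, stride, pad, k) {
  X <- as_hwc(X)
  d <- dim(X)
  Cout <- nrow(W) / (k * k)
  Ho <- (d[1] - 1L) * stride + k - 2L * pad
  Wo <- (d[2] - 1L) * stride + k - 2L * pad
  ii <- im2col_idx(Ho, Wo, Cout, k, stride, pad)
  stopifnot(ii$Ho == d[1], ii$Wo == d[2])
  Xm <- matrix(X, nrow = d[1] * d[2])
  dcols <- tcrossprod(Xm, W)           # (H*W) x (k*k*Cout)
  Yp <- numeric(ii$Hp * ii$Wp * Cout)
  for (j in seq_len(ncol(dcols))) {
    jj <- ii$idx[, j]
    Yp[jj] <- Yp[jj] + dcols[, j]
  }
  dim(Yp) <- c(ii$Hp, ii$Wp, Cout)
  Y <- unpad_array(Yp, pad, Ho, Wo)
  Y <- Y + rep(b, each = Ho * Wo)
  list(Y = Y, Xm = Xm, in_dim = d, out_dim = c(Ho, Wo, Cout))
}

deconv_bwd <- function(dY, fwd, W, stride, pad, k, need_dx = TRUE) {
  od <- fwd$out_dim
  ii <- im2col_idx(od[1], od[2], od[3], k, stride, pad)
  dYp <- pad_array(dY, pad)
  cols <- matrix(dYp[as.vector(ii$idx)],
                 nrow = ii$Ho * ii$Wo)   # (H*W) x (k*k*Cout)
  dW <- crossprod(cols, fwd$Xm)
  db <- colSums(matrix(dY, ncol = od[3]))
  dX <- NULL
  if (need_dx) {
    dX <- cols %*% W
    dim(dX) <- fwd$in_dim
  }
  list(dX = dX, dW = dW, db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(dY, Y) { dY[Y <= 0] <- 0; dY }

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer constructors ------------------------------------------------

new_conv_layer <- function(Cin, Cout, k = 3L, stride = 1L, pad = 1L,
                           act = "relu", bias_init = 0) {
  fan_in <- k * k * Cin
  W <- matrix(stats::rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)),
              nrow = fan_in, ncol = Cout)
  list(kind = "conv", W = W, b = rep(bias_init, Cout), k = k,
       stride = stride, pad = pad, Cin = Cin, Cout = Cout, act = act)
}

new_deconv_layer <- function(Cin, Cout, k = 4L, stride = 2L, pad = 1L,
                             act = "relu") {
  fan_in <- k * k * Cin
  W <- matrix(stats::rnorm(k * k * Cout * Cin, sd = sqrt(2 / fan_in)),
              nrow = k * k * Cout, ncol = Cin)
  list(kind = "deconv", W = W, b = rep(0, Cout), k = k,
       stride = stride, pad = pad, Cin = Cin, Cout = Cout, act = act)
}

layer_fwd <- function(layer, X) {
  f <- if (layer$kind == "conv") {
    conv_fwd(X, layer$W, layer$b, layer$stride, layer$pad)
  } else {
    deconv_fwd(X, layer$W, layer$b, layer$stride, layer$pad, layer$k)
  }
  pre <- f$Y
  Y <- if (layer$act == "relu") relu(pre) else pre
  list(Y = Y, fwd = f)
}

layer_bwd <- function(layer, dY, cache, need_dx = TRUE) {
  if (layer$act == "relu") dY <- relu_bwd(dY, cache$Y)
  if (layer$kind == "conv") {
    conv_bwd(dY, cache$fwd, layer$W, layer$stride, layer$pad, need_dx)
  } else {
    deconv_bwd(dY, cache$fwd, layer$W, layer$stride, layer$pad, layer$k,
               need_dx)
  }
}

seq_fwd <- function(layers, X) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], X)
    caches[[i]] <- r
    X <- r$Y
  }
  list(out = X, caches = caches)
}

seq_bwd <- function(layers, caches, dOut, need_dx = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    g <- layer_bwd(layers[[i]], dOut, caches[[i]],
                   need_dx = need_dx || i > 1L)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    dOut <- g$dX
  }
  list(grads = grads, dX = dOut)
}

# ---- parameter vector view --------------------------------------------

layers_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

layers_unflatten <- function(layers, theta) {
  pos <- 0L
  for (i in seq_along(layers)) {
    nw <- length(layers[[i]]$W); nb <- length(layers[[i]]$b)
    layers[[i]]$W[] <- theta[pos + seq_len(nw)]
    layers[[i]]$b <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  stopifnot(pos == length(theta))
  layers
}

grads_flatten <- function(grads) {
  unlist(lapply(grads, function(g) c(as.vector(g$dW), g$db)),
         use.names = FALSE)
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(state, theta, grad, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(state = state, theta = theta)
}
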