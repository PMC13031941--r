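# Minimal dense/convolutional network primitives used by the frame
# detector. Feature maps are stored column-major as (H*W*C) x N matrices
# with channel-major blocks (pixel index = h + (w-1)*H + (c-1)*H*W);
# convolutions are evaluated as BLAS matrix products over precomputed
# im2col index tables, which is fast enough for desk-scale CPU training.

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

nn_conv <- function(shape_in, filters, kernel = 3L, stride = 2L) {
  H <- shape_in[1]; W <- shape_in[2]; C <- shape_in[3]
  kh <- kernel; kw <- kernel
  H2 <- (H - kh) %/% stride + 1L
  W2 <- (W - kw) %/% stride + 1L
  if (H2 < 1 || W2 < 1) stop("feature map smaller than kernel")
  K <- kh * kw * C
  P <- H2 * W2
  off <- expand.grid(di = 0:(kh - 1), dj = 0:(kw - 1), c = 0:(C - 1))
  pos <- expand.grid(i = 0:(H2 - 1), j = 0:(W2 - 1))
  idx <- outer(off$di + off$dj * H + off$c * H * W,
               pos$i * stride + pos$j * stride * H, `+`) + 1L
  list(type = "conv",
       W = matrix(glorot_uniform(K, kh * kw * filters, K * filters),
                  K, filters),
       b = numeric(filters),
       idx = as.integer(idx), K = K, P = P,
       n_in = H * W * C, filters = filters,
       shape_out = c(H2, W2, filters))
}

nn_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(glorot_uniform(n_in, n_out, n_in * n_out), n_in, n_out),
       b = numeric(n_out))
}

nn_relu <- function() list(type = "relu")
nn_gap <- function(shape_in) list(type = "gap", P = shape_in[1] * shape_in[2],
                                  C = shape_in[3])
nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    l <- layers[[k]]
    if (l$type == "conv") {
      N <- ncol(X)
      col <- X[l$idx, , drop = FALSE]
      dim(col) <- c(l$K, l$P * N)
      out <- crossprod(l$W, col) + l$b
      caches[[k]] <- list(col = col, N = N)
      out <- aperm(array(out, c(l$filters, l$P, N)), c(2, 1, 3))
      dim(out) <- c(l$P * l$filters, N)
      X <- out
    } else if (l$type == "dense") {
      caches[[k]] <- list(a = X)
      X <- crossprod(l$W, X) + l$b
    } else if (l$type == "relu") {
      caches[[k]] <- list(mask = X > 0)
      X <- X * caches[[k]]$mask
    } else if (l$type == "gap") {
      N <- ncol(X)
      caches[[k]] <- list(N = N)
      X <- colMeans(array(X, c(l$P, l$C, N)))
      dim(X) <- c(l$C, N)
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix((stats::runif(length(X)) >= l$rate) / (1 - l$rate),
                       nrow(X), ncol(X))
        caches[[k]] <- list(mask = mask)
        X <- X * mask
      } else caches[[k]] <- list(mask = NULL)
    }
  }
  list(out = X, caches = caches)
}

nn_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (k in rev(seq_along(layers))) {
    l <- layers[[k]]; cache <- caches[[k]]
    if (l$type == "conv") {
      N <- cache$N
      dOut <- aperm(array(dY, c(l$P, l$filters, N)), c(2, 1, 3))
      dim(dOut) <- c(l$filters, l$P * N)
      grads[[k]] <- list(W = tcrossprod(cache$col, dOut),
                         b = rowSums(dOut))
      dcol <- l$W %*% dOut
      dim(dcol) <- c(l$K * l$P, N)
      acc <- rowsum(dcol, l$idx)
      dX <- matrix(0, l$n_in, N)
      dX[as.integer(rownames(acc)), ] <- acc
      dY <- dX
    } else if (l$type == "dense") {
      grads[[k]] <- list(W = tcrossprod(cache$a, dY), b = rowSums(dY))
      dY <- l$W %*% dY
    } else if (l$type == "relu") {
      dY <- dY * cache$mask
    } else if (l$type == "gap") {
      dY <- dY[rep(seq_len(l$C), each = l$P), , drop = FALSE] / l$P
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) dY <- dY * cache$mask
    }
  }
  grads
}

nn_softmax <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

nn_count_params <- function(layers) {
  sum(vapply(layers, function(l)
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L, numeric(1)))
}

# Adam with externally supplied learning rate (staircase schedule)
nn_adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(layers)) {
    if (is.null(state[[k]])) next
    g <- grads[[k]]; s <- state[[k]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhat <- s$mW / (1 - beta1^t); vhat <- s$vW / (1 - beta2^t)
    layers[[k]]$W <- layers[[k]]$W - lr * mhat / (sqrt(vhat) + eps)
    mhat <- s$mb / (1 - beta1^t); vhat <- s$vb / (1 - beta2^t)
    layers[[k]]$b <- layers[[k]]$b - lr * mhat / (sqrt(vhat) + eps)
    state[[k]] <- s
  }
  list(layers = layers, state = state)
}
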