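# Internal 2D convolutional-network numerics for the kernel converter.
#
# The network is a plain stack of 3x3 "same" convolutions evaluated as
# im2col matrices times weight matrices, so all heavy lifting is BLAS GEMM.
# Feature maps move through the stack as 4D arrays (H, W, C, B); im2col
# matrices have one row per (pixel, image) and one column per
# (offset, channel), offset-major.

nn_pad <- function(x) {
  d <- dim(x)
  out <- array(0, d + c(2L, 2L, 0L, 0L))
  out[2:(d[1] + 1), 2:(d[2] + 1), , ] <- x
  out
}

nn_im2col <- function(x) {
  d <- dim(x)  # (H, W, C, B)
  h <- d[1]; w <- d[2]; cc <- d[3]; b <- d[4]
  p <- nn_pad(x)
  out <- matrix(0, h * w * b, 9L * cc)
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1L
      sl <- p[dy + seq_len(h), dx + seq_len(w), , , drop = FALSE]
      out[, ((k - 1L) * cc + 1L):(k * cc)] <-
        matrix(aperm(sl, c(1, 2, 4, 3)), h * w * b, cc)
    }
  }
  out
}

nn_col2im <- function(dcol, h, w, cc, b) {
  dp <- array(0, c(h + 2L, w + 2L, cc, b))
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1L
      sl <- array(dcol[, ((k - 1L) * cc + 1L):(k * cc)], c(h, w, b, cc))
      dp[dy + seq_len(h), dx + seq_len(w), , ] <-
        dp[dy + seq_len(h), dx + seq_len(w), , , drop = FALSE] +
        aperm(sl, c(1, 2, 4, 3))
    }
  }
  dp[2:(h + 1), 2:(w + 1), , , drop = FALSE]
}

# Matrix (HWB x C) -> feature-map array (H, W, C, B)
nn_mat2map <- function(m, h, w, b) {
  cc <- ncol(m)
  aperm(array(m, c(h, w, b, cc)), c(1, 2, 4, 3))
}

nn_map2mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

nn_init_layers <- function(n_layers, channels, seed) {
  with_seed(seed, {
    layers <- vector("list", n_layers)
    c_in <- 1L
    for (l in seq_len(n_layers)) {
      c_out <- if (l == n_layers) 1L else channels
      if (l == n_layers) {
        # zero-initialized final layer: the untrained network is the identity
        w <- matrix(0, 9L * c_in, c_out)
      } else {
        w <- matrix(rnorm(9L * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                    9L * c_in, c_out)
      }
      layers[[l]] <- list(
        W = w, b = numeric(c_out),
        activation = if (l == n_layers) "linear" else "relu"
      )
      c_in <- c_out
    }
    layers
  })
}

# Forward pass. input: (H, W, B) single-channel slices.
# Returns the residual map (H, W, B) and, if keep_cache, the im2col matrices
# and ReLU masks needed for backprop.
nn_forward <- function(layers, input, keep_cache = FALSE) {
  d <- dim(input)
  h <- d[1]; w <- d[2]; b <- d[3]
  x <- array(input, c(h, w, 1L, b))
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    xcol <- nn_im2col(x)
    y <- xcol %*% ly$W
    y <- sweep(y, 2L, ly$b, `+`)
    if (ly$activation == "relu") {
      mask <- y > 0
      y <- y * mask
    } else {
      mask <- NULL
    }
    if (keep_cache) cache[[l]] <- list(xcol = xcol, mask = mask)
    x <- nn_mat2map(y, h, w, b)
  }
  list(residual = array(x, c(h, w, b)), cache = cache)
}

# Backprop of d(loss)/d(residual). Returns per-layer gradients.
nn_backward <- function(layers, cache, dres, h, w, b) {
  d <- matrix(dres, h * w * b, 1L)
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    if (!is.null(cache[[l]]$mask)) d <- d * cache[[l]]$mask
    grads[[l]] <- list(dW = crossprod(cache[[l]]$xcol, d), db = colSums(d))
    if (l > 1L) {
      dcol <- d %*% t(ly$W)
      c_in <- ncol(layers[[l - 1L]]$W)  # channels out of previous layer
      dmap <- nn_col2im(dcol, h, w, c_in, b)
      d <- nn_map2mat(dmap)
    }
  }
  grads
}

nn_adam_init <- function(layers) {
  lapply(layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[l]]$W <- layers[[l]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    layers[[l]]$b <- layers[[l]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}
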