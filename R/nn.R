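# Layer primitives for the segmentation network. Tensors are numeric arrays
# with dim = (H, W, C, N); convolution and pooling run through compiled
# kernels, element-wise layers are vectorized R.

conv_forward <- function(x, W, b, k) {
  y <- cpp_conv2d_forward(x, W, b, as.integer(k))
  list(y = y, cache = list(x = x, k = k))
}

conv_backward <- function(dy, W, cache) {
  g <- cpp_conv2d_backward(cache$x, W, dy, as.integer(cache$k))
  list(dx = g$dx, dW = g$dW, db = as.numeric(g$db))
}

bn_forward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  M <- d[1] * d[2] * d[4]
  if (training) {
    st <- cpp_channel_stats(x)
    mean_c <- st[1, ] / M
    var_c <- pmax(st[2, ] / M - mean_c^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mean_c
    rvar <- (1 - momentum) * rvar + momentum * var_c
  } else {
    mean_c <- rmean; var_c <- rvar
  }
  inv_sd <- 1 / sqrt(var_c + eps)
  scale <- gamma * inv_sd
  y <- cpp_scale_shift(x, scale, beta - mean_c * scale)
  list(y = y, rmean = rmean, rvar = rvar,
       cache = list(x = x, mean = mean_c, inv_sd = inv_sd, gamma = gamma,
                    batch_stats = training))
}

bn_backward <- function(dy, cache) {
  cpp_bn_backward(dy, cache$x, cache$mean, cache$inv_sd, cache$gamma,
                  cache$batch_stats)
}

prelu_forward <- function(x, alpha) {
  list(y = cpp_prelu_forward(x, alpha), cache = list(x = x, alpha = alpha))
}

prelu_backward <- function(dy, cache) {
  cpp_prelu_backward(dy, cache$x, cache$alpha)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  y <- x * keep
  dim(y) <- dim(x)
  list(y = y, cache = keep)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  dx <- dy * cache
  dim(dx) <- dim(dy)
  dx
}

maxpool_forward <- function(x) {
  out <- cpp_maxpool_forward(x)
  list(y = out$y, cache = list(idx = out$idx, xdim = dim(x)))
}

maxpool_backward <- function(dy, cache) {
  cpp_maxpool_backward(dy, cache$idx, as.integer(cache$xdim))
}

upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample_backward <- function(dy) {
  d <- dim(dy)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  dy[oi, oj, , , drop = FALSE] + dy[oi + 1L, oj, , , drop = FALSE] +
    dy[oi, oj + 1L, , , drop = FALSE] + dy[oi + 1L, oj + 1L, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(a = dy[, , seq_len(c1), , drop = FALSE],
       b = dy[, , (c1 + 1):d[3], , drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))
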