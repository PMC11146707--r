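# Low-level layers of the 1-D CNN engine. All signal tensors are R arrays
# with dim (length, channels, batch); weights are (k, in_channels,
# out_channels). Convolutions run through the compiled im2col kernels.

conv_pads <- function(L, k, stride, dilation,
                      padding = c("same", "causal", "valid")) {
  padding <- match.arg(padding)
  span <- (k - 1L) * dilation
  switch(padding,
    same = {
      Lout <- ceiling(L / stride)
      total <- max(0L, (Lout - 1L) * stride + span + 1L - L)
      c(total %/% 2L, total - total %/% 2L)
    },
    causal = c(span, 0L),
    valid = c(0L, 0L))
}

conv1d_forward <- function(x, w, bias = NULL, stride = 1L, dilation = 1L,
                           padding = "same") {
  k <- dim(w)[1]
  if (is.null(bias)) bias <- numeric(dim(w)[3])
  p <- conv_pads(dim(x)[1], k, stride, dilation, padding)
  y <- .conv1d_forward(x, w, bias, as.integer(stride), as.integer(dilation),
                       p[1], p[2])
  list(y = y, cache = list(x = x, w = w, stride = as.integer(stride),
                           dilation = as.integer(dilation), pads = p,
                           has_bias = !is.null(bias)))
}

conv1d_backward <- function(cache, dy) {
  g <- .conv1d_backward(cache$x, cache$w, dy, cache$stride, cache$dilation,
                        cache$pads[1], cache$pads[2])
  g$db <- as.numeric(g$db)    # arma::vec comes back as an n x 1 matrix
  g
}

# --- batch normalization over the channel axis ------------------------------

channel_stat <- function(x) {
  # per-channel sums of an (L, C, B) array -> length-C vector
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, nrow = d[1])), nrow = d[2]))
}

bn_forward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[3]
  if (training) {
    mu <- channel_stat(x) / n
    xm <- sweep_channels(x, mu, "-")
    v <- channel_stat(xm * xm) / n
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean; v <- rvar
    xm <- sweep_channels(x, mu, "-")
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep_channels(xm, inv_std, "*")
  y <- sweep_channels(xhat, gamma, "*")
  y <- sweep_channels(y, beta, "+")
  list(y = y,
       cache = list(xhat = xhat, gamma = gamma, inv_std = inv_std, n = n),
       rmean = rmean, rvar = rvar)
}

sweep_channels <- function(x, v, op) {
  # broadcast a per-channel vector over an (L, C, B) array
  d <- dim(x)
  col <- rep(v, times = d[3])          # one value per (c, b) column
  m <- sweep(matrix(x, nrow = d[1]), 2, col, op)
  array(m, dim = d)
}

bn_backward <- function(cache, dy) {
  d <- dim(dy); n <- cache$n
  dgamma <- channel_stat(dy * cache$xhat)
  dbeta <- channel_stat(dy)
  dxhat <- sweep_channels(dy, cache$gamma, "*")
  s1 <- channel_stat(dxhat)
  s2 <- channel_stat(dxhat * cache$xhat)
  t1 <- dxhat * n
  t1 <- sweep_channels(t1, s1, "-")
  t1 <- t1 - sweep_channels(cache$xhat, s2, "*")
  dx <- sweep_channels(t1, cache$inv_std / n, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- pointwise layers -------------------------------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dy) dy * cache

gap_forward <- function(x) {
  d <- dim(x)
  y <- matrix(colSums(matrix(x, nrow = d[1])), nrow = d[2]) / d[1]  # (C, B)
  list(y = y, cache = d)
}
gap_backward <- function(cache, dy) {
  array(rep(as.numeric(dy) / cache[1], each = cache[1]), dim = cache)
}

dense_forward <- function(h, W, b) {
  # h: (C, B); W: (C, K); returns scores (B, K)
  list(y = sweep(crossprod(h, W), 2, b, "+"), cache = list(h = h, W = W))
}
dense_backward <- function(cache, dy) {
  list(dW = cache$h %*% dy, db = colSums(dy), dh = cache$W %*% t(dy))
}

softmax_xent <- function(scores, labels) {
  # scores: (B, K); labels: integer class index in 1..K
  B <- nrow(scores)
  z <- scores - apply(scores, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(B), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, probs = p, dscores = dscores / B)
}
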