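# -- small neural-net primitives shared by the encoder ------------------------
# Each op comes as a forward (returning output + cache) and a backward
# (consuming the cache); gradients are verified by finite differences in the
# test suite.

LN_EPS <- 1e-6

layernorm_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  Xh <- Xc * inv
  out <- Xh * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(out = out, cache = list(Xh = Xh, inv = inv))
}

layernorm_backward <- function(dout, g, cache) {
  Xh <- cache$Xh; inv <- cache$inv
  n <- ncol(Xh)
  dXh <- dout * rep(g, each = nrow(Xh))
  dX <- (dXh - rowMeans(dXh) - Xh * rowMeans(dXh * Xh)) * inv
  list(dX = dX, dg = colSums(dout * Xh), db = colSums(dout))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

linear_forward <- function(X, W, b) X %*% W + rep(b, each = nrow(X))
linear_backward <- function(dout, X, W) {
  list(dX = dout %*% t(W), dW = t(X) %*% dout, db = colSums(dout))
}

# inverted dropout; mask cached for backward
dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate), nrow(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}
dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# residual-branch drop (drop path): the whole branch is zeroed with
# probability `rate` during training and compensated by 1/(1-rate)
drop_path_scale <- function(rate, training) {
  if (!training || rate <= 0) return(1)
  if (stats::runif(1) < rate) 0 else 1 / (1 - rate)
}

# adaptive average pooling matrix mapping a length-`len` vector to `out_len`
# segment means (torch-style segment boundaries)
adaptive_pool_matrix <- function(len, out_len) {
  P <- matrix(0, out_len, len)
  for (i in seq_len(out_len)) {
    lo <- floor((i - 1) * len / out_len) + 1L
    hi <- ceiling(i * len / out_len)
    P[i, lo:hi] <- 1 / (hi - lo + 1L)
  }
  P
}

#' Feed-forward block with an inner residual shortcut
#'
#' The transformer feed-forward sub-layer used here is
#' `inner(x) + x` with `inner = Linear(d -> 4d) -> GELU -> Dropout ->
#' Linear(4d -> d) -> Dropout`. The inner shortcut is *additional* to the
#' encoder-level residual around the whole sub-layer; it counters the
#' degradation the plain feed-forward block shows on hard-to-separate
#' lesion features by keeping an identity path inside the block itself.
#'
#' @param x `n x embed_dim` activation matrix.
#' @param mlp List with weights `W1` (`d x hidden`), `b1`, `W2`
#'   (`hidden x d`), `b2`.
#' @param dropout Dropout rate applied inside the block when
#'   `training = TRUE`.
#' @param training Logical; dropout is identity when `FALSE`.
#' @return `n x embed_dim` matrix, `inner(x) + x`.
#' @export
residual_mlp <- function(x, mlp, dropout = 0, training = FALSE) {
  residual_mlp_forward(x, mlp, dropout, training)$out
}

residual_mlp_forward <- function(x, mlp, dropout = 0, training = FALSE) {
  h1 <- linear_forward(x, mlp$W1, mlp$b1)
  a1 <- gelu(h1)
  d1 <- dropout_forward(a1, dropout, training)
  h2 <- linear_forward(d1$out, mlp$W2, mlp$b2)
  d2 <- dropout_forward(h2, dropout, training)
  list(out = d2$out + x,
       cache = list(x = x, h1 = h1, a1 = d1$out, m1 = d1$mask, m2 = d2$mask))
}

residual_mlp_backward <- function(dout, mlp, cache) {
  dh2 <- dropout_backward(dout, cache$m2)
  l2 <- linear_backward(dh2, cache$a1, mlp$W2)
  da1 <- dropout_backward(l2$dX, cache$m1)
  dh1 <- da1 * gelu_grad(cache$h1)
  l1 <- linear_backward(dh1, cache$x, mlp$W1)
  list(dX = l1$dX + dout,   # inner shortcut passes the gradient through
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}
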