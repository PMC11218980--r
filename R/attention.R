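#' Clip a relative offset
#'
#' Clamps a signed token offset to `[-k, k]`, so that all pairs further apart
#' than `k` along an axis share one encoding bucket. This bounds the number
#' of learnable relative-position parameters irrespective of sequence length.
#'
#' @param delta Signed offset(s); vectorized.
#' @param k Clip bound, >= 1.
#' @return Clamped offset(s).
#' @export
clip_offset <- function(delta, k) {
  if (k < 1) stop("clip bound k must be >= 1", call. = FALSE)
  pmax(-k, pmin(k, delta))
}

#' Relative-position bucket of a token pair
#'
#' Maps the clipped 2-D offset between two grid positions to a bucket id in
#' `[0, (2k+1)^2]`: spatial pairs use the row-major index
#' `(clip(drow)+k) * (2k+1) + (clip(dcol)+k)`, and any pair involving the
#' class token falls in the reserved last bucket `(2k+1)^2`. The id depends
#' only on the offset, so the encoding is translation-invariant.
#'
#' @param pos_i,pos_j Length-2 `(row, col)` positions, or the string `"cls"`
#'   for the class token.
#' @param k Clip bound.
#' @param grid Optional `(rows, cols)`; when given, positions are checked to
#'   lie on the grid.
#' @return Integer bucket id (0-based).
#' @export
bucket_index <- function(pos_i, pos_j, k, grid = NULL) {
  is_cls <- function(p) identical(p, "cls")
  side <- 2L * k + 1L
  if (is_cls(pos_i) || is_cls(pos_j)) return(side * side)
  for (p in list(pos_i, pos_j)) {
    if (!is.numeric(p) || length(p) != 2) {
      stop("positions must be (row, col) pairs or \"cls\"", call. = FALSE)
    }
    if (!is.null(grid) && (p[1] < 1 || p[1] > grid[1] || p[2] < 1 || p[2] > grid[2])) {
      stop("position (", p[1], ", ", p[2], ") off the ", grid[1], "x", grid[2],
           " grid", call. = FALSE)
    }
  }
  dr <- clip_offset(pos_i[1] - pos_j[1], k)
  dc <- clip_offset(pos_i[2] - pos_j[2], k)
  as.integer((dr + k) * side + (dc + k))
}

#' Token sequence container
#'
#' @param values `n_tokens x embed_dim` activation matrix; when a class token
#'   is present it occupies row 1, followed by the spatial tokens in
#'   row-major grid order.
#' @param grid `(rows, cols)` of the spatial token layout.
#' @param has_class_token Whether row 1 is the class token.
#' @return An object of class `token_sequence`.
#' @export
token_sequence <- function(values, grid, has_class_token = TRUE) {
  expected <- prod(grid) + as.integer(has_class_token)
  if (nrow(values) != expected) {
    stop("token count ", nrow(values), " does not match grid ",
         grid[1], "x", grid[2],
         if (has_class_token) " + class token" else "", call. = FALSE)
  }
  structure(list(values = values, grid = as.integer(grid),
                 has_class_token = isTRUE(has_class_token)),
            class = "token_sequence")
}

# token positions in sequence order: "cls" then (row, col) row-major
token_positions <- function(grid, has_class_token = TRUE) {
  pos <- list()
  if (has_class_token) pos <- list("cls")
  for (r in seq_len(grid[1])) for (c in seq_len(grid[2])) {
    pos[[length(pos) + 1L]] <- c(r, c)
  }
  pos
}

# precomputed bucket geometry for a token layout: 1-based bucket matrix,
# linear gather indices, and per-bucket 0/1 masks for aggregation
bucket_map <- function(grid, k, has_class_token = TRUE) {
  side <- 2L * k + 1L
  nb <- side * side + 1L
  pos <- token_positions(grid, has_class_token)
  n <- length(pos)
  B <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    B[i, j] <- bucket_index(pos[[i]], pos[[j]], k)
  }
  B1 <- B + 1L
  masks <- lapply(seq_len(nb), function(b) (B1 == b) * 1)
  list(n = n, n_buckets = nb, B1 = B1,
       idx_i = as.vector(row(B1)) + (as.vector(B1) - 1L) * n,
       idx_j = as.vector(col(B1)) + (as.vector(B1) - 1L) * n,
       masks = masks)
}

# n x n_buckets aggregation of an n x n matrix over buckets, per row / col
bucket_rowsums <- function(M, bm) {
  vapply(bm$masks, function(msk) rowSums(M * msk), numeric(nrow(M)))
}
bucket_colsums <- function(M, bm) {
  vapply(bm$masks, function(msk) colSums(M * msk), numeric(ncol(M)))
}

#' Learnable relative-position tables
#'
#' Per head: a scalar logit bias per bucket and three `head_dim` vectors per
#' bucket that are added to the projected query, key and value of a pair
#' before their interaction. `n_buckets = (2k+1)^2 + 1`, the last bucket
#' reserved for pairs involving the class token. Zero initialization makes
#' attention start exactly at its plain scaled-dot-product reduction.
#'
#' @param n_heads Number of heads.
#' @param head_dim Per-head channel count.
#' @param clip_k Clip bound of the offset.
#' @param init `"zeros"` (default) or `"normal"` (sd 0.02).
#' @return A list of `n_heads` table sets (`bias`, `pq`, `pk`, `pv`), with
#'   attribute `clip_k`.
#' @export
rpe_tables <- function(n_heads, head_dim, clip_k, init = c("zeros", "normal")) {
  init <- match.arg(init)
  nb <- (2L * clip_k + 1L)^2 + 1L
  draw <- function(n) {
    if (init == "zeros") rep(0, n) else stats::rnorm(n, sd = 0.02)
  }
  tabs <- lapply(seq_len(n_heads), function(h) {
    list(bias = draw(nb),
         pq = matrix(draw(nb * head_dim), nb, head_dim),
         pk = matrix(draw(nb * head_dim), nb, head_dim),
         pv = matrix(draw(nb * head_dim), nb, head_dim))
  })
  attr(tabs, "clip_k") <- as.integer(clip_k)
  tabs
}

#' Multi-head attention parameters
#'
#' Query/key/value projections, output projection and the relative-offset
#' clip bound.
#'
#' @param embed_dim Embedding width; must be divisible by `n_heads`.
#' @param n_heads Number of heads.
#' @param clip_k Clip bound for the relative-position buckets.
#' @param init `"normal"` (truncated-normal sd 0.02, default) or `"zeros"`.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(embed_dim, n_heads, clip_k = 7L,
                             init = c("normal", "zeros")) {
  init <- match.arg(init)
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim (", embed_dim, ") not divisible by n_heads (", n_heads, ")",
         call. = FALSE)
  }
  if (clip_k < 1) stop("clip_k must be >= 1", call. = FALSE)
  w <- function() {
    if (init == "zeros") matrix(0, embed_dim, embed_dim)
    else matrix(trunc_normal(embed_dim * embed_dim, sd = 0.02), embed_dim, embed_dim)
  }
  structure(list(embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 head_dim = embed_dim %/% n_heads, clip_k = as.integer(clip_k),
                 Wq = w(), Wk = w(), Wv = w(), Wo = w(),
                 bq = rep(0, embed_dim), bk = rep(0, embed_dim),
                 bv = rep(0, embed_dim), bo = rep(0, embed_dim)),
            class = "attention_params")
}

# truncated normal at +-2 sd, the usual transformer projection init
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  while (any(bad <- abs(x) > 2 * sd)) x[bad] <- stats::rnorm(sum(bad), sd = sd)
  x
}

#' Pairwise attention logit with relative encodings
#'
#' The per-pair logit
#' `e_ij = ((q_i + p^Q_b) . (k_j + p^K_b) + bias_b) / sqrt(d_z)` with
#' `d_z` the per-head channel count. With all tables zero this is the plain
#' scaled dot product.
#'
#' @param q_i,k_j Projected query / key vectors of length `head_dim`.
#' @param tables_head One head's table set from [rpe_tables()].
#' @param bucket Bucket id (0-based) of the pair.
#' @return Scalar logit.
#' @export
attention_logits <- function(q_i, k_j, tables_head, bucket) {
  nb <- length(tables_head$bias)
  if (bucket < 0 || bucket >= nb) {
    stop("bucket id ", bucket, " out of range [0, ", nb, ")", call. = FALSE)
  }
  b <- bucket + 1L
  d_z <- length(q_i)
  (sum((q_i + tables_head$pq[b, ]) * (k_j + tables_head$pk[b, ])) +
      tables_head$bias[b]) / sqrt(d_z)
}

#' Row-wise softmax attention weights
#'
#' Numerically stable (max-subtracted) softmax over each row of a logit
#' matrix; every row sums to 1.
#'
#' @param logits Numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape with non-negative rows summing to 1.
#' @export
attention_weights <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Attention output with relative value encodings
#'
#' `z_i = sum_j alpha_ij (v_j + p^V_{b(i,j)})`.
#'
#' @param weights Row-normalized attention matrix (`n x n`).
#' @param values Projected value matrix (`n x head_dim`).
#' @param tables_head One head's table set.
#' @param buckets `n x n` bucket-id matrix (0-based).
#' @return `n x head_dim` output matrix.
#' @export
attention_output <- function(weights, values, tables_head, buckets) {
  n <- nrow(values)
  if (!all(dim(weights) == c(n, n)) || !all(dim(buckets) == c(n, n))) {
    stop("weights / buckets must be n x n with n = nrow(values)", call. = FALSE)
  }
  out <- weights %*% values
  pv <- tables_head$pv
  for (i in seq_len(n)) {
    out[i, ] <- out[i, ] + colSums(weights[i, ] * pv[buckets[i, ] + 1L, , drop = FALSE])
  }
  out
}

# vectorized per-head forward; returns output and the cache backward needs
attn_head_forward <- function(Qh, Kh, Vh, tab, bm) {
  n <- nrow(Qh); hd <- ncol(Qh)
  QPK <- Qh %*% t(tab$pk)
  KPQ <- Kh %*% t(tab$pq)
  cst <- rowSums(tab$pq * tab$pk) + tab$bias
  E <- (Qh %*% t(Kh) +
          matrix(QPK[bm$idx_i], n, n) +
          matrix(KPQ[bm$idx_j], n, n) +
          matrix(cst[bm$B1], n, n)) / sqrt(hd)
  A <- attention_weights(E)
  W <- bucket_rowsums(A, bm)
  Z <- A %*% Vh + W %*% tab$pv
  list(Z = Z, A = A, W = W)
}

attn_head_backward <- function(dZ, Qh, Kh, Vh, tab, bm, cache) {
  A <- cache$A; W <- cache$W
  n <- nrow(A); hd <- ncol(Qh)
  dV <- t(A) %*% dZ
  dpv <- t(W) %*% dZ
  PVd <- dZ %*% t(tab$pv)
  dA <- dZ %*% t(Vh) + matrix(PVd[bm$idx_i], n, n)
  dE <- (A * (dA - rowSums(dA * A))) / sqrt(hd)
  G <- bucket_rowsums(dE, bm)
  Gt <- bucket_colsums(dE, bm)
  S <- colSums(G)
  list(dQ = dE %*% Kh + G %*% tab$pk,
       dK = t(dE) %*% Qh + Gt %*% tab$pq,
       dV = dV,
       dpq = t(Gt) %*% Kh + S * tab$pk,
       dpk = t(G) %*% Qh + S * tab$pq,
       dpv = dpv,
       dbias = S)
}

# full multi-head forward on a token matrix X (n x d); bm from bucket_map()
mha_forward <- function(X, params, tables, bm) {
  d <- params$embed_dim; nh <- params$n_heads; hd <- params$head_dim
  Q <- X %*% params$Wq + rep(params$bq, each = nrow(X))
  K <- X %*% params$Wk + rep(params$bk, each = nrow(X))
  V <- X %*% params$Wv + rep(params$bv, each = nrow(X))
  Z <- matrix(0, nrow(X), d)
  caches <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    fh <- attn_head_forward(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                            V[, cols, drop = FALSE], tables[[h]], bm)
    Z[, cols] <- fh$Z
    caches[[h]] <- fh[c("A", "W")]
  }
  out <- Z %*% params$Wo + rep(params$bo, each = nrow(X))
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, Z = Z, heads = caches))
}

mha_backward <- function(dout, params, tables, bm, cache) {
  nh <- params$n_heads; hd <- params$head_dim
  X <- cache$X
  dZ <- dout %*% t(params$Wo)
  g <- list(Wo = t(cache$Z) %*% dout, bo = colSums(dout),
            Wq = 0, Wk = 0, Wv = 0, tables = vector("list", nh))
  dQ <- dK <- dV <- matrix(0, nrow(X), params$embed_dim)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    bh <- attn_head_backward(dZ[, cols, drop = FALSE],
                             cache$Q[, cols, drop = FALSE],
                             cache$K[, cols, drop = FALSE],
                             cache$V[, cols, drop = FALSE],
                             tables[[h]], bm, cache$heads[[h]])
    dQ[, cols] <- bh$dQ; dK[, cols] <- bh$dK; dV[, cols] <- bh$dV
    g$tables[[h]] <- list(bias = bh$dbias, pq = bh$dpq, pk = bh$dpk, pv = bh$dpv)
  }
  g$Wq <- t(X) %*% dQ; g$bq <- colSums(dQ)
  g$Wk <- t(X) %*% dK; g$bk <- colSums(dK)
  g$Wv <- t(X) %*% dV; g$bv <- colSums(dV)
  dX <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  list(dX = dX, grads = g)
}

#' Multi-head self-attention with clipped 2-D relative position encoding
#'
#' Runs every head's relative-position attention over a token sequence,
#' concatenates the head outputs and applies the output projection. All
#' heads share the bucket geometry; biases and encoding vectors are
#' per-head. The encodings enter pre-softmax only (and the value side of the
#' weighted sum), never the input embeddings.
#'
#' @param seq A [token_sequence()].
#' @param params An [attention_params()] object.
#' @param tables [rpe_tables()] for `params$n_heads` heads.
#' @return A [token_sequence()] of the same shape.
#' @export
multi_head_irpe <- function(seq, params, tables) {
  stopifnot(inherits(seq, "token_sequence"), inherits(params, "attention_params"))
  bm <- bucket_map(seq$grid, params$clip_k, seq$has_class_token)
  out <- mha_forward(seq$values, params, tables, bm)$out
  token_sequence(out, seq$grid, seq$has_class_token)
}

#' Literal double-loop reference of iRPE attention
#'
#' Computes the same quantity as [multi_head_irpe()] by looping over every
#' token pair and head with the scalar defining equations
#' (pairwise logit, softmax weight, encoded value sum). Quadratic and slow;
#' kept as an independent check of the vectorized path.
#'
#' @inheritParams multi_head_irpe
#' @return A [token_sequence()] of the same shape.
#' @export
irpe_attention_naive <- function(seq, params, tables) {
  X <- seq$values
  n <- nrow(X); nh <- params$n_heads; hd <- params$head_dim
  pos <- token_positions(seq$grid, seq$has_class_token)
  Q <- X %*% params$Wq + rep(params$bq, each = n)
  K <- X %*% params$Wk + rep(params$bk, each = n)
  V <- X %*% params$Wv + rep(params$bv, each = n)
  Z <- matrix(0, n, params$embed_dim)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    tab <- tables[[h]]
    for (i in seq_len(n)) {
      e <- numeric(n)
      for (j in seq_len(n)) {
        b <- bucket_index(pos[[i]], pos[[j]], params$clip_k)
        e[j] <- attention_logits(Q[i, cols], K[j, cols], tab, b)
      }
      alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
      zi <- rep(0, hd)
      for (j in seq_len(n)) {
        b <- bucket_index(pos[[i]], pos[[j]], params$clip_k)
        zi <- zi + alpha[j] * (V[j, cols] + tab$pv[b + 1L, ])
      }
      Z[i, cols] <- zi
    }
  }
  out <- Z %*% params$Wo + rep(params$bo, each = n)
  token_sequence(out, seq$grid, seq$has_class_token)
}
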