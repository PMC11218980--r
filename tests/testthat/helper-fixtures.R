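# shared fixtures: tiny configurations and deterministic random inputs

# smallest model that exercises every architectural piece
micro_config <- function(...) {
  vit_config_tiny(image_size = 16L, patch_size = 8L, embed_dim = 8L,
                  depth = 1L, n_heads = 2L, clip_k = 1L, pooled_dim = 4L, ...)
}

# seeded random token sequence on an r x c grid (+ class token)
random_sequence <- function(seed, grid = c(3L, 3L), embed_dim = 16L) {
  set.seed(seed)
  n <- prod(grid) + 1L
  token_sequence(matrix(rnorm(n * embed_dim), n, embed_dim), grid, TRUE)
}

# seeded attention parameters + non-zero tables
random_attention <- function(seed, embed_dim = 16L, n_heads = 4L, clip_k = 1L) {
  set.seed(seed)
  params <- attention_params(embed_dim, n_heads, clip_k, init = "normal")
  tables <- rpe_tables(n_heads, embed_dim %/% n_heads, clip_k, init = "normal")
  list(params = params, tables = tables)
}

# plain multi-head scaled-dot-product attention, written independently of the
# package's vectorized path (reference for the zero-table reduction)
plain_mha <- function(X, params) {
  n <- nrow(X)
  hd <- params$head_dim
  Q <- X %*% params$Wq + rep(params$bq, each = n)
  K <- X %*% params$Wk + rep(params$bk, each = n)
  V <- X %*% params$Wv + rep(params$bv, each = n)
  Z <- matrix(0, n, params$embed_dim)
  for (h in seq_len(params$n_heads)) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    logits <- Q[, cols] %*% t(K[, cols]) / sqrt(hd)
    A <- exp(logits - apply(logits, 1, max))
    A <- A / rowSums(A)
    Z[, cols] <- A %*% V[, cols]
  }
  Z %*% params$Wo + rep(params$bo, each = n)
}

# class-folder tree of tiny images for manifest tests
write_fixture_tree <- function(root, n_per_class = 3L, side = 8L, seed = 1L) {
  set.seed(seed)
  for (cl in tumor_classes()) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      write_gray(matrix(runif(side * side, 0, 255), side, side),
                 file.path(root, cl, sprintf("%s_%d.png", cl, i)))
    }
  }
  root
}

paper_class_counts <- c(glioma = 1621L, meningioma = 1645L,
                        pituitary = 1757L, no_tumor = 2000L)
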