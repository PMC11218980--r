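#' Model configuration
#'
#' Hyperparameters of the modified ViT-B/16. The defaults are the full-size
#' network: 224-pixel inputs cut into 16-pixel patches (a 14 x 14 token grid
#' plus a class token), 12 encoder blocks of width 768 with 12 heads, a
#' feed-forward expansion of 4, clipped 2-D relative position encodings with
#' bound 7, and an adaptive-average-pooling tanh head of width 256 over 4
#' classes. Absolute position embeddings are off by default (the relative
#' encodings are the position mechanism) but can be switched back on.
#'
#' @param image_size,patch_size Input side length and patch side length
#'   (pixels); `image_size` must be divisible by `patch_size`.
#' @param embed_dim,depth,n_heads Encoder width, number of blocks, heads.
#' @param mlp_ratio Feed-forward expansion factor (hidden width =
#'   `mlp_ratio * embed_dim`).
#' @param n_classes Output classes (default 4).
#' @param dropout,drop_path Regularization rates in `[0, 1)`; both are
#'   identity at evaluation time.
#' @param clip_k Relative-offset clip bound.
#' @param pooled_dim Channel count after the head's adaptive average pooling.
#' @param use_abs_pos Additionally learn absolute position embeddings.
#' @return An object of class `vit_config`.
#' @export
vit_config <- function(image_size = 224L, patch_size = 16L, embed_dim = 768L,
                       depth = 12L, n_heads = 12L, mlp_ratio = 4L,
                       n_classes = 4L, dropout = 0.1, drop_path = 0.1,
                       clip_k = 7L, pooled_dim = 256L, use_abs_pos = FALSE) {
  if (image_size %% patch_size != 0) {
    stop("image_size must be divisible by patch_size", call. = FALSE)
  }
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  if (mlp_ratio < 1) stop("mlp_ratio must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1 || drop_path < 0 || drop_path >= 1) {
    stop("dropout / drop_path rates must lie in [0, 1)", call. = FALSE)
  }
  grid <- as.integer(image_size %/% patch_size)
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 n_heads = as.integer(n_heads), mlp_ratio = as.integer(mlp_ratio),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 drop_path = drop_path, clip_k = as.integer(clip_k),
                 pooled_dim = as.integer(pooled_dim),
                 use_abs_pos = isTRUE(use_abs_pos),
                 grid = c(grid, grid), n_tokens = grid * grid + 1L),
            class = "vit_config")
}

#' Reduced configuration for desk-scale experiments
#'
#' A small variant of the network (64-pixel inputs, 8-pixel patches, width
#' 32, 2 blocks, 4 heads, clip bound 3, pooling width 32, no dropout) that a
#' single CPU can train in minutes while exercising every architectural
#' component. Used throughout the tests and the phantom training runs.
#'
#' @param ... Overrides passed to [vit_config()].
#' @return A `vit_config`.
#' @export
vit_config_tiny <- function(...) {
  args <- utils::modifyList(list(image_size = 64L, patch_size = 8L,
                                 embed_dim = 32L, depth = 2L, n_heads = 4L,
                                 mlp_ratio = 4L, n_classes = 4L, dropout = 0,
                                 drop_path = 0, clip_k = 3L, pooled_dim = 32L),
                            list(...))
  do.call(vit_config, args)
}

#' Initialize a model
#'
#' Builds the full parameter set: truncated-normal (sd 0.02) projections,
#' zero biases, unit layer-norm gains, and zero relative-position tables, so
#' the untrained network starts exactly at its plain-attention reduction
#' point. The bucket geometry and the head's pooling matrix are precomputed
#' and stored with the model.
#'
#' @param cfg A [vit_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `vit_model`.
#' @export
vit_model <- function(cfg = vit_config(), seed = 1L) {
  stopifnot(inherits(cfg, "vit_config"))
  d <- cfg$embed_dim
  with_seed(seed, {
    ln <- function() list(g = rep(1, d), b = rep(0, d))
    blocks <- lapply(seq_len(cfg$depth), function(l) {
      list(ln1 = ln(),
           attn = attention_params(d, cfg$n_heads, cfg$clip_k, init = "normal"),
           tables = rpe_tables(cfg$n_heads, d %/% cfg$n_heads, cfg$clip_k,
                               init = "zeros"),
           ln2 = ln(),
           mlp = list(W1 = matrix(trunc_normal(d * cfg$mlp_ratio * d), d,
                                  cfg$mlp_ratio * d),
                      b1 = rep(0, cfg$mlp_ratio * d),
                      W2 = matrix(trunc_normal(cfg$mlp_ratio * d * d),
                                  cfg$mlp_ratio * d, d),
                      b2 = rep(0, d)))
    })
    patch_dim <- cfg$patch_size^2
    params <- list(
      patch = list(W = matrix(trunc_normal(patch_dim * d), patch_dim, d),
                   b = rep(0, d)),
      cls = trunc_normal(d),
      blocks = blocks,
      ln_f = ln(),
      # Glorot scaling for the tanh head: two stacked sd-0.02 layers would
      # attenuate the backbone's gradient by ~0.02^2 and stall early training
      head = list(W1 = matrix(stats::rnorm(cfg$pooled_dim^2,
                                           sd = sqrt(1 / cfg$pooled_dim)),
                              cfg$pooled_dim, cfg$pooled_dim),
                  b1 = rep(0, cfg$pooled_dim),
                  W2 = matrix(stats::rnorm(cfg$pooled_dim * cfg$n_classes,
                                           sd = sqrt(1 / cfg$pooled_dim)),
                              cfg$pooled_dim, cfg$n_classes),
                  b2 = rep(0, cfg$n_classes)))
    if (cfg$use_abs_pos) {
      params$abs_pos <- matrix(trunc_normal(cfg$n_tokens * d), cfg$n_tokens, d)
    }
    structure(list(cfg = cfg, params = params,
                   bm = bucket_map(cfg$grid, cfg$clip_k, TRUE),
                   pool = adaptive_pool_matrix(d, cfg$pooled_dim)),
              class = "vit_model")
  })
}

#' Cut an image into flattened patches
#'
#' Non-overlapping `patch_size x patch_size` patches in row-major grid
#' order, each flattened column-major. [unpatchify()] inverts the operation
#' exactly.
#'
#' @param img Numeric matrix whose sides are divisible by `patch_size`.
#' @param patch_size Patch side length.
#' @return `n_patches x patch_size^2` matrix.
#' @export
patchify <- function(img, patch_size) {
  if (nrow(img) %% patch_size != 0 || ncol(img) %% patch_size != 0) {
    stop("image sides (", nrow(img), "x", ncol(img),
         ") not divisible by patch size ", patch_size, call. = FALSE)
  }
  gr <- nrow(img) %/% patch_size
  gc <- ncol(img) %/% patch_size
  out <- matrix(0, gr * gc, patch_size^2)
  idx <- 1L
  for (r in seq_len(gr)) {
    rows <- ((r - 1L) * patch_size + 1L):(r * patch_size)
    for (c in seq_len(gc)) {
      cols <- ((c - 1L) * patch_size + 1L):(c * patch_size)
      out[idx, ] <- as.vector(img[rows, cols])
      idx <- idx + 1L
    }
  }
  out
}

#' @rdname patchify
#' @param patches Matrix produced by [patchify()].
#' @param grid `(rows, cols)` of the patch grid.
#' @export
unpatchify <- function(patches, patch_size, grid) {
  img <- matrix(0, grid[1] * patch_size, grid[2] * patch_size)
  idx <- 1L
  for (r in seq_len(grid[1])) {
    rows <- ((r - 1L) * patch_size + 1L):(r * patch_size)
    for (c in seq_len(grid[2])) {
      cols <- ((c - 1L) * patch_size + 1L):(c * patch_size)
      img[rows, cols] <- matrix(patches[idx, ], patch_size, patch_size)
      idx <- idx + 1L
    }
  }
  img
}

#' Patch embedding of an image
#'
#' Flattens the image's non-overlapping patches, projects them to
#' `embed_dim`, and prepends the learnable class token (plus absolute
#' position embeddings when configured).
#'
#' @param img Numeric matrix of side `cfg$image_size`.
#' @param model A [vit_model()].
#' @return A [token_sequence()] with `grid^2 + 1` tokens.
#' @export
patchify_embed <- function(img, model) {
  cfg <- model$cfg
  if (nrow(img) != cfg$image_size || ncol(img) != cfg$image_size) {
    stop("image is ", nrow(img), "x", ncol(img), " but the model expects ",
         cfg$image_size, "x", cfg$image_size, call. = FALSE)
  }
  P <- patchify(img, cfg$patch_size)
  tok <- linear_forward(P, model$params$patch$W, model$params$patch$b)
  X <- rbind(model$params$cls, tok)
  if (cfg$use_abs_pos) X <- X + model$params$abs_pos
  token_sequence(X, cfg$grid, has_class_token = TRUE)
}

#' One encoder block
#'
#' `x + drop_path(attention(norm1(x)))`, then
#' `x + drop_path(residual_mlp(norm2(x)))`; at evaluation time drop path and
#' dropout are identities.
#'
#' @param seq A [token_sequence()].
#' @param block One element of `model$params$blocks`.
#' @param bm Bucket geometry from [bucket_map()] (precomputed in the model).
#' @param dropout,drop_path Rates used when `training = TRUE`.
#' @param training Logical.
#' @return A [token_sequence()] of the same shape.
#' @export
encoder_block <- function(seq, block, bm, dropout = 0, drop_path = 0,
                          training = FALSE) {
  out <- encoder_block_forward(seq$values, block, bm, dropout, drop_path, training)
  token_sequence(out$X, seq$grid, seq$has_class_token)
}

encoder_block_forward <- function(X, block, bm, dropout, drop_path, training,
                                  keep_attn = FALSE) {
  ln1 <- layernorm_forward(X, block$ln1$g, block$ln1$b)
  at <- mha_forward(ln1$out, block$attn, block$tables, bm)
  ad <- dropout_forward(at$out, dropout, training)
  s1 <- drop_path_scale(drop_path, training)
  X1 <- X + s1 * ad$out
  ln2 <- layernorm_forward(X1, block$ln2$g, block$ln2$b)
  mf <- residual_mlp_forward(ln2$out, block$mlp, dropout, training)
  s2 <- drop_path_scale(drop_path, training)
  Xo <- X1 + s2 * mf$out
  list(X = Xo,
       cache = list(X = X, ln1 = ln1$cache, attn = at$cache, amask = ad$mask,
                    s1 = s1, X1 = X1, ln2 = ln2$cache, mlp = mf$cache, s2 = s2),
       attn_weights = if (keep_attn) lapply(at$cache$heads, `[[`, "A") else NULL)
}

encoder_block_backward <- function(dX, block, bm, cache) {
  mb <- residual_mlp_backward(cache$s2 * dX, block$mlp, cache$mlp)
  l2 <- layernorm_backward(mb$dX, block$ln2$g, cache$ln2)
  dX1 <- dX + l2$dX
  da <- dropout_backward(cache$s1 * dX1, cache$amask)
  ab <- mha_backward(da, block$attn, block$tables, bm, cache$attn)
  l1 <- layernorm_backward(ab$dX, block$ln1$g, cache$ln1)
  list(dX = dX1 + l1$dX,
       grads = list(ln1 = list(g = l1$dg, b = l1$db),
                    attn = ab$grads[c("Wq", "Wk", "Wv", "Wo",
                                      "bq", "bk", "bv", "bo")],
                    tables = ab$grads$tables,
                    ln2 = list(g = l2$dg, b = l2$db),
                    mlp = mb$grads))
}

#' Classification head
#'
#' Adaptive average pooling of the class-token vector to `pooled_dim`
#' channels, a linear layer, `tanh`, and a final linear layer to the class
#' scores. Scores are unnormalized; softmax lives in the loss / inference
#' wrapper.
#'
#' @param seq Encoder output [token_sequence()].
#' @param model A [vit_model()].
#' @return Numeric vector of `n_classes` scores.
#' @export
classify_head <- function(seq, model) {
  head_forward(seq$values[1, ], model)$scores
}

head_forward <- function(clsv, model) {
  pooled <- matrix(model$pool %*% clsv, 1)
  h1 <- linear_forward(pooled, model$params$head$W1, model$params$head$b1)
  a <- tanh(h1)
  scores <- linear_forward(a, model$params$head$W2, model$params$head$b2)
  list(scores = as.vector(scores), cache = list(pooled = pooled, h1 = h1, a = a))
}

head_backward <- function(dscores, model, cache) {
  l2 <- linear_backward(matrix(dscores, 1), cache$a, model$params$head$W2)
  dh1 <- l2$dX * (1 - cache$a^2)
  l1 <- linear_backward(dh1, cache$pooled, model$params$head$W1)
  dcls <- as.vector(t(model$pool) %*% as.vector(l1$dX))
  list(dcls = dcls,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

# full forward on one image; returns scores + cache (+ per-block attention)
vit_forward_one <- function(model, img, training = FALSE, keep_attn = FALSE) {
  cfg <- model$cfg
  P <- patchify(img, cfg$patch_size)
  tok <- linear_forward(P, model$params$patch$W, model$params$patch$b)
  X <- rbind(model$params$cls, tok)
  if (cfg$use_abs_pos) X <- X + model$params$abs_pos
  block_caches <- vector("list", cfg$depth)
  attn <- if (keep_attn) vector("list", cfg$depth) else NULL
  for (l in seq_len(cfg$depth)) {
    fb <- encoder_block_forward(X, model$params$blocks[[l]], model$bm,
                                cfg$dropout, cfg$drop_path, training, keep_attn)
    X <- fb$X
    block_caches[[l]] <- fb$cache
    if (keep_attn) attn[[l]] <- fb$attn_weights
  }
  lnf <- layernorm_forward(X, model$params$ln_f$g, model$params$ln_f$b)
  hf <- head_forward(lnf$out[1, ], model)
  list(scores = hf$scores,
       cache = list(P = P, blocks = block_caches, lnf = lnf$cache,
                    Xf = X, head = hf$cache),
       attn = attn)
}

vit_backward_one <- function(model, cache, dscores) {
  cfg <- model$cfg
  hb <- head_backward(dscores, model, cache$head)
  dLN <- matrix(0, cfg$n_tokens, cfg$embed_dim)
  dLN[1, ] <- hb$dcls
  lf <- layernorm_backward(dLN, model$params$ln_f$g, cache$lnf)
  dX <- lf$dX
  block_grads <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    bb <- encoder_block_backward(dX, model$params$blocks[[l]], model$bm,
                                 cache$blocks[[l]])
    dX <- bb$dX
    block_grads[[l]] <- bb$grads
  }
  grads <- list(patch = list(W = t(cache$P) %*% dX[-1, , drop = FALSE],
                             b = colSums(dX[-1, , drop = FALSE])),
                cls = dX[1, ],
                blocks = block_grads,
                ln_f = list(g = lf$dg, b = lf$db),
                head = hb$grads)
  if (cfg$use_abs_pos) grads$abs_pos <- dX
  grads
}

#' Class scores / predictions for a batch of images
#'
#' @param object A [vit_model()].
#' @param x Array `n x size x size` (as from [load_batch()]) or a single
#'   image matrix.
#' @param type `"score"` (default), `"prob"` (softmax) or `"class"`
#'   (1-based argmax index).
#' @param ... Unused.
#' @return Matrix `n x n_classes`, or an integer vector for
#'   `type = "class"`.
#' @export
predict.vit_model <- function(object, x, type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))
  n <- dim(x)[1]
  scores <- matrix(0, n, object$cfg$n_classes)
  for (i in seq_len(n)) {
    scores[i, ] <- vit_forward_one(object, x[i, , ], training = FALSE)$scores
  }
  if (type == "score") return(scores)
  probs <- attention_weights(scores)
  if (type == "prob") probs else max.col(probs, ties.method = "first")
}

#' Per-block attention maps for one image
#'
#' For every encoder block, the class-token row of the attention matrix
#' (averaged over heads, class-token self-weight excluded) reshaped to the
#' patch grid and bilinearly upsampled to the input size. Each raw row sums
#' to at most 1; with `normalize = TRUE` every map is min-max scaled to
#' `[0, 1]` for display.
#'
#' @param model A [vit_model()].
#' @param img Image matrix of the model's input size.
#' @param normalize Min-max scale each map (default `TRUE`).
#' @return List of `depth` matrices of the input size.
#' @export
attention_maps <- function(model, img, normalize = TRUE) {
  fw <- vit_forward_one(model, img, training = FALSE, keep_attn = TRUE)
  lapply(fw$attn, function(heads) {
    row <- Reduce(`+`, lapply(heads, function(A) A[1, -1])) / length(heads)
    m <- matrix(row, model$cfg$grid[1], model$cfg$grid[2], byrow = TRUE)
    m <- resize_gray(m, model$cfg$image_size, model$cfg$image_size)
    if (normalize) {
      rng <- range(m)
      if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
    }
    m
  })
}

#' Trainable parameter count
#'
#' Counts every trainable value in the model (projections, biases,
#' layer-norm gains, relative-position tables, class token, head weights).
#'
#' @param model A [vit_model()] or a [vit_config()] (a config is
#'   instantiated analytically without allocating the weights).
#' @return Integer count.
#' @export
vit_param_count <- function(model) {
  if (inherits(model, "vit_config")) {
    cfg <- model
    d <- cfg$embed_dim; hd <- d %/% cfg$n_heads
    nb <- (2 * cfg$clip_k + 1)^2 + 1
    per_block <- 2 * d +                       # ln1
      4 * (d^2 + d) +                          # q/k/v/o projections
      cfg$n_heads * nb * (1 + 3 * hd) +        # relative tables
      2 * d +                                  # ln2
      d * cfg$mlp_ratio * d + cfg$mlp_ratio * d +
      cfg$mlp_ratio * d * d + d                # feed-forward
    total <- cfg$patch_size^2 * d + d +        # patch projection
      d +                                      # class token
      cfg$depth * per_block +
      2 * d +                                  # final layer norm
      cfg$pooled_dim^2 + cfg$pooled_dim +
      cfg$pooled_dim * cfg$n_classes + cfg$n_classes
    if (cfg$use_abs_pos) total <- total + cfg$n_tokens * d
    return(total)
  }
  skip <- c("embed_dim", "n_heads", "head_dim", "clip_k")
  count <- function(x, name = "") {
    if (is.numeric(x)) return(if (name %in% skip) 0 else length(x))
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- rep("", length(x))
      return(sum(vapply(seq_along(x), function(i) count(x[[i]], nms[i]),
                        numeric(1))))
    }
    0
  }
  count(model$params)
}

#' Save / load a model checkpoint
#'
#' Weights and configuration are stored in one RDS archive with a
#' human-readable JSON sidecar (`<path>.json`) describing the configuration.
#'
#' @param model A [vit_model()] (or [vit_train()] fit, whose model is saved).
#' @param path Checkpoint path.
#' @return `path` invisibly; `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "vit_fit")) model <- model$model
  stopifnot(inherits(model, "vit_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vit_model"))
  model
}
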