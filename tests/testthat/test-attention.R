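test_that("offset clipping matches a branch-free oracle", {
  expect_identical(clip_offset(2, 3), 2)
  expect_identical(clip_offset(7, 3), 3)
  expect_identical(clip_offset(-7, 3), -3)
  for (k in 1:4) expect_identical(clip_offset(0, k), 0)

  oracle <- function(d, k) {
    if (d > k) k else if (d < -k) -k else d
  }
  set.seed(1)
  for (i in 1:50) {
    d <- sample(-20:20, 1); k <- sample(1:6, 1)
    expect_identical(clip_offset(d, k), oracle(d, k))
  }
})

test_that("bucket ids are translation-invariant and enumerate (2k+1)^2 + 1 cases", {
  k <- 2L
  expect_identical(bucket_index(c(3, 3), c(3, 3), k), k * (2L * k + 1L) + k)

  set.seed(2)
  for (i in 1:30) {
    p <- sample(1:10, 2); q <- sample(1:10, 2); s <- sample(-5:5, 2)
    expect_identical(bucket_index(p, q, k), bucket_index(p + s, q + s, k))
  }

  # k = 1: brute force over all pairs of a 3x3 grid covers 9 distinct spatial
  # buckets 0..8, plus the reserved class bucket
  ids <- integer(0)
  for (r1 in 1:3) for (c1 in 1:3) for (r2 in 1:3) for (c2 in 1:3) {
    ids <- c(ids, bucket_index(c(r1, c1), c(r2, c2), 1L))
  }
  expect_identical(sort(unique(ids)), 0:8)
  expect_identical(bucket_index("cls", c(1, 1), 1L), 9L)
  expect_identical(bucket_index(c(1, 1), "cls", 1L), 9L)
  expect_error(bucket_index(c(9, 1), c(1, 1), 1L, grid = c(3, 3)), "off the")
})

test_that("pairwise logits reduce to scaled dot product and honor the bias", {
  hd <- 4L
  tabs <- rpe_tables(1L, hd, 2L, init = "zeros")[[1]]
  set.seed(3)
  q <- rnorm(hd); k <- rnorm(hd)
  expect_equal(attention_logits(q, k, tabs, 0L), sum(q * k) / sqrt(hd),
               tolerance = 1e-12)

  tabs$bias[6] <- 2
  expect_equal(attention_logits(rep(0, hd), rep(0, hd), tabs, 5L), 1,
               tolerance = 1e-12)
  expect_error(attention_logits(q, k, tabs, 99L), "out of range")
})

test_that("softmax weights are exact on anchor cases and always normalized", {
  expect_equal(as.vector(attention_weights(rep(1.3, 5))), rep(0.2, 5))
  expect_equal(as.vector(attention_weights(7)), 1)
  expect_equal(as.vector(attention_weights(c(0, log(3)))), c(0.25, 0.75),
               tolerance = 1e-12)
  set.seed(4)
  W <- attention_weights(matrix(rnorm(64, sd = 30), 8, 8))
  expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  expect_true(all(W >= 0))
})

test_that("encoded attention output matches a double-loop oracle", {
  hd <- 4L; k <- 1L; n <- 10L
  set.seed(5)
  tabs <- rpe_tables(1L, hd, k, init = "normal")[[1]]
  V <- matrix(rnorm(n * hd), n, hd)
  B <- matrix(sample(0:9, n * n, replace = TRUE), n, n)
  A <- attention_weights(matrix(rnorm(n * n), n, n))

  out <- attention_output(A, V, tabs, B)
  oracle <- matrix(0, n, hd)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    oracle[i, ] <- oracle[i, ] + A[i, j] * (V[j, ] + tabs$pv[B[i, j] + 1L, ])
  }
  expect_lt(max(abs(out - oracle)), 1e-10)

  # zero value-encodings: plain weighted sum
  tabs$pv[] <- 0
  expect_equal(attention_output(A, V, tabs, B), A %*% V, tolerance = 1e-12)

  # single token attends to itself: v + center encoding
  tabs1 <- rpe_tables(1L, hd, k, init = "normal")[[1]]
  ctr <- k * (2L * k + 1L) + k
  v1 <- matrix(rnorm(hd), 1)
  out1 <- attention_output(matrix(1, 1, 1), v1, tabs1, matrix(ctr, 1, 1))
  expect_equal(as.vector(out1), as.vector(v1) + tabs1$pv[ctr + 1L, ],
               tolerance = 1e-12)
})

test_that("vectorized multi-head attention equals the literal-equation loop", {
  sq <- random_sequence(6)
  ra <- random_attention(7)
  fast <- multi_head_irpe(sq, ra$params, ra$tables)
  slow <- irpe_attention_naive(sq, ra$params, ra$tables)
  expect_lt(max(abs(fast$values - slow$values)), 1e-6)

  # one head is just the single-head path
  ra1 <- random_attention(8, n_heads = 1L)
  f1 <- multi_head_irpe(sq, ra1$params, ra1$tables)
  s1 <- irpe_attention_naive(sq, ra1$params, ra1$tables)
  expect_lt(max(abs(f1$values - s1$values)), 1e-6)
})

test_that("zero relative tables reduce to plain multi-head attention", {
  sq <- random_sequence(9)
  ra <- random_attention(10)
  zero_tabs <- rpe_tables(ra$params$n_heads, ra$params$head_dim,
                          ra$params$clip_k, init = "zeros")
  out <- multi_head_irpe(sq, ra$params, zero_tabs)
  expect_lt(max(abs(out$values - plain_mha(sq$values, ra$params))), 1e-6)
})

test_that("swapping two spatial tokens with their positions permutes the output", {
  ra <- random_attention(11)
  sq <- random_sequence(12)
  k <- ra$params$clip_k
  pos <- c(list("cls"),
           unlist(lapply(1:3, function(r) lapply(1:3, function(c) c(r, c))),
                  recursive = FALSE))

  # literal attention over an explicit position list, built from the exported
  # scalar primitives only
  naive_pos <- function(X, pos) {
    n <- nrow(X); hd <- ra$params$head_dim
    Q <- X %*% ra$params$Wq; K <- X %*% ra$params$Wk; V <- X %*% ra$params$Wv
    Z <- matrix(0, n, ra$params$embed_dim)
    for (h in seq_len(ra$params$n_heads)) {
      cols <- ((h - 1L) * hd + 1L):(h * hd)
      tab <- ra$tables[[h]]
      for (i in seq_len(n)) {
        e <- vapply(seq_len(n), function(j) {
          attention_logits(Q[i, cols], K[j, cols], tab,
                           bucket_index(pos[[i]], pos[[j]], k))
        }, numeric(1))
        a <- as.vector(attention_weights(e))
        for (j in seq_len(n)) {
          b <- bucket_index(pos[[i]], pos[[j]], k)
          Z[i, cols] <- Z[i, cols] + a[j] * (V[j, cols] + tab$pv[b + 1L, ])
        }
      }
    }
    Z %*% ra$params$Wo
  }

  X <- sq$values
  base <- naive_pos(X, pos)
  swap <- c(3L, 8L)  # two spatial tokens
  Xp <- X; Xp[swap, ] <- X[rev(swap), ]
  posp <- pos; posp[swap] <- pos[rev(swap)]
  perm <- naive_pos(Xp, posp)
  expected <- base; expected[swap, ] <- base[rev(swap), ]
  expect_lt(max(abs(perm - expected)), 1e-9)
})

test_that("attention parameter constructor enforces divisibility", {
  expect_error(attention_params(10, 3), "divisible")
  expect_error(attention_params(8, 2, clip_k = 0), "clip_k")
  sq <- random_sequence(13)
  expect_error(token_sequence(sq$values[-1, ], c(3, 3), TRUE), "token count")
})
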