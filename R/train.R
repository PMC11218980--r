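#' Training configuration
#'
#' The published training recipe: Adam, learning rate 0.001, batch size 8,
#' 30 epochs, categorical cross-entropy on softmax scores.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Minibatch size (default 8).
#' @param epochs Training epochs (default 30).
#' @param seed Integer seed controlling shuffling, dropout and drop path.
#' @param clip_norm Global gradient-norm ceiling per step (the usual
#'   stabilizer for transformer training at small batch sizes); `NULL`
#'   disables clipping. Default 1.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8L, epochs = 30L,
                         seed = 1L, clip_norm = 1, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 0) {
    stop("need learning_rate > 0, batch_size >= 1, epochs >= 0", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 clip_norm = clip_norm, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

tree_sq_sum <- function(g) {
  if (is.numeric(g)) return(sum(g^2))
  sum(vapply(g, tree_sq_sum, numeric(1)))
}

# softmax cross-entropy; scores B x C, y 1-based labels
softmax_ce <- function(scores, y) {
  p <- attention_weights(scores)
  idx <- cbind(seq_along(y), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dscores = d / length(y))
}

# ---- gradient-tree utilities ----------------------------------------------
# Gradient trees mirror the trainable subset of the parameter tree; the
# walkers recurse over the gradient tree so non-trainable metadata in the
# parameter objects is never touched.

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(b)) return(a + b)
  for (nm in seq_along(b)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
  a
}

tree_scale <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  for (nm in seq_along(a)) a[[nm]] <- tree_scale(a[[nm]], s)
  a
}

tree_zeros_like <- function(g) {
  if (is.numeric(g)) return(g * 0)
  lapply(g, tree_zeros_like)
}

# one Adam step; returns updated params and state (m, v trees shaped like g)
adam_step <- function(params, g, state, cfg, t) {
  upd <- function(p, g, m, v) {
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    mh <- m / (1 - cfg$beta1^t)
    vh <- v / (1 - cfg$beta2^t)
    list(p = p - cfg$learning_rate * mh / (sqrt(vh) + cfg$adam_eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.numeric(g)) return(upd(p, g, m, v))
    keys <- names(g)
    for (i in seq_along(g)) {
      key <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
      r <- walk(p[[key]], g[[i]], m[[i]], v[[i]])
      p[[key]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  walk(params, g, state$m, state$v)
}

#' Train the model
#'
#' Seeded minibatch training with Adam and categorical cross-entropy.
#' Training and test accuracy and loss are recorded after every epoch, and
#' the checkpoint with the highest test accuracy is returned (with
#' `epochs = 0` the model is returned unchanged).
#'
#' @param model A [vit_model()].
#' @param x,y Training images (array `n x size x size`) and 1-based labels.
#' @param x_test,y_test Held-out images and labels evaluated each epoch.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `vit_fit`: `model` (best checkpoint),
#'   `final_model`, `history` tibble
#'   (`epoch`, `train_loss`, `train_acc`, `test_loss`, `test_acc`),
#'   `best_epoch`, `config`.
#' @export
vit_train <- function(model, x, y, x_test, y_test, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "vit_model"), inherits(config, "train_config"))
  n <- dim(x)[1]
  if (n == 0 || length(y) != n) stop("empty or mismatched training set", call. = FALSE)
  history <- vector("list", config$epochs)
  best <- list(acc = -Inf, model = model, epoch = 0L)
  t_adam <- 0L
  state <- NULL
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_correct <- 0L
      for (bt in batches) {
        scores <- matrix(0, length(bt), model$cfg$n_classes)
        caches <- vector("list", length(bt))
        for (i in seq_along(bt)) {
          fw <- vit_forward_one(model, x[bt[i], , ], training = TRUE)
          scores[i, ] <- fw$scores
          caches[[i]] <- fw$cache
        }
        ce <- softmax_ce(scores, y[bt])
        if (!is.finite(ce$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
        }
        g <- NULL
        for (i in seq_along(bt)) {
          g <- tree_add(g, vit_backward_one(model, caches[[i]], ce$dscores[i, ]))
        }
        if (!is.null(config$clip_norm)) {
          gn <- sqrt(tree_sq_sum(g))
          if (gn > config$clip_norm) g <- tree_scale(g, config$clip_norm / gn)
        }
        if (is.null(state)) state <- list(m = tree_zeros_like(g),
                                          v = tree_zeros_like(g))
        t_adam <- t_adam + 1L
        st <- adam_step(model$params, g, state, config, t_adam)
        model$params <- st$p
        state <- list(m = st$m, v = st$v)
        ep_loss <- ep_loss + ce$loss * length(bt)
        ep_correct <- ep_correct + sum(max.col(scores, ties.method = "first") == y[bt])
      }
      ev <- evaluate_scores(model, x_test, y_test)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = ep_loss / n, train_acc = ep_correct / n,
        test_loss = ev$loss, test_acc = ev$acc)
      if (ev$acc > best$acc) {
        best <- list(acc = ev$acc, model = model, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %2d  train loss %.4f acc %.3f | test loss %.4f acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, ev$loss, ev$acc))
      }
    }
  })
  structure(list(model = if (best$epoch > 0) best$model else model,
                 final_model = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, config = config),
            class = "vit_fit")
}

# test-set loss and accuracy
evaluate_scores <- function(model, x, y) {
  scores <- predict(model, x)
  list(loss = softmax_ce(scores, y)$loss,
       acc = mean(max.col(scores, ties.method = "first") == y))
}

#' Evaluate a model into a confusion matrix
#'
#' Argmax predictions over the evaluation images accumulated into a 4 x 4
#' count table (rows = true class, columns = predicted class).
#'
#' @param model A [vit_model()] or [vit_train()] fit.
#' @param x Image array, `n x size x size`.
#' @param y True labels (1-based indices or a factor over
#'   [tumor_classes()]).
#' @param class_levels Class names for the table dimensions.
#' @return A `confusion_matrix` object (integer matrix).
#' @export
evaluate_model <- function(model, x, y, class_levels = tumor_classes()) {
  if (inherits(model, "vit_fit")) model <- model$model
  if (dim(x)[1] == 0) stop("empty evaluation set", call. = FALSE)
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y, class_levels))
  pred <- predict(model, x, type = "class")
  confusion_matrix(y, pred, n_classes = model$cfg$n_classes,
                   class_levels = class_levels)
}

#' Train from a split manifest
#'
#' Loads the manifest's train and test records at the model's input size and
#' runs [vit_train()].
#'
#' @param model A [vit_model()].
#' @param manifest A split manifest (see [stratified_split()]).
#' @param config A [train_config()].
#' @param ... Passed to [load_batch()] (e.g. `mean`, `sd`).
#' @inheritParams vit_train
#' @return A `vit_fit` (see [vit_train()]), with the loaded test tensors
#'   attached as `test_data`.
#' @export
fit_vit <- function(model, manifest, config = train_config(), verbose = FALSE,
                    ...) {
  tr <- manifest |> dplyr::filter(.data$split == "train")
  te <- manifest |> dplyr::filter(.data$split == "test")
  if (nrow(tr) == 0 || nrow(te) == 0) {
    stop("manifest must contain assigned train and test records", call. = FALSE)
  }
  btr <- load_batch(tr, size = model$cfg$image_size, ...)
  bte <- load_batch(te, size = model$cfg$image_size, ...)
  fit <- vit_train(model, btr$x, btr$y, bte$x, bte$y, config, verbose)
  fit$test_data <- bte
  fit
}
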