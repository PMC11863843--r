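#' Training configuration
#'
#' Adam optimizer minimizing mean binary cross-entropy over the 17
#' outputs, with the learning rate decayed linearly from its base value
#' to (near) zero over the epochs.
#'
#' @param epochs Number of epochs (default 50).
#' @param base_lr Base learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param beta1,beta2,eps Adam moment-decay and stabilization constants.
#' @param seed Seed governing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, base_lr = 1e-3, batch_size = 32,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  stopifnot(epochs >= 1, base_lr > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), base_lr = base_lr,
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, eps = eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Linearly decayed learning rate for an epoch
#'
#' Epoch e (1-based) trains at `base_lr * (1 - (e - 1) / epochs)`: the
#' first epoch uses the full base rate and the rate interpolates linearly
#' down to `base_lr / epochs` at the last epoch.
#'
#' @param epoch 1-based epoch index.
#' @param epochs Total number of epochs.
#' @param base_lr Base learning rate.
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, epochs, base_lr) {
  stopifnot(epoch >= 1, epoch <= epochs)
  base_lr * (1 - (epoch - 1) / epochs)
}

#' K-fold cross-validation splits
#'
#' Uniform random partition (seeded, not label-stratified) of `n` samples
#' into `k` folds; each fold in turn is the validation set.
#'
#' @param n Number of samples, or a list of records.
#' @param k Number of folds (default 5).
#' @param seed Shuffling seed.
#' @return List of `k` elements, each `list(train = ..., validation = ...)`
#'   index vectors; the validation sets partition `1:n` with sizes within
#'   one of `n / k`.
#' @export
kfold_split <- function(n, k = 5, seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k samples", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  fold_of <- rep(seq_len(k), length.out = n)  # sizes differ by at most 1
  lapply(seq_len(k), function(f) {
    val <- sort(idx[fold_of == f])
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}

stable_bce <- function(z, Y) {
  mean(pmax(z, 0) - z * Y + log1p(exp(-abs(z))))
}

# Weight-gradient matrices are written into preallocated buffers
# (crossprod_into) so the multi-megabyte allocations happen once per
# training run, not once per step.
head_backward <- function(dh, cache, dense2, bn1, bn2, bufW1, bufW2) {
  da2 <- if (!is.null(cache$m2)) dh * cache$m2 else dh
  do2 <- da2 * cache$relu2
  bb2 <- bn_backward(do2, cache$b2, bn2$gamma)
  crossprod_into(cache$a1, bb2$dz, bufW2)
  db2 <- colSums(bb2$dz)
  da1 <- tcrossprod(bb2$dz, dense2$W)
  if (!is.null(cache$m1)) da1 <- da1 * cache$m1
  do1 <- da1 * cache$relu1
  bb1 <- bn_backward(do1, cache$b1, bn1$gamma)
  crossprod_into(cache$X, bb1$dz, bufW1)
  db1 <- colSums(bb1$dz)
  list(b1 = db1, g1 = bb1$dgamma, be1 = bb1$dbeta,
       b2 = db2, g2 = bb2$dgamma, be2 = bb2$dbeta)
}

grad_buffers <- function(params) {
  lapply(stats::setNames(nm = c("fp1.W", "fp2.W", "fg1.W", "fg2.W",
                                "joint.W", "out.W")),
         function(k) param_get(params, k) * 0)
}

splitnet_gradients <- function(params, fwd, Y, bufs) {
  n <- nrow(Y); K <- ncol(Y)
  dz4 <- (fwd$prob - Y) / (n * K)
  g <- list()
  crossprod_into(fwd$a3, dz4, bufs[["out.W"]])
  g[["out.b"]] <- colSums(dz4)
  da3 <- tcrossprod(dz4, params$out$W)
  dz3 <- da3 * fwd$relu3
  crossprod_into(fwd$C, dz3, bufs[["joint.W"]])
  g[["joint.b"]] <- colSums(dz3)
  dC <- tcrossprod(dz3, params$joint$W)
  h <- params$config$head_hidden
  gfp <- head_backward(dC[, seq_len(h), drop = FALSE], fwd$cache_fp,
                       params$fp2, params$fp1_bn, params$fp2_bn,
                       bufs[["fp1.W"]], bufs[["fp2.W"]])
  gfg <- head_backward(dC[, h + seq_len(h), drop = FALSE], fwd$cache_fg,
                       params$fg2, params$fg1_bn, params$fg2_bn,
                       bufs[["fg1.W"]], bufs[["fg2.W"]])
  g[["fp1.b"]] <- gfp$b1
  g[["fp1_bn.gamma"]] <- gfp$g1; g[["fp1_bn.beta"]] <- gfp$be1
  g[["fp2.b"]] <- gfp$b2
  g[["fp2_bn.gamma"]] <- gfp$g2; g[["fp2_bn.beta"]] <- gfp$be2
  g[["fg1.b"]] <- gfg$b1
  g[["fg1_bn.gamma"]] <- gfg$g1; g[["fg1_bn.beta"]] <- gfg$be1
  g[["fg2.b"]] <- gfg$b2
  g[["fg2_bn.gamma"]] <- gfg$g2; g[["fg2_bn.beta"]] <- gfg$be2
  for (k in names(bufs)) g[[k]] <- bufs[[k]]
  g
}

param_get <- function(params, key) {
  p <- strsplit(key, ".", fixed = TRUE)[[1]]
  params[[p[1]]][[p[2]]]
}

param_force_copy <- function(params, keys) {
  for (key in keys) {
    p <- strsplit(key, ".", fixed = TRUE)[[1]]
    params[[p[1]]][[p[2]]] <- params[[p[1]]][[p[2]]] + 0
  }
  params
}

trainable_keys <- function() {
  c("fp1.W", "fp1.b", "fp1_bn.gamma", "fp1_bn.beta",
    "fp2.W", "fp2.b", "fp2_bn.gamma", "fp2_bn.beta",
    "fg1.W", "fg1.b", "fg1_bn.gamma", "fg1_bn.beta",
    "fg2.W", "fg2.b", "fg2_bn.gamma", "fg2_bn.beta",
    "joint.W", "joint.b", "out.W", "out.b")
}

#' Train the split network
#'
#' Minibatch Adam on mean binary cross-entropy with linear learning-rate
#' decay. Shuffling, dropout and initialization are all governed by the
#' seeds in the two config objects, so a fixed pair of configs reproduces
#' the loss history bit-for-bit on the same platform.
#'
#' @param records List of `dataset_record`s, or a `list(X, Y)` with an
#'   n x p intensity matrix and n x 17 label matrix.
#' @param model_config A [splitnet_config()].
#' @param tc A [train_config()].
#' @param grid Analysis grid (required when passing matrices whose grid is
#'   not the default).
#' @param verbose Print per-epoch loss.
#' @return List with `params` (trained `splitnet_params`) and
#'   `loss_history` (one mean training loss per epoch).
#' @export
splitnet_train <- function(records, model_config = splitnet_config(),
                           tc = train_config(), grid = NULL,
                           verbose = FALSE) {
  if (is.list(records) && !is.null(records$X)) {
    X <- records$X; Y <- records$Y
    if (is.null(grid)) grid <- fg_grid()
    if (length(grid) != ncol(X)) {
      stop("grid length does not match X columns", call. = FALSE)
    }
  } else {
    stopifnot(length(records) > 0L)
    mats <- records_to_matrices(records)
    X <- mats$X; Y <- mats$Y; grid <- mats$grid
  }
  n <- nrow(X)
  stopifnot(n >= 1, nrow(Y) == n)

  params <- splitnet_init(model_config, grid)
  keys <- trainable_keys()
  params <- param_force_copy(params, keys)

  m <- lapply(keys, function(k) param_get(params, k) * 0)
  v <- lapply(keys, function(k) param_get(params, k) * 0)
  names(m) <- names(v) <- keys
  bufs <- grad_buffers(params)

  set.seed(tc$seed)
  loss_history <- numeric(tc$epochs)
  step <- 0L
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_schedule(epoch, tc$epochs, tc$base_lr)
    idx <- sample.int(n)
    starts <- seq(1L, n, by = tc$batch_size)
    tot_loss <- 0
    for (s in starts) {
      b <- idx[s:min(s + tc$batch_size - 1L, n)]
      Xb <- X[b, , drop = FALSE]; Yb <- Y[b, , drop = FALSE]
      fwd <- splitnet_forward_matrix(params, Xb, training = TRUE)
      params <- fwd$params  # refreshed batch-norm running stats
      loss <- stable_bce(fwd$z4, Yb)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      tot_loss <- tot_loss + loss * length(b)
      grads <- splitnet_gradients(params, fwd, Yb, bufs)
      step <- step + 1L
      bc1 <- 1 - tc$beta1^step
      bc2 <- 1 - tc$beta2^step
      for (k in keys) {
        adam_step_inplace(param_get(params, k), m[[k]], v[[k]],
                          grads[[k]], lr, tc$beta1, tc$beta2, tc$eps,
                          bc1, bc2)
      }
    }
    loss_history[epoch] <- tot_loss / n
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.5f",
                      epoch, lr, loss_history[epoch]))
    }
  }
  list(params = params, loss_history = loss_history)
}

#' 5-fold cross-validation of the split network
#'
#' Trains on each fold's training portion and evaluates on its validation
#' portion; reports per-group F1 as mean and standard deviation over
#' folds, plus perfect-match and FPR/FNR tables pooled over the validation
#' predictions of all folds (each sample is evaluated exactly once).
#'
#' @param records List of `dataset_record`s or `list(X, Y)`.
#' @param model_config A [splitnet_config()].
#' @param tc A [train_config()].
#' @param k Number of folds (default 5).
#' @param grid Analysis grid when passing matrices.
#' @param verbose Print per-epoch loss.
#' @return An `eval_report`: list with `per_group_f1` (data.frame `group`,
#'   `mean`, `sd`), `macro_f1`, `perfect_match`, `fpr_fnr`, and `fold_f1`
#'   (k x 17 matrix).
#' @export
cross_validate <- function(records, model_config = splitnet_config(),
                           tc = train_config(), k = 5, grid = NULL,
                           verbose = FALSE) {
  if (is.list(records) && !is.null(records$X)) {
    X <- records$X; Y <- records$Y
    if (is.null(grid)) grid <- fg_grid()
  } else {
    mats <- records_to_matrices(records)
    X <- mats$X; Y <- mats$Y; grid <- mats$grid
  }
  n <- nrow(X)
  if (n < k) stop("need at least k samples", call. = FALSE)
  folds <- kfold_split(n, k, tc$seed)
  fold_f1 <- matrix(NA_real_, k, ncol(Y))
  pred_all <- matrix(NA_integer_, n, ncol(Y))
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; va <- folds[[f]]$validation
    fit <- splitnet_train(list(X = X[tr, , drop = FALSE],
                               Y = Y[tr, , drop = FALSE]),
                          model_config, tc, grid = grid, verbose = verbose)
    ev <- evaluate_model(fit$params, X[va, , drop = FALSE],
                         Y[va, , drop = FALSE])
    fold_f1[f, ] <- ev$f1
    pred_all[va, ] <- ev$pred
  }
  per_group <- data.frame(
    group = fg_names()[seq_len(ncol(Y))],
    mean = apply(fold_f1, 2, mean, na.rm = TRUE),
    sd = apply(fold_f1, 2, stats::sd, na.rm = TRUE)
  )
  structure(list(
    per_group_f1 = per_group,
    macro_f1 = mean(per_group$mean[is.finite(per_group$mean)]),
    perfect_match = perfect_match_table(pred_all, Y),
    fpr_fnr = fpr_fnr_table(pred_all, Y),
    fold_f1 = fold_f1
  ), class = "eval_report")
}

#' Holdout protocol: 70-20-10 split with 5-fold CV models
#'
#' Sets aside an untouched test split (10% by default) before any
#' training, runs k-fold cross-validation on the remaining samples (for
#' k = 5 this trains on 72% and validates on 18% of the full data, the
#' 70-20 part of the ratio), then evaluates every fold model on the test
#' split.
#'
#' @param records List of `dataset_record`s or `list(X, Y)`.
#' @param model_config A [splitnet_config()].
#' @param tc A [train_config()]; its seed fixes the test split and folds.
#' @param test_frac Fraction held out for final testing (default 0.10).
#' @param k Number of folds (default 5).
#' @param grid Analysis grid when passing matrices.
#' @return List with `per_group_f1` (mean, sd over the k fold models on
#'   the test set), `macro_f1`, `test_idx`, and `fold_f1`.
#' @export
holdout_protocol <- function(records, model_config = splitnet_config(),
                             tc = train_config(), test_frac = 0.10,
                             k = 5, grid = NULL) {
  if (is.list(records) && !is.null(records$X)) {
    X <- records$X; Y <- records$Y
    if (is.null(grid)) grid <- fg_grid()
  } else {
    mats <- records_to_matrices(records)
    X <- mats$X; Y <- mats$Y; grid <- mats$grid
  }
  n <- nrow(X)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  set.seed(tc$seed)
  test_idx <- sort(sample.int(n, round(test_frac * n)))
  rest <- setdiff(seq_len(n), test_idx)
  folds <- kfold_split(length(rest), k, tc$seed + 1L)
  fold_f1 <- matrix(NA_real_, k, ncol(Y))
  for (f in seq_len(k)) {
    tr <- rest[folds[[f]]$train]
    fit <- splitnet_train(list(X = X[tr, , drop = FALSE],
                               Y = Y[tr, , drop = FALSE]),
                          model_config, tc, grid = grid)
    ev <- evaluate_model(fit$params, X[test_idx, , drop = FALSE],
                         Y[test_idx, , drop = FALSE])
    fold_f1[f, ] <- ev$f1
  }
  per_group <- data.frame(
    group = fg_names()[seq_len(ncol(Y))],
    mean = apply(fold_f1, 2, mean, na.rm = TRUE),
    sd = apply(fold_f1, 2, stats::sd, na.rm = TRUE)
  )
  list(per_group_f1 = per_group,
       macro_f1 = mean(per_group$mean[is.finite(per_group$mean)]),
       test_idx = test_idx, fold_f1 = fold_f1)
}
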