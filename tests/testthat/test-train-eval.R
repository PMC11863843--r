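test_that("learning rate decays linearly from base to base/epochs", {
  expect_equal(lr_schedule(1, 50, 1e-3), 1e-3)
  expect_equal(lr_schedule(26, 50, 1e-3), 1e-3 * 0.5)
  expect_equal(lr_schedule(50, 50, 1e-3), 1e-3 * 0.02)
  expect_lt(lr_schedule(50, 50, 1e-3), lr_schedule(1, 50, 1e-3))
})

test_that("k-fold splits are seeded partitions with balanced folds", {
  folds <- kfold_split(10, k = 5, seed = 3)
  vals <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(vals) == 2))
  expect_setequal(unlist(vals), 1:10)
  expect_equal(anyDuplicated(unlist(vals)), 0)
  for (f in folds) {
    expect_setequal(c(f$train, f$validation), 1:10)
    expect_length(intersect(f$train, f$validation), 0)
  }
  expect_identical(folds, kfold_split(10, k = 5, seed = 3))
  expect_false(identical(folds, kfold_split(10, k = 5, seed = 4)))
  # uneven n: fold sizes within 1 of n/k
  sizes <- lengths(lapply(kfold_split(23, 5, 1), `[[`, "validation"))
  expect_true(all(abs(sizes - 23 / 5) <= 1))
  expect_error(kfold_split(10, k = 1), "at least 2")
})

test_that("the network overfits a single repeated sample", {
  g <- tiny_grid(200)
  labels <- integer(17); labels[c(3, 7)] <- 1L
  sp <- generate_spectrum(labels, sim_config(grid = g, noise_sd = 0,
                                             drift_amp = 0), seed = 5)
  X <- matrix(rep(sp$intensities, 50), nrow = 50, byrow = TRUE)
  Y <- matrix(rep(labels, 50), nrow = 50, byrow = TRUE)
  # identical minibatch rows carry no batch-norm contrast, so the memorized
  # mapping is learned through the post-normalization parameters alone; a
  # hotter schedule than the study configuration reaches it quickly
  fit <- splitnet_train(list(X = X, Y = Y), splitnet_config(seed = 2),
                        train_config(epochs = 150, base_lr = 0.1,
                                     batch_size = 25, seed = 2), grid = g)
  expect_length(fit$loss_history, 150)
  expect_lt(fit$loss_history[150], 0.01)
  pred <- predict_labels(splitnet_forward(fit$params, sp))
  expect_equal(unname(pred), labels)
})

test_that("a non-finite loss aborts training and names the epoch", {
  g <- tiny_grid(400)
  X <- matrix(runif(8 * length(g)), 8)
  X[3, 5] <- NaN
  Y <- matrix(rbinom(8 * 17, 1, 0.3), 8)
  expect_error(
    splitnet_train(list(X = X, Y = Y), splitnet_config(seed = 1),
                   train_config(epochs = 3, seed = 1), grid = g),
    "diverged.*epoch 1")
})

test_that("training is bit-reproducible for a fixed seed", {
  g <- tiny_grid(400)
  recs <- generate_dataset(sim_config(n = 12, grid = g, seed = 6))
  f1 <- splitnet_train(recs, splitnet_config(seed = 3),
                       train_config(epochs = 3, seed = 3))
  f2 <- splitnet_train(recs, splitnet_config(seed = 3),
                       train_config(epochs = 3, seed = 3))
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params$out$W, f2$params$out$W)
})

test_that("per-group F1 matches the closed form and handles undefined
          groups", {
  pred <- rbind(c(1, 1), c(1, 0), c(1, 0), c(0, 0))
  lab  <- rbind(c(1, 0), c(1, 0), c(0, 0), c(1, 0))
  # group 1: TP=2 FP=1 FN=1 -> 2/3 ; group 2: TP=0 FP=1 FN=0 -> 0
  f1 <- per_group_f1(pred, lab)
  expect_equal(unname(f1), c(2 / 3, 0))
  # all-negative group is undefined and excluded from the macro mean
  pred2 <- cbind(pred, 0); lab2 <- cbind(lab, 0)
  f12 <- per_group_f1(pred2, lab2)
  expect_true(is.na(f12[3]))
  expect_equal(macro_f1(f12), mean(c(2 / 3, 0)))
  # perfect predictions: every group with support scores 1
  set.seed(3)
  lab3 <- random_label_matrix(10, 4)
  lab3[1, ] <- 1  # guarantee support everywhere
  expect_equal(unname(per_group_f1(lab3, lab3)), rep(1, 4))
})

test_that("perfect-match table groups by true-group count", {
  lab <- random_label_matrix(6)
  pm <- perfect_match_table(lab, lab)
  expect_equal(pm$overall_ratio, 1)
  expect_true(all(pm$by_count$ratio == 1))
  # one flipped bit in one of two samples
  lab2 <- rbind(rep(0L, 17), rep(0L, 17))
  pred2 <- lab2; pred2[2, 5] <- 1L
  pm2 <- perfect_match_table(pred2, lab2)
  expect_equal(pm2$overall_ratio, 0.5)
  # bucket counts partition the samples
  expect_equal(sum(pm$by_count$n), nrow(lab))
})

test_that("FPR/FNR tables follow per-sample definitions", {
  lab <- matrix(0L, 1, 17)
  pred <- lab; pred[1, 3] <- 1L
  tab <- fpr_fnr_table(pred, lab)
  expect_equal(tab$mean_fpr, 1 / 17)
  expect_true(is.nan(tab$mean_fnr))  # no true positives -> undefined
  # all-correct gives zero rates in every bucket
  lab2 <- random_label_matrix(10)
  tab2 <- fpr_fnr_table(lab2, lab2)
  expect_true(all(tab2$mean_fpr == 0))
  expect_true(all(tab2$mean_fnr == 0))
})

test_that("perfect-match ratio never exceeds any group's bitwise
          accuracy", {
  set.seed(11)
  for (i in 1:20) {
    lab <- random_label_matrix(30)
    pred <- lab
    flip <- matrix(rbinom(length(pred), 1, 0.1), nrow(pred))
    pred <- abs(pred - flip)
    ratio <- perfect_match_table(pred, lab)$overall_ratio
    acc <- colMeans(pred == lab)
    expect_lte(ratio, min(acc) + 1e-12)
  }
})

test_that("cross-validation reports 17 mean/sd pairs on synthetic data", {
  g <- tiny_grid(400)
  recs <- generate_dataset(sim_config(n = 25, grid = g, seed = 9))
  rep5 <- cross_validate(recs, splitnet_config(seed = 1),
                         train_config(epochs = 2, seed = 1), k = 5)
  expect_equal(nrow(rep5$per_group_f1), 17)
  expect_true(all(c("mean", "sd") %in% names(rep5$per_group_f1)))
  expect_equal(dim(rep5$fold_f1), c(5, 17))
  expect_equal(sum(rep5$perfect_match$by_count$n), 25)
})

test_that("holdout protocol isolates the test split before CV", {
  g <- tiny_grid(400)
  recs <- generate_dataset(sim_config(n = 30, grid = g, seed = 10))
  hp <- holdout_protocol(recs, splitnet_config(seed = 1),
                         train_config(epochs = 2, seed = 1))
  expect_length(hp$test_idx, 3)  # 10% of 30
  expect_equal(dim(hp$fold_f1), c(5, 17))
  # same seed -> identical test set
  hp2 <- holdout_protocol(recs, splitnet_config(seed = 1),
                          train_config(epochs = 2, seed = 1))
  expect_identical(hp$test_idx, hp2$test_idx)
})
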