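# Classifier module: architecture geometry, training behavior, prediction,
# and cross-validation mechanics.

test_that("the shape chain of the default architecture is exact", {
  m <- build_cnn(cnn_config(seed = 1))
  # 10 -> 8 -> 6 via two valid 3x3 convolutions, -> 3 via 2x2 pooling
  expect_equal(m$geom$im1$out_h, 8L)
  expect_equal(m$geom$im2$out_h, 6L)
  expect_equal(m$geom$pool$out_h, 3L)
  expect_equal(m$geom$flat, 1152L)           # 3 * 3 * 128
  expect_equal(conv2_kernel_slices(m), 4096L)  # 32 * 128 kernel slices
})

test_that("parameter counts are reported with and without biases", {
  m <- build_cnn(cnn_config(seed = 1))
  pc <- count_parameters(m)
  # closed-form: 3*3*2*32 + 3*3*32*128 + 1152*32 + 32*16 + 16*2
  expect_equal(pc$weights, 576 + 36864 + 36864 + 512 + 32)
  expect_equal(pc$weights, 74848)
  expect_equal(pc$with_biases, 74848 + 32 + 128 + 32 + 16 + 2)
  expect_equal(pc$with_biases, 75058)
})

test_that("inputs too small for the layer stack are rejected at config time", {
  expect_error(cnn_config(input_shape = c(5, 5, 2)), "too small")
  expect_error(cnn_config(input_shape = c(6, 4, 2)), "too small")
  expect_silent(cnn_config(input_shape = c(6, 6, 2)))
})

test_that("softmax outputs are probability pairs", {
  m <- build_cnn(cnn_config(seed = 2))
  imgs <- withr::with_seed(3, array(stats::runif(5 * 10 * 10 * 2, 0, 30),
                                    c(5, 10, 10, 2)))
  pred <- predict(m, imgs)
  expect_equal(pred$prob_control + pred$prob_case, rep(1, 5),
               tolerance = 1e-6)
  expect_true(all(pred$prob_control >= 0 & pred$prob_control <= 1))
})

test_that("prediction is invariant to batch composition", {
  m <- build_cnn(cnn_config(seed = 4))
  imgs <- withr::with_seed(5, array(stats::runif(6 * 10 * 10 * 2, 0, 30),
                                    c(6, 10, 10, 2)))
  all6 <- predict(m, imgs)
  two <- predict(m, imgs[1:2, , , , drop = FALSE])
  expect_equal(two$prob_case, all6$prob_case[1:2], tolerance = 1e-10)
})

test_that("prediction rejects mismatched image shapes", {
  m <- build_cnn(cnn_config(seed = 1))
  bad <- array(0, c(2, 8, 8, 2))
  expect_error(predict(m, bad), "does not match")
})

test_that("a separable toy set is fit perfectly well before epoch 200", {
  set <- toy_image_set()
  cfg <- toy_cnn_config()
  fit <- train_cnn(build_cnn(cfg), set, set, cfg)
  pred <- predict(fit$model, set)
  expect_equal(mean(pred$pred_class == set$labels), 1)
  acc <- fit$history$metrics$val_acc
  expect_lt(min(which(acc == 1)), 200)
  expect_lte(fit$history$stopped_epoch, cfg$max_epochs)
})

test_that("training is deterministic under a fixed seed", {
  set <- toy_image_set()
  cfg <- cnn_config(max_epochs = 30, early_stop_patience = 30, seed = 8)
  f1 <- train_cnn(build_cnn(cfg), set, set, cfg)
  f2 <- train_cnn(build_cnn(cfg), set, set, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history$metrics, f2$history$metrics)
})

test_that("dropout perturbs training passes only; evaluation is stable", {
  set <- toy_image_set()
  m <- build_cnn(cnn_config(seed = 9))
  p1 <- predict(m, set)
  p2 <- predict(m, set)
  expect_identical(p1, p2)
})

test_that("restored weights match the best validation loss seen", {
  set <- toy_image_set()
  cfg <- cnn_config(max_epochs = 60, early_stop_patience = 10, seed = 10)
  fit <- train_cnn(build_cnn(cfg), set, set, cfg)
  h <- fit$history
  expect_equal(h$best_val_loss, min(h$metrics$val_loss))
  # evaluating the restored model reproduces the best loss
  pred <- predict(fit$model, set)
  y <- cbind(as.integer(set$labels) == 1L, as.integer(set$labels) == 2L)
  loss <- -mean(log(rowSums(cbind(pred$prob_control, pred$prob_case) * y)))
  expect_equal(loss, h$best_val_loss, tolerance = 1e-9)
})

test_that("single-class training sets are rejected", {
  imgs <- array(1, c(4, 10, 10, 2))
  set <- labeled_image_set(imgs, rep("control", 4))
  cfg <- toy_cnn_config()
  expect_error(train_cnn(build_cnn(cfg), set, set, cfg), "single class")
})

test_that("cross-validation partitions are disjoint, covering, near-equal", {
  set <- toy_image_set(n_per_class = 20)   # 40 subjects
  folds <- withr::with_seed(1, netimage:::make_folds(40, 4))
  expect_equal(vapply(folds, length, 1L), rep(10L, 4), ignore_attr = TRUE)
  expect_identical(sort(unname(unlist(folds))), 1:40)
  folds5 <- withr::with_seed(1, netimage:::make_folds(23, 5))
  expect_identical(sort(vapply(folds5, length, 1L)),
                   c(4L, 4L, 5L, 5L, 5L), ignore_attr = TRUE)
  expect_identical(sort(unname(unlist(folds5))), 1:23)
})

test_that("cross-validation on a separable toy cohort is accurate", {
  set <- toy_image_set(n_per_class = 8)
  cfg <- cnn_config(max_epochs = 120, early_stop_patience = 120, seed = 2)
  res <- cross_validate(set, k = 4, iterations = 1, cfg = cfg, seed = 5)
  expect_equal(nrow(res$fold_results), 4)
  expect_equal(res$mean_accuracy, mean(res$fold_results$accuracy))
  expect_gte(res$mean_accuracy, 0.9)
  expect_error(cross_validate(set, k = 20, cfg = cfg), "exceeds")
})

test_that("tidiers summarize cross-validation results faithfully", {
  res <- new_cv_result(tibble::tibble(iteration = 1, fold = 1:4,
                                      accuracy = c(0.889, 0.746, 0.790, 0.825)),
                       k = 4, iterations = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- glance(res)
  expect_equal(gl$mean_accuracy, mean(c(0.889, 0.746, 0.790, 0.825)))
  expect_equal(gl$n_folds, 4L)
})

test_that("autoplot methods return ggplot objects", {
  res <- new_cv_result(tibble::tibble(iteration = 1, fold = 1:4,
                                      accuracy = c(0.9, 0.8, 0.85, 0.8)),
                       k = 4, iterations = 1)
  expect_s3_class(autoplot(res), "ggplot")
  emb <- withr::with_seed(1, matrix(stats::rnorm(200), 25, 8))
  expect_s3_class(autoplot(graph_to_image(emb, 4, 5)), "ggplot")
})
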