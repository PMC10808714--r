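test_that("estimator architectures follow the component count", {
  cfg2 <- estimator_config(2)
  expect_equal(cfg2$hidden, c(40L, 20L, 10L))
  expect_equal(cfg2$batch_size, 500L)
  expect_equal(cfg2$epochs, 20L)
  expect_equal(cfg2$learning_rate, 1e-3)
  cfg3 <- estimator_config(3)
  expect_equal(cfg3$hidden, c(70L, 50L, 30L, 10L))
  expect_equal(estimator_config(5)$hidden, c(70L, 50L, 30L, 10L))
  expect_error(estimator_config(1), "n_components")
  # explicit override wins
  expect_equal(estimator_config(2, hidden = c(8L, 4L))$hidden, c(8L, 4L))
})

test_that("training makes progress and is deterministic under a fixed seed", {
  fx <- small_two_comp()
  cfg <- estimator_config(2, seed = 9)
  fit <- flim_ann(fx$train, cfg)
  expect_length(fit$loss_history, cfg$epochs)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  fit2 <- flim_ann(fx$train, cfg)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$weights, fit2$weights)
  expect_error(flim_ann(fx$train, estimator_config(3)), "label columns")
})

test_that("predictions are valid fraction rows, invariant to intensity scale", {
  fx <- small_two_comp()
  fit <- flim_ann(fx$train, estimator_config(2, epochs = 5, seed = 2))
  pred <- predict(fit, fx$test)
  expect_equal(dim(pred), c(300L, 2L))
  expect_true(all(pred >= 0 & pred <= 1))
  expect_equal(rowSums(pred), rep(1, 300), tolerance = 1e-9)
  pred10 <- predict(fit, fx$test$counts * 10L)
  expect_lt(max(abs(pred10 - pred)), 1e-6)
  expect_error(predict(fit, fx$test$counts[, 1:100]), "bin mismatch")
  expect_equal(nrow(predict(fit, fx$test$counts[0, , drop = FALSE])), 0L)
  # a held-out fit on a clearly separated pair is genuinely informative
  expect_gt(r_squared(pred[, 1], fx$test$labels[, 1]), 0.9)
})

test_that("relabelling components permutes the fitted predictor exactly", {
  cfg_i <- fast_instrument(n_photons = 2000)
  tr <- generate_dataset(1200, c(3, 6, 12), cfg_i, seed = 4)
  te <- generate_dataset(50, c(3, 6, 12), cfg_i, seed = 5)
  perm <- c(2, 3, 1)
  tr_p <- tr
  tr_p$labels <- tr$labels[, perm]
  tr_p$lifetimes_ns <- tr$lifetimes_ns[perm]
  cfg <- estimator_config(3, epochs = 4, seed = 31)
  fit <- flim_ann(tr, cfg)
  fit_p <- flim_ann(tr_p, cfg)
  expect_equal(predict(fit_p, te), predict(fit, te)[, perm],
               tolerance = 1e-12)
})

test_that("uninformative spacing collapses predictions to the prior mean", {
  cfg_i <- fast_instrument(n_photons = 20000)
  tr <- generate_dataset(3000, c(4, 4.05), cfg_i, seed = 8)
  te <- generate_dataset(200, c(4, 4.05), cfg_i, seed = 9)
  fit <- flim_ann(tr, estimator_config(2, seed = 10))
  pred <- predict(fit, te)
  expect_lt(max(abs(pred - 0.5)), 0.05)
})

test_that("fine-tuning adapts to a lifetime-shifted domain", {
  cfg_i <- fast_instrument()
  base <- generate_dataset(2500, c(4, 9), cfg_i, seed = 14)
  fit <- flim_ann(base, estimator_config(2, seed = 15))
  # chemical-interaction-like shift of both lifetimes
  shifted_tr <- generate_dataset(1500, c(3.2, 7.6), cfg_i, seed = 16)
  shifted_te <- generate_dataset(400, c(3.2, 7.6), cfg_i, seed = 17)
  tuned <- fine_tune(fit, shifted_tr, epochs = 10)
  err_base <- mean(abs(predict(fit, shifted_te) - shifted_te$labels))
  err_tuned <- mean(abs(predict(tuned, shifted_te) - shifted_te$labels))
  expect_lt(err_tuned, err_base)
  # adaptation returns a new model; a zero learning rate is a no-op
  expect_false(identical(tuned$weights, fit$weights))
  expect_length(tuned$loss_history, length(fit$loss_history) + 10)
  frozen <- fine_tune(fit, shifted_tr, epochs = 2, learning_rate = 0)
  expect_equal(frozen$weights, fit$weights, tolerance = 1e-12)
  # determinism of the adaptation pass
  tuned2 <- fine_tune(fit, shifted_tr, epochs = 10)
  expect_identical(tuned$weights, tuned2$weights)
})

test_that("checkpoints round-trip bit-exactly", {
  fx <- small_two_comp(n_train = 600, n_test = 10)
  fit <- flim_ann(fx$train, estimator_config(2, epochs = 2, seed = 1))
  path <- tempfile(fileext = ".rds")
  write_estimator(fit, path)
  back <- read_estimator(path)
  expect_identical(back, fit)
  saveRDS(1:3, path)
  expect_error(read_estimator(path), "checkpoint")
})
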