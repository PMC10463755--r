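test_that("binary cross-entropy matches hand-evaluated cases", {
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  set.seed(21)
  p <- runif(20); y <- rbinom(20, 1, 0.5)
  expect_equal(bce_loss(p, y), bce_loss(rev(p), rev(y)))
  expect_gte(bce_loss(p, y), 0)
  expect_error(bce_loss(numeric(), integer()), "non-empty")
})

test_that("loss stays finite at the probability boundaries", {
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
})

test_that("learning-rate schedule decays stepwise and monotonically", {
  cfg <- train_config(lr = 1e-3, lr_decay = 0.8, decay_every = 10)
  expect_equal(lr_at(0, cfg), 1e-3)
  expect_equal(lr_at(9, cfg), 1e-3)
  expect_equal(lr_at(20, cfg), 6.4e-4)
  lrs <- vapply(0:99, lr_at, 0, cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  flat <- train_config(lr = 1e-3, lr_decay = 1.0)
  expect_equal(vapply(0:50, lr_at, 0, cfg = flat), rep(1e-3, 51))
})

test_that("training is reproducible and records a full history", {
  ex <- gen_dataset(24, seed = 5)
  cfg <- tiny_model_cfg(k_tgt = 3L, L_drug = 24L, L_tgt = 30L)
  tc <- train_config(epochs = 3, batch_size = 8, seed = 11)
  f1 <- train_model(cfg, tc, ex, ex)
  f2 <- train_model(cfg, tc, ex, ex)
  expect_equal(f1$history$train_loss[1], f2$history$train_loss[1],
               tolerance = 1e-6)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 3L)
  expect_false(any(is.na(f1$history$train_loss)))
  f3 <- train_model(cfg, train_config(epochs = 3, batch_size = 8,
                                      seed = 12), ex, ex)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("checkpoint selection returns the best-validation epoch", {
  ex <- gen_dataset(24, seed = 6)
  cfg <- tiny_model_cfg(k_tgt = 3L, L_drug = 24L, L_tgt = 30L)
  fit <- train_model(cfg, train_config(epochs = 4, batch_size = 8,
                                       seed = 2), ex, ex)
  aucs <- fit$history$valid_auc
  expect_equal(fit$best_epoch, which.max(aucs))
  expect_gte(aucs[fit$best_epoch], aucs[length(aucs)])
})

test_that("training errors on empty input and lambda stays fixed on demand", {
  cfg <- tiny_model_cfg(lambda_mode = "fixed", lambda_init = c(0.4, 0.6))
  expect_error(train_model(cfg, train_config(epochs = 1),
                           gen_dataset(8, 1)[0, ]), "empty")
  ex <- gen_dataset(16, seed = 9)
  fit <- train_model(tiny_model_cfg(lambda_mode = "fixed",
                                    lambda_init = c(0.4, 0.6),
                                    k_tgt = 3L, L_tgt = 30L),
                     train_config(epochs = 2, batch_size = 8, seed = 1),
                     ex, ex)
  expect_equal(fit$model$params$lambda, c(0.4, 0.6))
})

test_that("checkpoints round-trip through a file with config embedded", {
  ex <- gen_dataset(12, seed = 13)
  cfg <- tiny_model_cfg(k_tgt = 3L, L_tgt = 30L)
  fit <- train_model(cfg, train_config(epochs = 1, batch_size = 6,
                                       seed = 3), ex, ex)
  path <- withr::local_tempfile()
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  expect_equal(predict_proba(m2, ex), predict_proba(fit$model, ex))
  expect_equal(m2$cfg$d_model, cfg$d_model)
})

test_that("grid plan enumerates phase-1 and phase-2 cells", {
  grid <- list(lr = c(1e-1, 1e-2, 1e-3, 1e-4, 1e-5),
               lr_decay = c(0.5, 0.6, 0.7, 0.8, 0.9),
               batch_size = c(32, 64, 128, 256),
               dropout = c(0.1, 0.2, 0.3, 0.4, 0.5))
  plan <- grid_plan(grid)
  expect_equal(sum(plan$phase == 1L), 5L * 4L)
  expect_equal(sum(plan$phase == 2L), 5L * 5L)
  expect_error(grid_plan(list(lr = numeric(), lr_decay = 1,
                              batch_size = 1, dropout = 0.1)), "empty")
})

test_that("grid search returns the single candidate, or the dominant one", {
  ex <- gen_dataset(24, seed = 30)
  cfg <- tiny_model_cfg(k_tgt = 3L, L_tgt = 30L)
  g1 <- list(lr = 1e-3, lr_decay = 0.8, batch_size = 8, dropout = 0.1)
  r1 <- grid_search(g1, cfg, ex, ex, budget_epochs = 1, seed = 1)
  expect_equal(r1$best$lr, 1e-3)
  expect_equal(r1$best$batch_size, 8L)
  expect_equal(nrow(r1$results), 2L)

  # a learning rate of 0 is not allowed; an absurdly small one cannot
  # beat a working one on the planted rule
  g2 <- list(lr = c(1e-3, 1e-12), lr_decay = 0.8, batch_size = 8,
             dropout = 0.1)
  r2 <- grid_search(g2, cfg, ex, ex, budget_epochs = 2, seed = 1)
  expect_true(r2$best$lr %in% g2$lr)
  p1 <- r2$results[r2$results$phase == 1L, ]
  expect_equal(r2$best$lr, p1$lr[which.max(p1$valid_auc)])
})
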