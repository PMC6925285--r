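test_that("score is sigma(W y_T + b): zero weights give exactly 0.5", {
  inv <- tiny_inventory(4)
  m <- init_engine(inv, engine_config("gru", TRUE, 8), seed = 1)
  m$params$W_head[] <- 0
  m$params$b_head <- 0
  fs <- feature_sequence(c(0L, 1L, 2L), inv)
  expect_equal(score_sequence(m, fs), 0.5)
})

test_that("scores are deterministic, in (0,1), and validate their input", {
  inv <- tiny_inventory(4)
  m <- init_engine(inv, engine_config("gru", TRUE, 8), seed = 2)
  fs <- feature_sequence(sample(0:4, 30, replace = TRUE), inv)
  s1 <- score_sequence(m, fs)
  s2 <- score_sequence(m, fs)
  expect_identical(s1, s2)
  expect_gt(s1, 0)
  expect_lt(s1, 1)
  expect_error(score_sequence(m, feature_sequence(integer(0), inv)), "empty")
  other <- tiny_inventory(6)
  expect_error(score_sequence(m, feature_sequence(0L, other)), "mismatch")
})

test_that("scores stay in (0,1) across cells, directions and sequences", {
  inv <- tiny_inventory(5)
  set.seed(17)
  for (cell in c("gru", "lstm", "simple")) {
    for (bidir in c(TRUE, FALSE)) {
      m <- init_engine(inv, engine_config(cell, bidir, 6), seed = 3)
      for (i in 1:5) {
        fs <- feature_sequence(sample(0:5, sample(1:40, 1), replace = TRUE), inv)
        s <- score_sequence(m, fs)
        expect_true(s > 0 && s < 1)
      }
    }
  }
})

test_that("GRU has fewer parameters than LSTM at equal cell counts", {
  inv <- default_inventory()
  n_gru <- engine_param_count(init_engine(inv, engine_config("gru", FALSE, 256)))
  n_lstm <- engine_param_count(init_engine(inv, engine_config("lstm", FALSE, 256)))
  n_simple <- engine_param_count(init_engine(inv, engine_config("simple", FALSE, 256)))
  expect_lt(n_gru, n_lstm)
  expect_lt(n_simple, n_gru)
})

test_that("the cell budget matches across directionalities by default", {
  expect_equal(engine_config("gru", TRUE)$cells_per_direction, 128L)
  expect_equal(engine_config("gru", FALSE)$cells_per_direction, 256L)
})

test_that("padding and masking leave individual scores unchanged", {
  inv <- tiny_inventory(4)
  m <- init_engine(inv, engine_config("gru", TRUE, 8), seed = 5)
  set.seed(6)
  seqs <- lapply(c(3, 5, 9), function(len) {
    feature_sequence(sample(0:4, len, replace = TRUE), inv)
  })
  batch <- pad_and_mask(seqs)
  expect_equal(dim(batch$tokens), c(3L, 9L))
  expect_equal(batch$lengths, c(3L, 5L, 9L))
  expect_equal(rowSums(batch$mask), c(3, 5, 9))
  got <- score_batch(m, batch)
  want <- vapply(seqs, function(s) score_sequence(m, s), numeric(1))
  expect_equal(got, want, tolerance = 1e-5)

  equal_len <- pad_and_mask(seqs[c(2, 2)])
  expect_true(all(equal_len$mask))
  expect_error(pad_and_mask(list()), "empty")
})

test_that("training selects the lowest-validation-loss epoch and stops early", {
  inv <- tiny_inventory(4)
  train <- quick_labelled_set(inv, n_per_class = 6, len = 15, seed = 7)
  val <- quick_labelled_set(inv, n_per_class = 3, len = 15, seed = 8)
  fit <- train_engine(train, val, inv,
                      config = engine_config("gru", TRUE, 6),
                      train_config = engine_train_config(patience = 5,
                                                         max_epochs = 60,
                                                         seed = 9))
  h <- fit$history
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_loss)])
  # stopped within patience epochs of the best epoch (or hit the cap)
  expect_lte(nrow(h), max(fit$best_epoch + 5, 60))
  if (nrow(h) < 60) expect_equal(nrow(h), fit$best_epoch + 5)
  # linearly separable classes: validation loss improves from epoch 1
  expect_lt(min(h$val_loss), h$val_loss[1])
})

test_that("training is deterministic given the seed", {
  inv <- tiny_inventory(4)
  train <- quick_labelled_set(inv, n_per_class = 4, len = 10, seed = 10)
  val <- quick_labelled_set(inv, n_per_class = 2, len = 10, seed = 11)
  tc <- engine_train_config(max_epochs = 8, seed = 12)
  fit1 <- train_engine(train, val, inv, engine_config("gru", TRUE, 5), tc)
  fit2 <- train_engine(train, val, inv, engine_config("gru", TRUE, 5), tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("degenerate training inputs are rejected", {
  inv <- tiny_inventory(4)
  pos_only <- quick_labelled_set(inv, 4, 10, 13)[5:8]
  val <- quick_labelled_set(inv, 2, 10, 14)
  expect_error(train_engine(pos_only, val, inv), "single class")
  expect_error(train_engine(list(), val, inv), "non-empty")
  unlabelled <- list(feature_sequence(0:1, inv, "u"))
  expect_error(train_engine(unlabelled, val, inv), "no label")
})

test_that("checkpoints round-trip with their inventory hash", {
  inv <- tiny_inventory(4)
  m <- init_engine(inv, engine_config("gru", TRUE, 6), seed = 15)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  fs <- feature_sequence(c(0L, 2L, 1L), inv)
  expect_identical(score_sequence(back, fs), score_sequence(m, fs))
  expect_identical(back$inv_hash, m$inv_hash)
  expect_error(load_checkpoint(file.path(tempdir(), "missing.ckpt")),
               "not found")
})
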