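test_that("CTC loss matches closed-form and brute-force values", {
  # 2 frames, classes {a, blank}, uniform posteriors: paths aa, a-, -a
  logp <- matrix(log(0.5), 2, 2)
  expect_equal(ctc_forward_loss(logp, 0L, blank_id = 1L), -log(3 / 4),
               tolerance = 1e-12)
  # one-hot posteriors on a valid path -> probability ~1
  eps <- 1e-9
  hot <- log(matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2, byrow = TRUE))
  expect_lt(ctc_forward_loss(hot, 0L, blank_id = 1L), 1e-6)
  # infeasible: target needs more frames than available
  expect_equal(ctc_forward_loss(logp, c(0L, 0L, 0L), blank_id = 1L), Inf)
  # blank in target is rejected
  expect_error(ctc_forward_loss(logp, 1L, blank_id = 1L), "blank")
})

test_that("CTC dynamic programming equals brute-force path enumeration", {
  set.seed(21)
  for (i in 1:40) {
    T_ <- sample(1:5, 1)
    C <- sample(2:4, 1)
    blank <- C - 1L
    logits <- matrix(rnorm(T_ * C), T_, C)
    logp <- logits - apply(logits, 1, function(r) log(sum(exp(r))))
    L <- sample(0:min(T_, 2), 1)
    target <- if (L > 0) sample(0:(C - 2), L, replace = TRUE) else integer(0)
    expect_equal(ctc_forward_loss(logp, target, blank),
                 ctc_brute_force(logp, target, blank), tolerance = 1e-6)
  }
})

test_that("greedy frame path takes per-frame argmax with lowest-id ties", {
  hot <- diag(3)[c(2, 1, 3), ]
  expect_equal(as.integer(frame_argmax(hot)), c(1L, 0L, 2L))
  uniform <- matrix(1, 4, 3)
  expect_equal(as.integer(frame_argmax(uniform)), rep(0L, 4))
  empty <- frame_argmax(matrix(0, 0, 3))
  expect_equal(length(empty), 0L)
})

test_that("silence-run threshold converts seconds to frame counts", {
  expect_identical(silence_run_threshold(3.0, 0.01), 300L)
  expect_identical(silence_run_threshold(1.0, 0.01), 100L)
  expect_identical(silence_run_threshold(0.015, 0.01), 2L)
  expect_error(silence_run_threshold(0, 0.01), "positive")
  expect_error(silence_run_threshold(3, 0), "positive")
  expect_error(silence_run_threshold(-1, 0.01), "positive")
})

test_that("blank-run collapse follows the decode rules", {
  inv <- tiny_inventory(3)  # ids a=0 b=1 c=2 <sil>=3, blank=4
  blank <- inv$size
  path1 <- c(0L, 0L, rep(blank, 300), 1L, 1L)
  out1 <- collapse_to_feature_sequence(path1, 300, inv)
  expect_equal(out1$tokens, c(0L, inv$silence_id, 1L))

  # 299 blanks: no silence token, but the repeat is preserved
  path2 <- c(0L, 0L, rep(blank, 299), 0L)
  out2 <- collapse_to_feature_sequence(path2, 300, inv)
  expect_equal(out2$tokens, c(0L, 0L))

  # all-blank path below threshold -> empty sequence
  expect_equal(collapse_to_feature_sequence(rep(blank, 299), 300, inv)$length, 0L)
  # ...and at threshold -> single silence
  expect_equal(collapse_to_feature_sequence(rep(blank, 300), 300, inv)$tokens,
               inv$silence_id)
  # plain CTC merge without blanks
  expect_equal(collapse_to_feature_sequence(c(0L, 0L, 1L, 1L, 1L, 2L), 300,
                                            inv)$tokens, c(0L, 1L, 2L))
  expect_equal(collapse_to_feature_sequence(integer(0), 300, inv)$length, 0L)
  expect_error(collapse_to_feature_sequence(c(0L), 0, inv), "N must be")
})

test_that("collapse output is shorter than the path and never contains blank", {
  inv <- tiny_inventory(3)
  blank <- inv$size
  set.seed(31)
  syllable_or_blank <- c(0:(inv$silence_id - 1L), blank)  # CTC targets exclude silence
  for (i in 1:30) {
    path <- sample(syllable_or_blank, sample(1:80, 1), replace = TRUE,
                   prob = c(rep(1, length(syllable_or_blank) - 1), 4))
    N <- sample(1:10, 1)
    out <- collapse_to_feature_sequence(path, N, inv)
    expect_lte(out$length, length(path))
    expect_false(blank %in% out$tokens)
    runs <- rle(path)
    expect_equal(sum(out$tokens == inv$silence_id),
                 sum(runs$values == blank & runs$lengths >= N))
  }
})

test_that("generator training reduces CTC loss on toy audio", {
  inv <- tiny_inventory(4)
  gcfg <- generator_config(
    conv_specs = list(list(filters = 4, kernel = c(5, 5), stride = c(1, 2))),
    rnn_layers = 1, rnn_cells = 8, n_bins = 13)
  data <- generate_toy_ctc_data(inv, n_utterances = 8, tokens_per_utt = 3,
                                seed = 5)
  tcfg <- generator_train_config(batch_size = 4, iterations = 200, seed = 7)
  fit <- train_generator(data, inv, gcfg, tcfg)
  expect_equal(nrow(fit$history), 200L)
  expect_lt(mean(utils::tail(fit$history$loss, 10)),
            mean(utils::head(fit$history$loss, 10)))
})

test_that("generator training is deterministic and filters long utterances", {
  inv <- tiny_inventory(3)
  gcfg <- generator_config(
    conv_specs = list(list(filters = 3, kernel = c(3, 3), stride = c(1, 2))),
    rnn_layers = 1, rnn_cells = 6, n_bins = 10)
  data <- generate_toy_ctc_data(inv, n_utterances = 6, tokens_per_utt = 2,
                                seed = 9)
  tcfg <- generator_train_config(batch_size = 3, iterations = 15, seed = 13,
                                 max_utterance_s = 10)
  fit1 <- train_generator(data, inv, gcfg, tcfg)
  fit2 <- train_generator(data, inv, gcfg, tcfg)
  expect_identical(fit1$history$loss, fit2$history$loss)

  # an over-long utterance is dropped with a message
  long_item <- data[[1]]
  long_item$waveform <- rep(long_item$waveform, 200)  # > 10 s
  expect_message(
    train_generator(c(data[2:3], list(long_item)), inv, gcfg,
                    generator_train_config(batch_size = 2, iterations = 2,
                                           seed = 1)),
    "removed 1 utterance")
  # every utterance filtered out -> error
  all_long <- list(long_item)
  expect_error(train_generator(all_long, inv, gcfg, tcfg), "no utterances")
  expect_error(train_generator(list(), inv, gcfg, tcfg), "empty")
})

test_that("the generator architecture derives its output geometry correctly", {
  inv <- tiny_inventory(4)
  cfg <- generator_config()
  expect_equal(cfg$effective_frame_s, 0.01)
  m <- init_generator(inv, cfg, seed = 1)
  expect_equal(dim(m$params$out_W)[1], inv$size + 1L)
  # time stride 1 keeps one logit row per 10 ms frame
  small <- generator_config(
    conv_specs = list(list(filters = 2, kernel = c(3, 3), stride = c(1, 2))),
    rnn_layers = 1, rnn_cells = 4, n_bins = 8)
  ms <- init_generator(inv, small, seed = 1)
  feat <- cmvn(log_filterbank(rnorm(3200), 8000, n_bins = 8))
  fwd <- adspeech:::generator_forward(ms, feat)
  expect_equal(nrow(fwd$logits), nrow(feat))
  expect_equal(ncol(fwd$logits), inv$size + 1L)
})
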