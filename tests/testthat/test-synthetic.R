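test_that("the default cohort has the clinical study shape: 120 sequences", {
  inv <- default_inventory()
  cohort <- generate_cohort(cohort_spec(seed = 1), inv)
  expect_equal(length(cohort$sequences), 120L)
  expect_equal(nrow(cohort$manifest), 120L)
  expect_equal(sum(cohort$manifest$label == 0), 60L)
  expect_equal(sum(cohort$manifest$label == 1), 60L)
  expect_equal(length(unique(cohort$manifest$subject)), 20L)
  expect_equal(unname(table(cohort$manifest$test_type)["fluency_animal"]), 20L)
  expect_false(any(duplicated(cohort$manifest$id)))
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  inv <- tiny_inventory(10)
  spec <- cohort_spec(n_subjects_per_class = 2, tests_per_subject = 2,
                      ch = class_params(30, 5, 0.1, 0.1, 5),
                      ad = class_params(15, 3, 0.3, 0.2, 3), seed = 77)
  c1 <- generate_cohort(spec, inv)
  c2 <- generate_cohort(spec, inv)
  expect_identical(lapply(c1$sequences, `[[`, "tokens"),
                   lapply(c2$sequences, `[[`, "tokens"))
})

test_that("degenerate parameters give a constant-token sequence", {
  inv <- tiny_inventory(4)
  spec <- cohort_spec(n_subjects_per_class = 1, tests_per_subject = 1,
                      ch = class_params(20, 0, 0, 1, 1),
                      ad = class_params(20, 0, 0, 1, 1), seed = 5)
  cohort <- generate_cohort(spec, inv)
  toks <- cohort$sequences[[1]]$tokens
  expect_equal(length(unique(toks)), 1L)
  expect_equal(length(toks), 20L)
})

test_that("empirical silence fraction tracks the silence probability", {
  inv <- tiny_inventory(10)
  spec <- cohort_spec(n_subjects_per_class = 5, tests_per_subject = 2,
                      ch = class_params(150, 10, 0.3, 0, 8),
                      ad = class_params(150, 10, 0.3, 0, 8), seed = 31)
  cohort <- generate_cohort(spec, inv)
  toks <- unlist(lapply(cohort$sequences, `[[`, "tokens"))
  expect_gte(length(toks), 1000)
  frac <- mean(toks == inv$silence_id)
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("class statistics separate in the designed directions", {
  inv <- default_inventory()
  cohort <- generate_cohort(cohort_spec(seed = 13), inv)
  stats <- lapply(cohort$sequences, function(s) {
    sm <- sequence_summary(s, inv)
    c(label = s$label, len = sm$length,
      sil = sm$silence_count / sm$length,
      rep = sm$immediate_repeat_count / sm$length,
      uniq = sm$unique_token_count)
  })
  stats <- do.call(rbind, stats)
  ch <- stats[stats[, "label"] == 0, ]
  ad <- stats[stats[, "label"] == 1, ]
  expect_gt(mean(ch[, "len"]), mean(ad[, "len"]))       # AD speaks less
  expect_lt(mean(ch[, "sil"]), mean(ad[, "sil"]))       # AD pauses more
  expect_lt(mean(ch[, "rep"]), mean(ad[, "rep"]))       # AD repeats more
  expect_gt(mean(ch[, "uniq"]), mean(ad[, "uniq"]))     # AD less diverse
})

test_that("invalid cohort parameters are rejected", {
  expect_error(class_params(100, 10, 0.7, 0.5, 5), "<= 1")
  expect_error(class_params(100, 10, -0.1, 0, 5), "\\[0,1\\]")
  expect_error(class_params(0, 10, 0.1, 0.1, 5), "mean_length")
  inv <- tiny_inventory(3)
  spec <- cohort_spec(n_subjects_per_class = 1, tests_per_subject = 1,
                      ch = class_params(10, 0, 0, 0, 50),
                      ad = class_params(10, 0, 0, 0, 2), seed = 1)
  expect_error(generate_cohort(spec, inv), "exceeds")
})

test_that("corruption model: identity, total deletion, and expected TER", {
  inv <- default_inventory()
  fs <- feature_sequence(sample(0:300, 50), inv, "x", label = 0)
  clean <- corrupt_sequence(fs, corruption_spec(0, 0, 0, seed = 2), inv)
  expect_identical(clean$tokens, fs$tokens)
  gone <- corrupt_sequence(fs, corruption_spec(0, 0, 1, seed = 2), inv)
  expect_equal(gone$length, 0L)

  set.seed(91)
  refs <- lapply(1:10, function(i) {
    feature_sequence(sample(0:316, 100, replace = TRUE), inv, paste0("r", i))
  })
  hyps <- corrupt_cohort(refs, corruption_spec(substitution_prob = 0.1,
                                               seed = 19), inv)
  ters <- mapply(token_error_rate, refs, hyps)
  expect_lt(abs(mean(ters) - 0.1), 0.05)
})

test_that("corruption is deterministic given its seed and keeps metadata", {
  inv <- tiny_inventory(6)
  fs <- feature_sequence(sample(0:5, 40, replace = TRUE), inv, "id7", label = 1)
  cs <- corruption_spec(0.2, 0.1, 0.1, seed = 3)
  a <- corrupt_sequence(fs, cs, inv)
  b <- corrupt_sequence(fs, cs, inv)
  expect_identical(a$tokens, b$tokens)
  expect_equal(a$sample_id, "id7")
  expect_equal(a$label, 1L)
  expect_error(corruption_spec(0.6, 0, 0.5), "exceed 1")
  expect_error(corruption_spec(-0.1, 0, 0), "\\[0,1\\]")
})

test_that("toy audio duration arithmetic and alignments are exact", {
  inv <- tiny_inventory(4)
  empty <- generate_toy_audio(feature_sequence(integer(0), inv), inv)
  expect_equal(length(empty$waveform), 0L)

  one <- generate_toy_audio(feature_sequence(0L, inv), inv,
                            token_dur_s = 0.5, sample_rate = 16000)
  expect_equal(length(one$waveform), 8000L)

  fs <- feature_sequence(c(0L, 2L, 1L), inv)
  toy <- generate_toy_audio(fs, inv, token_dur_s = 0.1, sample_rate = 8000)
  feat <- log_filterbank(toy$waveform, toy$sample_rate, n_bins = 13)
  expect_equal(length(toy$frame_labels), nrow(feat))
  # frame centred at 50 ms lies inside token 1; at 150 ms inside token 2
  centers <- ((seq_along(toy$frame_labels) - 1) * 80 + 100) / 8000
  expect_equal(toy$frame_labels, fs$tokens[pmin(floor(centers / 0.1) + 1, 3)])

  sil <- generate_toy_audio(encode_tokens(c("a", "<sil>"), inv), inv)
  expect_lt(max(abs(sil$waveform[801:1600])), 0.1)  # silence is near-silent

  expect_error(generate_toy_audio(fs, inv, tone_freqs = c(100, NA, 200)),
               "no tone frequency")
  expect_error(generate_toy_audio(fs, inv, tone_freqs = c(100, 200, 9000),
                                  sample_rate = 8000), "Nyquist")
})
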