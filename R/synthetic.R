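#' Class-conditional parameters for a synthetic cohort
#'
#' One side (CH or AD) of a two-class synthetic cohort. Sequences are drawn
#' by a first-order process per position: with `repeat_prob` copy the
#' previous token (perseveration), with `silence_prob` start a silence run
#' whose length is geometric with mean `silence_run_mean` (pausing),
#' otherwise sample uniformly from the class's active vocabulary (the first
#' `vocab_size` syllables). Sequence length is a rounded normal around
#' `mean_length`. AD-like defaults differ from CH-like ones in exactly the
#' characteristics the Feature Sequence was designed to carry: more
#' silences, more repeats, fewer unique tokens, shorter sequences.
#'
#' @param mean_length mean token count.
#' @param length_sd standard deviation of the token count.
#' @param silence_prob per-position probability of starting a silence run.
#' @param repeat_prob per-position probability of copying the previous
#'   token.
#' @param vocab_size number of active syllables.
#' @param silence_run_mean mean silence-run length (>= 1; 1 means single
#'   silence tokens).
#' @return a list of class `class_params`.
#' @export
class_params <- function(mean_length, length_sd, silence_prob, repeat_prob,
                         vocab_size, silence_run_mean = 1) {
  stopifnot(mean_length > 0, length_sd >= 0, vocab_size >= 1,
            silence_run_mean >= 1)
  if (silence_prob < 0 || silence_prob > 1 || repeat_prob < 0 ||
      repeat_prob > 1 || silence_prob + repeat_prob > 1) {
    stop("probabilities must lie in [0,1] with silence_prob + repeat_prob <= 1")
  }
  structure(list(mean_length = mean_length, length_sd = length_sd,
                 silence_prob = silence_prob, repeat_prob = repeat_prob,
                 vocab_size = as.integer(vocab_size),
                 silence_run_mean = silence_run_mean),
            class = "class_params")
}

#' Synthetic cohort specification
#'
#' Defaults emulate the clinical study design this package targets: 10 CH +
#' 10 AD subjects with 6 one-minute neuropsychological-test responses each
#' (120 sequences), with strongly separated class parameters.
#'
#' @param n_subjects_per_class subjects per class (default 10).
#' @param tests_per_subject tests (sequences) per subject (default 6).
#' @param ch,ad [class_params()] for the cognitively-healthy and AD class.
#' @param seed integer RNG seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_class = 10, tests_per_subject = 6,
                        ch = class_params(mean_length = 150, length_sd = 20,
                                          silence_prob = 0.05,
                                          repeat_prob = 0.05,
                                          vocab_size = 100),
                        ad = class_params(mean_length = 60, length_sd = 12,
                                          silence_prob = 0.30,
                                          repeat_prob = 0.20,
                                          vocab_size = 30),
                        seed = 1) {
  stopifnot(n_subjects_per_class >= 1, tests_per_subject >= 1)
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 tests_per_subject = as.integer(tests_per_subject),
                 ch = ch, ad = ad, seed = as.integer(seed)),
            class = "cohort_spec")
}

test_type_cycle <- c("fluency_animal", "fluency_fruit", "picture_1",
                     "picture_2", "logical_1", "logical_2")

draw_sequence <- function(cp, inventory) {
  len <- max(1L, as.integer(round(rnorm(1, cp$mean_length, cp$length_sd))))
  if (cp$vocab_size > length(inventory$syllables)) {
    stop("vocab_size ", cp$vocab_size, " exceeds the ",
         length(inventory$syllables), " syllables in the inventory")
  }
  sil <- inventory$silence_id
  toks <- integer(len)
  t <- 1L
  while (t <= len) {
    u <- runif(1)
    if (t > 1L && u < cp$repeat_prob) {
      toks[t] <- toks[t - 1L]
      t <- t + 1L
    } else if (u < cp$repeat_prob + cp$silence_prob) {
      run <- 1L + if (cp$silence_run_mean > 1)
        rgeom(1, 1 / cp$silence_run_mean) else 0L
      run <- min(run, len - t + 1L)
      toks[t:(t + run - 1L)] <- sil
      t <- t + run
    } else {
      toks[t] <- sample.int(cp$vocab_size, 1) - 1L
      t <- t + 1L
    }
  }
  toks
}

#' Generate a labelled synthetic cohort of Feature Sequences
#'
#' Draws `n_subjects_per_class x 2 x tests_per_subject` sequences
#' (deterministic for a fixed `spec$seed`), labelling CH as 0 and AD as 1
#' and cycling the six neuropsychological test types across each subject's
#' samples.
#'
#' @param spec a [cohort_spec()].
#' @param inventory the [token_inventory()] to draw from.
#' @return list with `sequences` (list of labelled [feature_sequence()])
#'   and `manifest` (data frame: id, subject, test_type, label).
#' @export
generate_cohort <- function(spec, inventory) {
  set.seed(spec$seed)
  sequences <- list()
  rows <- list()
  for (cls in 0:1) {
    cp <- if (cls == 0) spec$ch else spec$ad
    cls_tag <- if (cls == 0) "CH" else "AD"
    for (subj in seq_len(spec$n_subjects_per_class)) {
      for (test in seq_len(spec$tests_per_subject)) {
        id <- sprintf("%s%02d_t%d", cls_tag, subj, test)
        toks <- draw_sequence(cp, inventory)
        sequences[[length(sequences) + 1]] <-
          feature_sequence(toks, inventory, sample_id = id, label = cls)
        rows[[length(rows) + 1]] <- data.frame(
          id = id, subject = sprintf("%s%02d", cls_tag, subj),
          test_type = test_type_cycle[(test - 1) %% length(test_type_cycle) + 1],
          label = cls)
      }
    }
  }
  list(sequences = sequences, manifest = do.call(rbind, rows))
}

#' Transcription-error corruption model
#'
#' Emulates automatic-transcription errors on a Feature Sequence:
#' independent per-token substitution and deletion, plus geometric
#' insertions after each surviving token.
#'
#' @param substitution_prob,insertion_prob,deletion_prob per-token error
#'   probabilities; `substitution_prob + deletion_prob` must not exceed 1.
#' @param seed integer RNG seed.
#' @return a list of class `corruption_spec`.
#' @export
corruption_spec <- function(substitution_prob = 0, insertion_prob = 0,
                            deletion_prob = 0, seed = 1) {
  for (p in c(substitution_prob, insertion_prob, deletion_prob)) {
    if (p < 0 || p > 1) stop("corruption probabilities must lie in [0,1]")
  }
  if (substitution_prob + deletion_prob > 1) {
    stop("substitution_prob + deletion_prob must not exceed 1")
  }
  if (insertion_prob >= 1) stop("insertion_prob must be < 1")
  structure(list(substitution_prob = substitution_prob,
                 insertion_prob = insertion_prob,
                 deletion_prob = deletion_prob, seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a Feature Sequence
#'
#' @param seq a [feature_sequence()].
#' @param cspec a [corruption_spec()].
#' @param inventory the [token_inventory()].
#' @param seed RNG seed; defaults to `cspec$seed`. Pass `NULL` to continue
#'   from the current RNG state (used when corrupting many sequences under
#'   one outer seed).
#' @return the corrupted [feature_sequence()] (same id and label).
#' @export
corrupt_sequence <- function(seq, cspec, inventory, seed = cspec$seed) {
  if (!is.null(seed)) set.seed(seed)
  out <- integer(0)
  V <- inventory$size
  for (tok in seq$tokens) {
    u <- runif(1)
    if (u < cspec$substitution_prob) {
      repl <- sample.int(V, 1) - 1L
      if (repl == tok) repl <- (repl + 1L) %% V
      out <- c(out, repl)
    } else if (u < cspec$substitution_prob + cspec$deletion_prob) {
      # deleted
    } else {
      out <- c(out, tok)
    }
    if (cspec$insertion_prob > 0) {
      k <- rgeom(1, 1 - cspec$insertion_prob)
      if (k > 0) out <- c(out, sample.int(V, k) - 1L)
    }
  }
  feature_sequence(out, inventory, sample_id = seq$sample_id,
                   label = seq$label)
}

#' Corrupt every sequence of a cohort under one seed
#'
#' @param sequences list of [feature_sequence()] objects.
#' @inheritParams corrupt_sequence
#' @return list of corrupted sequences.
#' @export
corrupt_cohort <- function(sequences, cspec, inventory, seed = cspec$seed) {
  set.seed(seed)
  lapply(sequences, corrupt_sequence, cspec = cspec, inventory = inventory,
         seed = NULL)
}

#' Evenly spaced sinusoid frequencies for toy audio
#'
#' @param inventory the [token_inventory()].
#' @param base_freq frequency of syllable id 0 (Hz).
#' @param step frequency spacing between consecutive syllable ids (Hz).
#' @return numeric vector of length `length(inventory$syllables)`.
#' @export
make_tone_map <- function(inventory, base_freq = 400, step = 300) {
  base_freq + step * (seq_along(inventory$syllables) - 1)
}

#' Toy audio with known token alignments
#'
#' Renders a Feature Sequence as a concatenation of fixed-duration pure
#' tones (one distinct frequency per syllable token) with additive
#' Gaussian noise; silence tokens render as noise only. Also returns the
#' ground-truth per-frame token labels at the front-end's frame rate, for
#' CTC sanity tests and toy transcriber training.
#'
#' @param seq a [feature_sequence()].
#' @param inventory the [token_inventory()].
#' @param tone_freqs numeric vector mapping syllable id `i` (0-based) to
#'   `tone_freqs[i+1]` Hz; every non-silence token in `seq` must be mapped
#'   and below the Nyquist frequency.
#' @param token_dur_s duration of each token (default 0.1 s).
#' @param sample_rate sampling rate in Hz (default 8000).
#' @param noise_sd additive noise standard deviation (default 0.01).
#' @param win_s,hop_s frame parameters used for the returned alignment
#'   (defaults match [log_filterbank()]).
#' @return list with `waveform`, `sample_rate`, `frame_labels` (0-based
#'   token id per frame; silence frames carry the silence id) and
#'   `alignment` (data frame: token, start_s, end_s).
#' @export
generate_toy_audio <- function(seq, inventory, tone_freqs = make_tone_map(inventory),
                               token_dur_s = 0.1, sample_rate = 8000,
                               noise_sd = 0.01, win_s = 0.025, hop_s = 0.010) {
  n_tok <- seq$length
  spt <- round(token_dur_s * sample_rate)  # samples per token
  if (n_tok == 0) {
    return(list(waveform = numeric(0), sample_rate = sample_rate,
                frame_labels = integer(0),
                alignment = data.frame(token = integer(0), start_s = numeric(0),
                                       end_s = numeric(0))))
  }
  sil <- inventory$silence_id
  pieces <- vector("list", n_tok)
  for (i in seq_len(n_tok)) {
    tok <- seq$tokens[i]
    tt <- (seq_len(spt) - 1) / sample_rate
    if (tok == sil) {
      pieces[[i]] <- rnorm(spt, sd = noise_sd)
    } else {
      if (tok + 1 > length(tone_freqs) || is.na(tone_freqs[tok + 1])) {
        stop("token id ", tok, " has no tone frequency mapping")
      }
      f <- tone_freqs[tok + 1]
      if (f >= sample_rate / 2) {
        stop("tone frequency ", f, " Hz is at or above Nyquist (",
             sample_rate / 2, " Hz)")
      }
      pieces[[i]] <- 0.5 * sin(2 * pi * f * tt) + rnorm(spt, sd = noise_sd)
    }
  }
  waveform <- unlist(pieces)
  win <- round(win_s * sample_rate)
  hop <- round(hop_s * sample_rate)
  n_frames <- if (length(waveform) >= win)
    floor((length(waveform) - win) / hop) + 1 else 0L
  centers <- ((seq_len(n_frames) - 1) * hop + win / 2) / sample_rate
  tok_idx <- pmin(floor(centers / token_dur_s) + 1, n_tok)
  list(waveform = waveform, sample_rate = sample_rate,
       frame_labels = seq$tokens[tok_idx],
       alignment = data.frame(token = seq$tokens,
                              start_s = (seq_len(n_tok) - 1) * token_dur_s,
                              end_s = seq_len(n_tok) * token_dur_s))
}

#' Toy CTC training set
#'
#' Draws random token sequences over a (small) inventory and renders each
#' with [generate_toy_audio()], producing items directly consumable by
#' [train_generator()].
#'
#' @param inventory a small [token_inventory()].
#' @param n_utterances number of items.
#' @param tokens_per_utt tokens per item (non-silence only).
#' @param seed integer RNG seed.
#' @inheritParams generate_toy_audio
#' @return list of items `list(waveform, sample_rate, tokens)` where
#'   `tokens` is a [feature_sequence()].
#' @export
generate_toy_ctc_data <- function(inventory, n_utterances = 20,
                                  tokens_per_utt = 4, token_dur_s = 0.1,
                                  sample_rate = 8000, noise_sd = 0.01,
                                  seed = 1) {
  set.seed(seed)
  n_syll <- length(inventory$syllables)
  lapply(seq_len(n_utterances), function(i) {
    toks <- sample.int(n_syll, tokens_per_utt, replace = TRUE) - 1L
    fs <- feature_sequence(toks, inventory,
                           sample_id = sprintf("toy%03d", i))
    audio <- generate_toy_audio(fs, inventory, token_dur_s = token_dur_s,
                                sample_rate = sample_rate,
                                noise_sd = noise_sd)
    list(waveform = audio$waveform, sample_rate = audio$sample_rate,
         tokens = fs, frame_labels = audio$frame_labels)
  })
}
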