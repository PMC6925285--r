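#' Feature Sequence Generator configuration
#'
#' The transcriber is a convolutional recurrent network: a stack of 2D
#' convolutions over the (time x mel-bin) feature map, each with
#' batch normalisation before a clipped-ReLU activation, followed by a stack
#' of bidirectional GRU layers with per-frame layer normalisation on each
#' layer's input, and a fully-connected softmax layer with
#' `inventory size + 1` outputs (the extra class is the CTC blank).
#'
#' Defaults reproduce the reference architecture: conv filters 32/32/96
#' with kernels (11,41)/(11,21)/(11,21), five biGRU layers of 512 cells per
#' direction. Time strides default to 1 so one output frame corresponds to
#' one 10 ms input hop and the silence-threshold arithmetic
#' (`threshold / 0.01`) holds exactly; frequency strides of 2 reduce the
#' spectral width. All of it is configurable, and the decode recomputes its
#' blank-run threshold from `effective_frame_s` if time strides change.
#'
#' @param conv_specs list of conv layer specs, each
#'   `list(filters =, kernel = c(time, freq), stride = c(time, freq))`.
#' @param rnn_layers number of recurrent layers (default 5).
#' @param rnn_cells GRU cells per direction (default 512).
#' @param bidirectional logical (default TRUE).
#' @param n_bins input mel bins (default 80).
#' @param win_s,hop_s front-end window and hop in seconds.
#' @param relu_cap clipped-ReLU ceiling (default 20).
#' @param bn_eps,ln_eps numerical-stability constants for the
#'   normalisations.
#' @return a list of class `generator_config` with derived field
#'   `effective_frame_s = hop_s * prod(time strides)`.
#' @export
generator_config <- function(conv_specs = list(
                               list(filters = 32, kernel = c(11, 41), stride = c(1, 2)),
                               list(filters = 32, kernel = c(11, 21), stride = c(1, 2)),
                               list(filters = 96, kernel = c(11, 21), stride = c(1, 2))),
                             rnn_layers = 5, rnn_cells = 512,
                             bidirectional = TRUE, n_bins = 80,
                             win_s = 0.025, hop_s = 0.010,
                             relu_cap = 20, bn_eps = 1e-5, ln_eps = 1e-5) {
  stopifnot(length(conv_specs) >= 1, rnn_layers >= 1, rnn_cells >= 1,
            n_bins >= 1, hop_s > 0, win_s > 0)
  for (cs in conv_specs) {
    stopifnot(cs$filters >= 1, length(cs$kernel) == 2, length(cs$stride) == 2,
              all(cs$stride >= 1))
  }
  time_strides <- vapply(conv_specs, function(cs) cs$stride[1], numeric(1))
  structure(list(conv_specs = conv_specs,
                 rnn_layers = as.integer(rnn_layers),
                 rnn_cells = as.integer(rnn_cells),
                 bidirectional = bidirectional,
                 n_bins = as.integer(n_bins),
                 win_s = win_s, hop_s = hop_s,
                 relu_cap = relu_cap, bn_eps = bn_eps, ln_eps = ln_eps,
                 effective_frame_s = hop_s * prod(time_strides)),
            class = "generator_config")
}

#' Generator training configuration (CTC)
#'
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param grad_clip maximum allowed global gradient L2 norm (default 400).
#' @param batch_size utterances per iteration (default 32).
#' @param iterations number of batch updates (default 50000; scale down for
#'   desk-scale runs).
#' @param max_utterance_s utterances longer than this are removed before
#'   batching (default 10 s).
#' @param seed integer RNG seed.
#' @return a list of class `generator_train_config`.
#' @export
generator_train_config <- function(learning_rate = 5e-4, grad_clip = 400,
                                   batch_size = 32, iterations = 50000,
                                   max_utterance_s = 10, seed = 1) {
  stopifnot(learning_rate > 0, grad_clip > 0, batch_size >= 1,
            iterations >= 1, max_utterance_s > 0)
  structure(list(learning_rate = learning_rate, grad_clip = grad_clip,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 max_utterance_s = max_utterance_s, seed = as.integer(seed)),
            class = "generator_train_config")
}

# Spectral width and flattened per-frame feature size after the conv stack.
conv_out_dims <- function(config) {
  f <- config$n_bins
  for (cs in config$conv_specs) f <- ceiling(f / cs$stride[2])
  c_last <- config$conv_specs[[length(config$conv_specs)]]$filters
  list(freq = f, channels = c_last, flat = f * c_last)
}

#' Initialise an (untrained) Feature Sequence Generator
#'
#' @param inventory the [token_inventory()]; the output layer has
#'   `inventory$size + 1` classes (the last is the CTC blank).
#' @param config a [generator_config()].
#' @param seed RNG seed for Glorot-normal initialisation.
#' @return an object of class `fs_generator`.
#' @export
init_generator <- function(inventory, config = generator_config(), seed = 1) {
  set.seed(seed)
  params <- list()
  bn_mean <- list()
  bn_var <- list()
  c_in <- 1L
  for (i in seq_along(config$conv_specs)) {
    cs <- config$conv_specs[[i]]
    kt <- cs$kernel[1]; kf <- cs$kernel[2]; co <- cs$filters
    fan_in <- kt * kf * c_in
    fan_out <- kt * kf * co
    W <- array(rnorm(kt * kf * c_in * co, sd = sqrt(2 / (fan_in + fan_out))),
               dim = c(kt, kf, c_in * co))
    params[[paste0("conv", i, "_W")]] <- W
    params[[paste0("conv", i, "_b")]] <- numeric(co)
    params[[paste0("conv", i, "_gamma")]] <- rep(1, co)
    params[[paste0("conv", i, "_beta")]] <- numeric(co)
    bn_mean[[i]] <- numeric(co)
    bn_var[[i]] <- rep(1, co)
    c_in <- co
  }
  H <- config$rnn_cells
  d_in <- conv_out_dims(config)$flat
  for (l in seq_len(config$rnn_layers)) {
    params[[paste0("ln", l, "_g")]] <- rep(1, d_in)
    params[[paste0("ln", l, "_b")]] <- numeric(d_in)
    dirs <- if (config$bidirectional) c("f", "b") else "f"
    for (d in dirs) {
      params[[paste0("gru", l, d, "_Wx")]] <- glorot_normal(3 * H, d_in)
      params[[paste0("gru", l, d, "_Wh")]] <- glorot_normal(3 * H, H)
      params[[paste0("gru", l, d, "_b")]] <- numeric(3 * H)
    }
    d_in <- if (config$bidirectional) 2L * H else H
  }
  n_classes <- inventory$size + 1L
  params$out_W <- glorot_normal(n_classes, d_in)
  params$out_b <- numeric(n_classes)
  structure(list(params = params, bn_mean = bn_mean, bn_var = bn_var,
                 config = config, inv_size = inventory$size,
                 blank_id = inventory$size,
                 inv_hash = inventory_hash(inventory)),
            class = "fs_generator")
}

#' @export
print.fs_generator <- function(x, ...) {
  cat("<fs_generator> ", length(x$config$conv_specs), " conv + ",
      x$config$rnn_layers, "x", x$config$rnn_cells,
      if (x$config$bidirectional) " biGRU" else " GRU", ", ",
      x$inv_size + 1L, " output classes, ",
      param_count(x$params), " parameters\n", sep = "")
  invisible(x)
}

# Layer norm over the feature dimension of each frame (columns of X).
layernorm_fwd <- function(X, g, b, eps) {
  mu <- colMeans(X)
  centered <- sweep(X, 2, mu)
  v <- colMeans(centered^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(centered, 2, inv_sd, `*`)
  list(Y = xhat * g + b, xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  dxhat <- dY * g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dX <- sweep(dX, 2, cache$inv_sd, `*`)
  list(dX = dX, dg = rowSums(dY * xhat), db = rowSums(dY))
}

# Full forward pass: CMVN features (frames x bins) -> logits (frames' x classes).
generator_forward <- function(model, feat, training = FALSE) {
  cfg <- model$config
  X <- array(unclass(feat), dim = c(nrow(feat), ncol(feat), 1L))
  conv_caches <- vector("list", length(cfg$conv_specs))
  conv_inputs <- vector("list", length(cfg$conv_specs))
  for (i in seq_along(cfg$conv_specs)) {
    cs <- cfg$conv_specs[[i]]
    conv_inputs[[i]] <- X
    res <- .conv_bn_relu_fwd_cpp(
      X, model$params[[paste0("conv", i, "_W")]],
      model$params[[paste0("conv", i, "_b")]],
      cs$filters, cs$stride[1], cs$stride[2],
      model$params[[paste0("conv", i, "_gamma")]],
      model$params[[paste0("conv", i, "_beta")]],
      training, model$bn_mean[[i]], model$bn_var[[i]],
      cfg$bn_eps, cfg$relu_cap)
    conv_caches[[i]] <- res
    X <- res$Y
  }
  To <- dim(X)[1]
  Xseq <- t(matrix(X, nrow = To))  # flat features x frames
  rnn_caches <- vector("list", cfg$rnn_layers)
  for (l in seq_len(cfg$rnn_layers)) {
    ln <- layernorm_fwd(Xseq, model$params[[paste0("ln", l, "_g")]],
                        model$params[[paste0("ln", l, "_b")]], cfg$ln_eps)
    fw <- .gru_dense_fwd_cpp(ln$Y, model$params[[paste0("gru", l, "f_Wx")]],
                             model$params[[paste0("gru", l, "f_Wh")]],
                             model$params[[paste0("gru", l, "f_b")]], FALSE)
    if (cfg$bidirectional) {
      bw <- .gru_dense_fwd_cpp(ln$Y, model$params[[paste0("gru", l, "b_Wx")]],
                               model$params[[paste0("gru", l, "b_Wh")]],
                               model$params[[paste0("gru", l, "b_b")]], TRUE)
      Y <- rbind(fw$Y, bw$Y)
    } else {
      bw <- NULL
      Y <- fw$Y
    }
    rnn_caches[[l]] <- list(X_in = Xseq, ln = ln, fw = fw, bw = bw)
    Xseq <- Y
  }
  logits <- t(model$params$out_W %*% Xseq + model$params$out_b)  # frames x classes
  list(logits = logits, H_last = Xseq, conv_caches = conv_caches,
       conv_inputs = conv_inputs, rnn_caches = rnn_caches, n_frames_out = To)
}

# Backward pass from d(logits) (frames x classes); returns gradient list
# matching model$params.
generator_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  grads <- list()
  dZ <- t(dlogits)  # classes x frames
  grads$out_W <- dZ %*% t(fwd$H_last)
  grads$out_b <- rowSums(dZ)
  dH <- t(model$params$out_W) %*% dZ
  H <- cfg$rnn_cells
  for (l in rev(seq_len(cfg$rnn_layers))) {
    cc <- fwd$rnn_caches[[l]]
    if (cfg$bidirectional) {
      dYf <- dH[seq_len(H), , drop = FALSE]
      dYb <- dH[H + seq_len(H), , drop = FALSE]
    } else {
      dYf <- dH
      dYb <- NULL
    }
    bf <- .gru_dense_bwd_cpp(cc$ln$Y, model$params[[paste0("gru", l, "f_Wx")]],
                             model$params[[paste0("gru", l, "f_Wh")]],
                             cc$fw, dYf, FALSE)
    grads[[paste0("gru", l, "f_Wx")]] <- bf$dWx
    grads[[paste0("gru", l, "f_Wh")]] <- bf$dWh
    grads[[paste0("gru", l, "f_b")]] <- as.numeric(bf$db)
    dLnY <- bf$dX
    if (cfg$bidirectional) {
      bb <- .gru_dense_bwd_cpp(cc$ln$Y, model$params[[paste0("gru", l, "b_Wx")]],
                               model$params[[paste0("gru", l, "b_Wh")]],
                               cc$bw, dYb, TRUE)
      grads[[paste0("gru", l, "b_Wx")]] <- bb$dWx
      grads[[paste0("gru", l, "b_Wh")]] <- bb$dWh
      grads[[paste0("gru", l, "b_b")]] <- as.numeric(bb$db)
      dLnY <- dLnY + bb$dX
    }
    lb <- layernorm_bwd(cc$ln, model$params[[paste0("ln", l, "_g")]], dLnY)
    grads[[paste0("ln", l, "_g")]] <- lb$dg
    grads[[paste0("ln", l, "_b")]] <- lb$db
    dH <- lb$dX
  }
  To <- fwd$n_frames_out
  dX <- array(t(dH), dim = dim(fwd$conv_caches[[length(cfg$conv_specs)]]$Y))
  for (i in rev(seq_along(cfg$conv_specs))) {
    cs <- cfg$conv_specs[[i]]
    res <- .conv_bn_relu_bwd_cpp(
      fwd$conv_inputs[[i]], model$params[[paste0("conv", i, "_W")]],
      cs$filters, cs$stride[1], cs$stride[2],
      model$params[[paste0("conv", i, "_gamma")]],
      fwd$conv_caches[[i]], dX, cfg$bn_eps, cfg$relu_cap)
    grads[[paste0("conv", i, "_W")]] <- res$dW
    grads[[paste0("conv", i, "_b")]] <- as.numeric(res$db)
    grads[[paste0("conv", i, "_gamma")]] <- as.numeric(res$dgamma)
    grads[[paste0("conv", i, "_beta")]] <- as.numeric(res$dbeta)
    dX <- res$dX
  }
  grads
}

#' CTC forward loss
#'
#' Negative log probability, under the frame-level posteriors, of all frame
#' paths that collapse to the target sequence (computed in the log domain
#' with the standard alpha recursion over the blank-extended target). The
#' target is the reference Feature Sequence *without* silence tokens:
#' silence is not a CTC label; it is recovered at decode time from long
#' blank runs.
#'
#' @param log_posteriors frames x classes matrix of log probabilities
#'   (classes include the blank).
#' @param target integer vector of 0-based token ids, or a
#'   [feature_sequence()]; must not contain `blank_id`.
#' @param blank_id 0-based id of the blank class.
#' @return non-negative scalar loss; `Inf` when the target is infeasible
#'   for the number of frames (more required emissions than frames).
#' @export
ctc_forward_loss <- function(log_posteriors, target, blank_id) {
  if (inherits(target, "feature_sequence")) target <- target$tokens
  target <- as.integer(target)
  if (any(target == blank_id)) {
    stop("target contains the blank id (", blank_id,
         "); blank is not part of the token space")
  }
  if (length(target) > 0 &&
      (min(target) < 0 || max(target) >= ncol(log_posteriors))) {
    stop("target ids outside [0, n_classes)")
  }
  .ctc_loss_cpp(log_posteriors, target, as.integer(blank_id))
}

#' Greedy frame path
#'
#' Per-frame argmax over the posterior classes; ties break to the lowest
#' class id.
#'
#' @param log_posteriors frames x classes matrix (any monotone transform of
#'   the posteriors works).
#' @return integer vector of 0-based class ids, one per frame (class
#'   `frame_path`, with attribute `n_classes`).
#' @export
frame_argmax <- function(log_posteriors) {
  if (nrow(log_posteriors) == 0) {
    return(structure(integer(0), class = "frame_path",
                     n_classes = ncol(log_posteriors)))
  }
  ids <- max.col(log_posteriors, ties.method = "first") - 1L
  structure(ids, class = "frame_path", n_classes = ncol(log_posteriors))
}

#' Minimum blank-run length for a silence token
#'
#' A maximal run of CTC blanks is transcribed as one silence token only if
#' it is at least `threshold_s` seconds long. With one decoded frame per
#' `effective_frame_s` seconds this is `ceiling(threshold_s /
#' effective_frame_s)` frames; at the default 10 ms frame rate a 3 s
#' threshold gives 300 consecutive blanks.
#'
#' @param threshold_s silence threshold in seconds (> 0).
#' @param effective_frame_s seconds per decoded frame (> 0).
#' @return integer minimum run length `N`.
#' @export
silence_run_threshold <- function(threshold_s, effective_frame_s = 0.01) {
  if (!is.finite(threshold_s) || threshold_s <= 0) {
    stop("threshold_s must be positive")
  }
  if (!is.finite(effective_frame_s) || effective_frame_s <= 0) {
    stop("effective_frame_s must be positive")
  }
  as.integer(ceiling(threshold_s / effective_frame_s))
}

#' Collapse a greedy frame path into a Feature Sequence
#'
#' Applies the decode rules in order: (i) each maximal run of at least `N`
#' consecutive blanks emits exactly one silence token; (ii) shorter blank
#' runs are dropped (but still separate repeated tokens, preserving CTC
#' semantics); (iii) runs of identical non-blank labels merge to a single
#' token. The output never contains the blank.
#'
#' @param path integer vector of 0-based per-frame class ids (e.g. from
#'   [frame_argmax()]); ids equal to `blank_id` are blanks.
#' @param N minimum blank-run length from [silence_run_threshold()].
#' @param inventory the [token_inventory()].
#' @param blank_id 0-based blank class id (default `inventory$size`).
#' @inheritParams feature_sequence
#' @return a [feature_sequence()].
#' @export
collapse_to_feature_sequence <- function(path, N, inventory,
                                         blank_id = inventory$size,
                                         sample_id = NA_character_,
                                         label = NULL) {
  N <- as.integer(N)
  if (N < 1) stop("N must be >= 1")
  path <- as.integer(path)
  if (length(path) == 0) {
    return(feature_sequence(integer(0), inventory, sample_id, label))
  }
  runs <- rle(path)
  out <- integer(0)
  for (i in seq_along(runs$values)) {
    v <- runs$values[i]
    if (v == blank_id) {
      if (runs$lengths[i] >= N) out <- c(out, inventory$silence_id)
    } else {
      out <- c(out, v)
    }
  }
  feature_sequence(out, inventory, sample_id = sample_id, label = label)
}

#' Train the Feature Sequence Generator with CTC
#'
#' Each item supplies a waveform and its reference token sequence; silence
#' tokens are stripped from references (silence is recovered from blank
#' runs at decode time, not modelled as a CTC label). Utterances longer
#' than `train_config$max_utterance_s` are removed before batching, with a
#' message reporting the count. Features are extracted once
#' ([log_filterbank()] + [cmvn()]); each iteration draws a batch, sums the
#' CTC losses, clips the global gradient norm, and takes an Adam step.
#' Deterministic for a fixed seed.
#'
#' @param data list of items `list(waveform =, sample_rate =, tokens =)`
#'   where `tokens` is a [feature_sequence()] or 0-based id vector.
#' @param inventory the [token_inventory()].
#' @param config a [generator_config()].
#' @param train_config a [generator_train_config()].
#' @return list with `model` (an `fs_generator`) and `history` (data frame
#'   of per-iteration mean batch loss).
#' @export
train_generator <- function(data, inventory, config = generator_config(),
                            train_config = generator_train_config()) {
  if (length(data) == 0) stop("empty training data")
  durations <- vapply(data, function(d) length(d$waveform) / d$sample_rate,
                      numeric(1))
  keep <- durations <= train_config$max_utterance_s
  if (sum(!keep) > 0) {
    message("removed ", sum(!keep), " utterance(s) over ",
            train_config$max_utterance_s, " s")
  }
  data <- data[keep]
  if (length(data) == 0) {
    stop("no utterances remain after the ", train_config$max_utterance_s,
         " s duration filter")
  }
  model <- init_generator(inventory, config, seed = train_config$seed)
  feats <- lapply(data, function(d) {
    cmvn(log_filterbank(d$waveform, d$sample_rate, n_bins = config$n_bins,
                        win_s = config$win_s, hop_s = config$hop_s))
  })
  targets <- lapply(data, function(d) {
    toks <- if (inherits(d$tokens, "feature_sequence")) d$tokens$tokens
            else as.integer(d$tokens)
    toks[toks != inventory$silence_id]
  })
  params <- model$params
  opt <- adam_init(params)
  n <- length(data)
  bn_momentum <- 0.9
  history <- numeric(train_config$iterations)
  for (iter in seq_len(train_config$iterations)) {
    idx <- sample.int(n, min(train_config$batch_size, n),
                      replace = n < train_config$batch_size)
    grads <- NULL
    batch_loss <- 0
    for (i in idx) {
      model$params <- params
      fwd <- generator_forward(model, feats[[i]], training = TRUE)
      ctc <- .ctc_grad_cpp(fwd$logits, targets[[i]], model$blank_id)
      if (!is.finite(ctc$loss)) {
        stop("infeasible CTC target for item ", i,
             " (target longer than the frames permit)")
      }
      batch_loss <- batch_loss + ctc$loss
      grads <- add_grads(grads, generator_backward(model, fwd, ctc$grad))
      for (ci in seq_along(config$conv_specs)) {
        cc <- fwd$conv_caches[[ci]]
        model$bn_mean[[ci]] <- bn_momentum * model$bn_mean[[ci]] +
          (1 - bn_momentum) * as.numeric(cc$mean)
        model$bn_var[[ci]] <- bn_momentum * model$bn_var[[ci]] +
          (1 - bn_momentum) * as.numeric(cc$var)
      }
    }
    grads <- clip_global_norm(grads, train_config$grad_clip)
    upd <- adam_step(params, grads, opt, lr = train_config$learning_rate)
    params <- upd$params
    opt <- upd$state
    history[iter] <- batch_loss / length(idx)
  }
  model$params <- params
  list(model = model,
       history = data.frame(iteration = seq_len(train_config$iterations),
                            loss = history))
}

#' Transcribe audio into a Feature Sequence
#'
#' Runs the front-end ([log_filterbank()] + [cmvn()]), the trained
#' generator, greedy decoding ([frame_argmax()]) and the blank-run collapse
#' ([collapse_to_feature_sequence()]).
#'
#' @param model a trained `fs_generator`.
#' @param waveform numeric audio samples.
#' @param sample_rate sampling rate in Hz.
#' @param silence_threshold_s minimum silence duration (seconds) for a
#'   blank run to become a silence token (default 3).
#' @param inventory the [token_inventory()]; must match the model's
#'   inventory hash.
#' @inheritParams feature_sequence
#' @return a [feature_sequence()].
#' @export
transcribe_waveform <- function(model, waveform, sample_rate, inventory,
                                silence_threshold_s = 3,
                                sample_id = NA_character_) {
  if (inventory_hash(inventory) != model$inv_hash) {
    stop("inventory hash mismatch: this checkpoint was trained on a ",
         "different token space")
  }
  cfg <- model$config
  feat <- cmvn(log_filterbank(waveform, sample_rate, n_bins = cfg$n_bins,
                              win_s = cfg$win_s, hop_s = cfg$hop_s))
  fwd <- generator_forward(model, feat, training = FALSE)
  path <- frame_argmax(fwd$logits)
  N <- silence_run_threshold(silence_threshold_s, cfg$effective_frame_s)
  collapse_to_feature_sequence(path, N, inventory,
                               blank_id = model$blank_id,
                               sample_id = sample_id)
}
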