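#' Assessment engine configuration
#'
#' The AD Assessment Engine is a single-layer recurrent classifier: token
#' ids enter as one-hot vectors (realised as a column lookup into the input
#' weight matrix), a recurrent layer encodes the sequence, and a
#' fully-connected sigmoid head maps the final-timestep output to a score in
#' (0, 1). In the bidirectional setup the final output of each direction is
#' concatenated before the head. Defaults follow the total-cell-budget
#' convention used when comparing directionalities: 256 cells
#' unidirectional, 128 per direction bidirectional.
#'
#' @param cell_type one of `"gru"`, `"lstm"`, `"simple"`.
#' @param bidirectional logical.
#' @param cells_per_direction hidden size per direction; if `NULL`, 128 when
#'   bidirectional, 256 otherwise.
#' @return a list of class `engine_config`.
#' @export
engine_config <- function(cell_type = c("gru", "lstm", "simple"),
                          bidirectional = TRUE, cells_per_direction = NULL) {
  cell_type <- match.arg(cell_type)
  if (is.null(cells_per_direction)) {
    cells_per_direction <- if (bidirectional) 128L else 256L
  }
  stopifnot(cells_per_direction >= 1)
  structure(list(cell_type = cell_type, bidirectional = bidirectional,
                 cells_per_direction = as.integer(cells_per_direction)),
            class = "engine_config")
}

#' Engine training configuration
#'
#' Training minimises the cross-entropy *sum* over each batch of labelled
#' sequences with Adam; weights are Glorot-normal initialised; early
#' stopping keeps the parameters from the epoch with the lowest validation
#' loss and halts after `patience` epochs without improvement.
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size sequences per update (default 16).
#' @param patience early-stopping patience in epochs (default 20).
#' @param max_epochs hard cap on epochs so runs always terminate
#'   (default 500).
#' @param seed integer RNG seed controlling init and batch order.
#' @return a list of class `engine_train_config`.
#' @export
engine_train_config <- function(learning_rate = 0.001, batch_size = 16,
                                patience = 20, max_epochs = 500, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "engine_train_config")
}

n_gates <- function(cell_type) {
  switch(cell_type, gru = 3L, lstm = 4L, simple = 1L)
}

#' Initialise an (untrained) assessment engine
#'
#' @param inventory the [token_inventory()] the engine scores sequences
#'   over.
#' @param config an [engine_config()].
#' @param seed RNG seed for the Glorot-normal initialisation.
#' @return an object of class `ad_engine`.
#' @export
init_engine <- function(inventory, config = engine_config(), seed = 1) {
  set.seed(seed)
  V <- inventory$size
  H <- config$cells_per_direction
  G <- n_gates(config$cell_type)
  H_out <- if (config$bidirectional) 2L * H else H
  params <- list(
    Wx_f = glorot_normal(G * H, V),
    Wh_f = glorot_normal(G * H, H),
    b_f = numeric(G * H)
  )
  if (config$bidirectional) {
    params$Wx_b <- glorot_normal(G * H, V)
    params$Wh_b <- glorot_normal(G * H, H)
    params$b_b <- numeric(G * H)
  }
  params$W_head <- glorot_normal(1, H_out)
  params$b_head <- 0
  structure(list(params = params, config = config,
                 inv_size = inventory$size,
                 inv_hash = inventory_hash(inventory)),
            class = "ad_engine")
}

#' @export
print.ad_engine <- function(x, ...) {
  cat("<ad_engine> ", if (x$config$bidirectional) "bi" else "uni",
      "directional ", x$config$cell_type, ", ",
      x$config$cells_per_direction, " cells/direction, ",
      engine_param_count(x), " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters in an engine
#'
#' @param model an `ad_engine`.
#' @return integer parameter count.
#' @export
engine_param_count <- function(model) {
  param_count(model$params)
}

#' Score a Feature Sequence
#'
#' Computes the AD-likelihood score `sigma(W y_T + b)` where `y_T` is the
#' recurrent encoder's final-timestep output (both directions concatenated
#' for bidirectional models). Higher scores mean higher assessed AD
#' likelihood.
#'
#' @param model a trained or initialised `ad_engine`.
#' @param seq a non-empty [feature_sequence()] over the model's inventory.
#' @return score in (0, 1).
#' @export
score_sequence <- function(model, seq) {
  if (seq$length == 0) stop("cannot score an empty Feature Sequence")
  if (seq$inv_size != model$inv_size) {
    stop("inventory mismatch: sequence uses a token space of size ",
         seq$inv_size, ", model expects ", model$inv_size)
  }
  .engine_score_cpp(seq$tokens, model$params, model$config$cell_type,
                    model$config$bidirectional)
}

#' Pad a batch of Feature Sequences
#'
#' Right-pads token ids to the batch maximum length and returns the mask of
#' genuine positions. Downstream scoring reads each sequence's final output
#' at its true length, so padded positions can never influence `y_T` of
#' either direction.
#'
#' @param seqs non-empty list of [feature_sequence()] objects.
#' @return list with `tokens` (n x max_len integer matrix, 0-padded),
#'   `mask` (logical matrix), `lengths` (integer vector).
#' @export
pad_and_mask <- function(seqs) {
  if (length(seqs) == 0) stop("empty batch")
  lens <- vapply(seqs, function(s) s$length, integer(1))
  max_len <- max(lens)
  tokens <- matrix(0L, nrow = length(seqs), ncol = max_len)
  mask <- matrix(FALSE, nrow = length(seqs), ncol = max_len)
  for (i in seq_along(seqs)) {
    if (lens[i] > 0) {
      tokens[i, seq_len(lens[i])] <- seqs[[i]]$tokens
      mask[i, seq_len(lens[i])] <- TRUE
    }
  }
  list(tokens = tokens, mask = mask, lengths = lens)
}

#' Score a padded batch
#'
#' @param model an `ad_engine`.
#' @param batch output of [pad_and_mask()].
#' @return numeric vector of scores, one per row.
#' @export
score_batch <- function(model, batch) {
  vapply(seq_len(nrow(batch$tokens)), function(i) {
    len <- batch$lengths[i]
    if (len == 0) stop("cannot score an empty Feature Sequence (row ", i, ")")
    .engine_score_cpp(batch$tokens[i, seq_len(len)], model$params,
                      model$config$cell_type, model$config$bidirectional)
  }, numeric(1))
}

seq_label <- function(s) {
  if (is.null(s$label)) stop("sequence '", s$sample_id, "' has no label")
  s$label
}

#' Train the assessment engine
#'
#' Runs Adam on the batch cross-entropy sum, evaluates validation loss each
#' epoch, and returns the parameters from the epoch with the lowest
#' validation loss (early stopping with the configured patience).
#' Deterministic for a fixed `train_config$seed`.
#'
#' @param train_set,val_set non-empty lists of labelled
#'   [feature_sequence()] objects; the training set must contain both
#'   classes.
#' @param inventory the [token_inventory()] in use.
#' @param config an [engine_config()].
#' @param train_config an [engine_train_config()].
#' @return list with `model` (the best `ad_engine`), `history` (data frame
#'   of per-epoch mean train/validation loss), `best_epoch`.
#' @export
train_engine <- function(train_set, val_set, inventory,
                         config = engine_config(),
                         train_config = engine_train_config()) {
  if (length(train_set) == 0 || length(val_set) == 0) {
    stop("training and validation sets must be non-empty")
  }
  y_train <- vapply(train_set, seq_label, integer(1))
  invisible(vapply(val_set, seq_label, integer(1)))
  if (length(unique(y_train)) < 2) {
    stop("training set contains a single class; both CH and AD are required")
  }
  model <- init_engine(inventory, config, seed = train_config$seed)
  params <- model$params
  opt <- adam_init(params)
  cell <- config$cell_type
  bidir <- config$bidirectional

  val_loss_of <- function(p) {
    losses <- vapply(val_set, function(s) {
      sc <- .engine_score_cpp(s$tokens, p, cell, bidir)
      eps <- 1e-12
      -(s$label * log(sc + eps) + (1 - s$label) * log(1 - sc + eps))
    }, numeric(1))
    mean(losses)
  }

  n <- length(train_set)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  history <- vector("list", train_config$max_epochs)

  for (epoch in seq_len(train_config$max_epochs)) {
    order <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = train_config$batch_size)) {
      idx <- order[start:min(start + train_config$batch_size - 1, n)]
      grads <- NULL
      for (i in idx) {
        s <- train_set[[i]]
        res <- .engine_grad_cpp(s$tokens, s$label, params, cell, bidir)
        epoch_loss <- epoch_loss + res$loss
        grads <- add_grads(grads, res$grads)
      }
      upd <- adam_step(params, grads, opt, lr = train_config$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    val_loss <- val_loss_of(params)
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = epoch_loss / n,
                                   val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_config$patience) break
    }
  }
  model$params <- best_params
  list(model = model,
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       best_epoch = best_epoch)
}

#' Save / load engine and generator checkpoints
#'
#' Checkpoints embed the configuration and the inventory hash so a model
#' cannot silently be applied to a different token space.
#'
#' @param model an `ad_engine` or `fs_generator`.
#' @param path checkpoint path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the model object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
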