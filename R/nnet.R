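# Shared neural-network utilities: Glorot-normal initialisation, the Adam
# optimiser over named parameter lists, and global-norm gradient clipping.
# All randomness comes from R's RNG so training is reproducible via set.seed.

glorot_normal <- function(n_rows, n_cols) {
  sd <- sqrt(2 / (n_rows + n_cols))
  matrix(rnorm(n_rows * n_cols, sd = sd), n_rows, n_cols)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Scale the whole gradient so its global L2 norm does not exceed max_norm.
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

param_count <- function(params) {
  sum(vapply(params, length, integer(1)))
}
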