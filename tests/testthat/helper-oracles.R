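# Independent oracles used to validate the package's implementations.

# CTC loss by brute-force enumeration of all classes^frames frame paths:
# sum the probability of every path whose blank-collapse equals the target.
ctc_brute_force <- function(logp, target, blank) {
  T_ <- nrow(logp)
  C <- ncol(logp)
  target <- as.integer(target)
  if (T_ == 0) return(if (length(target) == 0) 0 else Inf)
  grid <- as.matrix(expand.grid(rep(list(0:(C - 1)), T_)))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    coll <- rle(p)$values
    coll <- coll[coll != blank]
    if (length(coll) == length(target) && all(coll == target)) {
      total <- total + exp(sum(logp[cbind(seq_len(T_), p + 1)]))
    }
  }
  if (total == 0) Inf else -log(total)
}

# Edit distance straight from its recursive definition (memoised so length-7
# cases stay fast); independent of the package's iterative DP.
edit_distance_recursive <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1, j) + 1,
             rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (a[i] != b[j]))
    assign(key, v, envir = memo)
    v
  }
  rec(length(a), length(b))
}

# AUROC by explicit positive-negative pair counting with half-credit ties.
auroc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Small fixtures
tiny_inventory <- function(n = 4) {
  token_inventory(letters[seq_len(n)])
}

# A quick, strongly separable labelled set for engine tests.
quick_labelled_set <- function(inv, n_per_class = 8, len = 20, seed = 1) {
  set.seed(seed)
  c(
    lapply(seq_len(n_per_class), function(i) {
      feature_sequence(sample(0:1, len, replace = TRUE), inv,
                       sample_id = paste0("neg", i), label = 0)
    }),
    lapply(seq_len(n_per_class), function(i) {
      feature_sequence(sample(2:3, len, replace = TRUE), inv,
                       sample_id = paste0("pos", i), label = 1)
    })
  )
}
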