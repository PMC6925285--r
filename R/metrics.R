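#' Edit distance between two Feature Sequences
#'
#' Minimal number of unit-cost insertions, deletions and substitutions
#' turning the reference into the hypothesis (Levenshtein distance, dynamic
#' programming). Silence tokens count as ordinary tokens.
#'
#' @param ref,hyp [feature_sequence()] objects over the same inventory, or
#'   plain integer token-id vectors.
#' @return non-negative integer.
#' @export
edit_distance <- function(ref, hyp) {
  a <- seq_tokens(ref)
  b <- seq_tokens(hyp)
  check_same_inventory(ref, hyp)
  .edit_distance_cpp(a, b)
}

seq_tokens <- function(x) {
  if (inherits(x, "feature_sequence")) x$tokens else as.integer(x)
}

check_same_inventory <- function(ref, hyp) {
  if (inherits(ref, "feature_sequence") && inherits(hyp, "feature_sequence") &&
      ref$inv_size != hyp$inv_size) {
    stop("sequences use different inventories (sizes ", ref$inv_size,
         " vs ", hyp$inv_size, ")")
  }
  invisible(NULL)
}

#' Token error rate
#'
#' Edit distance normalized by the reference length; may exceed 1 when the
#' hypothesis carries many insertions.
#'
#' @inheritParams edit_distance
#' @return non-negative real.
#' @export
token_error_rate <- function(ref, hyp) {
  n_ref <- length(seq_tokens(ref))
  if (n_ref == 0) stop("token error rate is undefined for an empty reference")
  edit_distance(ref, hyp) / n_ref
}

#' Length difference
#'
#' Signed token-count difference, `length(hyp) - length(ref)`: negative
#' values mean the hypothesis under-transcribes (is shorter than) the
#' reference. Use `sign = "ref_minus_hyp"` for the opposite convention.
#'
#' @inheritParams edit_distance
#' @param sign which difference to report.
#' @return signed integer.
#' @export
length_difference <- function(ref, hyp, sign = c("hyp_minus_ref", "ref_minus_hyp")) {
  sign <- match.arg(sign)
  d <- length(seq_tokens(hyp)) - length(seq_tokens(ref))
  if (sign == "ref_minus_hyp") -d else d
}

#' Compare a reference and a hypothesis sequence
#'
#' @inheritParams edit_distance
#' @return list with `edit_distance`, `token_error_rate` (NA when the
#'   reference is empty), `length_difference`.
#' @export
compare_sequences <- function(ref, hyp) {
  ed <- edit_distance(ref, hyp)
  n_ref <- length(seq_tokens(ref))
  list(
    edit_distance = ed,
    token_error_rate = if (n_ref > 0) ed / n_ref else NA_real_,
    length_difference = length_difference(ref, hyp)
  )
}

#' Score matched reference/hypothesis sequence sets
#'
#' Computes per-sample edit distance, token error rate and length
#' difference for paired sequences, plus mean and standard-deviation
#' aggregates, optionally within groups (e.g. class or test type).
#'
#' @param refs,hyps equal-length lists of [feature_sequence()] objects,
#'   matched by position.
#' @param group optional character/factor vector of group labels, one per
#'   pair.
#' @return list with `per_sample` (data frame) and `summary` (data frame of
#'   mean and sd per group, or overall when `group` is NULL).
#' @export
score_sequence_sets <- function(refs, hyps, group = NULL) {
  if (length(refs) != length(hyps)) {
    stop("refs and hyps must have the same length")
  }
  rows <- lapply(seq_along(refs), function(i) {
    cmp <- compare_sequences(refs[[i]], hyps[[i]])
    data.frame(id = if (inherits(refs[[i]], "feature_sequence"))
                      refs[[i]]$sample_id else as.character(i),
               edit_distance = cmp$edit_distance,
               token_error_rate = cmp$token_error_rate,
               length_difference = cmp$length_difference)
  })
  per_sample <- do.call(rbind, rows)
  if (is.null(group)) group <- rep("all", nrow(per_sample))
  per_sample$group <- as.character(group)
  agg <- lapply(split(per_sample, per_sample$group), function(d) {
    data.frame(group = d$group[1],
               n = nrow(d),
               ed_mean = mean(d$edit_distance), ed_sd = sd(d$edit_distance),
               ter_mean = mean(d$token_error_rate), ter_sd = sd(d$token_error_rate),
               ld_mean = mean(d$length_difference), ld_sd = sd(d$length_difference))
  })
  list(per_sample = per_sample,
       summary = do.call(rbind, c(agg, list(make.row.names = FALSE))))
}
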