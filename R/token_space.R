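#' Build a closed token inventory
#'
#' The Feature Sequence representation draws every token from a closed
#' vocabulary: a fixed list of base-syllable strings plus one reserved
#' silence token. Token ids are assigned deterministically: syllables keep
#' their list order (ids `0 .. length-1`) and the silence token always takes
#' the last id, so checkpoints trained against an inventory remain valid as
#' long as the syllable list is unchanged. The CTC blank used by the
#' transcriber is *not* part of the inventory; it occupies the extra class
#' `inv$size` in the acoustic model's output layer only.
#'
#' @param syllables character vector of unique base-syllable strings.
#' @param silence_marker string used for the silence token; must not collide
#'   with any syllable. Default `"<sil>"`.
#' @return An object of class `token_inventory` with fields `syllables`,
#'   `silence_token`, `size` (syllable count + 1), `silence_id` (0-based),
#'   and a lookup environment `id_of`.
#' @examples
#' inv <- token_inventory(c("ba", "ma"))
#' inv$size       # 3
#' inv$silence_id # 2
#' @export
token_inventory <- function(syllables, silence_marker = "<sil>") {
  syllables <- as.character(syllables)
  if (length(syllables) == 0) stop("syllable list must be non-empty")
  if (anyNA(syllables)) stop("syllable list contains NA")
  dup <- unique(syllables[duplicated(syllables)])
  if (length(dup) > 0) {
    stop("duplicate syllables in inventory: ", paste(dup, collapse = ", "))
  }
  if (silence_marker %in% syllables) {
    stop("silence marker '", silence_marker, "' collides with a syllable")
  }
  tokens <- c(syllables, silence_marker)
  id_of <- new.env(parent = emptyenv(), size = length(tokens))
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = id_of)
  structure(
    list(
      syllables = syllables,
      silence_token = silence_marker,
      tokens = tokens,
      size = length(tokens),
      silence_id = length(tokens) - 1L,
      id_of = id_of
    ),
    class = "token_inventory"
  )
}

#' @export
print.token_inventory <- function(x, ...) {
  cat("<token_inventory> ", x$size, " tokens (", length(x$syllables),
      " syllables + silence '", x$silence_token, "')\n", sep = "")
  invisible(x)
}

#' Read a token inventory from a plain-text file
#'
#' One syllable per line, UTF-8; blank lines ignored.
#'
#' @param path file path.
#' @param silence_marker silence token string, appended as the last id.
#' @return a [token_inventory()].
#' @export
read_inventory <- function(path, silence_marker = "<sil>") {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  token_inventory(lines[nzchar(lines)], silence_marker)
}

#' The packaged 317-syllable inventory
#'
#' Loads the base-syllable list shipped with the package (317 romanized
#' Mandarin-style base syllables, a synthetic stand-in list; see
#' `inst/extdata/syllables_synthetic_317.txt`) plus the silence token, for a
#' token space of size 318. Any other unit list (another language, phonemes,
#' words) can be used instead via [token_inventory()] or [read_inventory()].
#'
#' @param silence_marker silence token string.
#' @return a [token_inventory()] of size 318.
#' @export
default_inventory <- function(silence_marker = "<sil>") {
  path <- system.file("extdata", "syllables_synthetic_317.txt",
                      package = "adspeech", mustWork = TRUE)
  read_inventory(path, silence_marker)
}

#' Construct a Feature Sequence from token ids
#'
#' A Feature Sequence is the ordered token-id representation
#' `s_1, ..., s_T` of one speech sample. Ids are 0-based and must lie in
#' `[0, inv$size)`; the CTC blank id (`inv$size`) never appears in a Feature
#' Sequence.
#'
#' @param tokens integer vector of 0-based token ids (may be empty).
#' @param inventory the [token_inventory()] the ids refer to.
#' @param sample_id optional sample identifier string.
#' @param label optional class label: 0 = cognitively healthy (CH),
#'   1 = Alzheimer's disease (AD).
#' @return an object of class `feature_sequence`.
#' @export
feature_sequence <- function(tokens, inventory, sample_id = NA_character_,
                             label = NULL) {
  tokens <- as.integer(tokens)
  if (anyNA(tokens)) stop("tokens contain NA")
  if (length(tokens) > 0 && (min(tokens) < 0L || max(tokens) >= inventory$size)) {
    bad <- which(tokens < 0L | tokens >= inventory$size)[1]
    stop("token id ", tokens[bad], " at position ", bad,
         " outside inventory range [0, ", inventory$size, ")")
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    if (!(label %in% c(0L, 1L))) stop("label must be 0 (CH) or 1 (AD)")
  }
  structure(
    list(tokens = tokens, length = length(tokens),
         sample_id = as.character(sample_id), label = label,
         inv_size = inventory$size),
    class = "feature_sequence"
  )
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat("<feature_sequence> id=", x$sample_id, " T=", x$length,
      if (!is.null(x$label)) paste0(" label=", x$label) else "", "\n", sep = "")
  invisible(x)
}

#' Encode token strings into a Feature Sequence
#'
#' @param strings character vector of token strings (syllables or the
#'   silence marker), in temporal order.
#' @param inventory a [token_inventory()].
#' @inheritParams feature_sequence
#' @return a [feature_sequence()].
#' @export
encode_tokens <- function(strings, inventory, sample_id = NA_character_,
                          label = NULL) {
  strings <- as.character(strings)
  ids <- integer(length(strings))
  for (i in seq_along(strings)) {
    id <- get0(strings[i], envir = inventory$id_of, ifnotfound = NULL)
    if (is.null(id)) {
      stop("unknown token '", strings[i], "' at position ", i)
    }
    ids[i] <- id
  }
  feature_sequence(ids, inventory, sample_id = sample_id, label = label)
}

#' Decode a Feature Sequence back to token strings
#'
#' @param seq a [feature_sequence()].
#' @param inventory the matching [token_inventory()].
#' @return character vector of token strings.
#' @export
decode_tokens <- function(seq, inventory) {
  if (seq$inv_size != inventory$size) {
    stop("sequence was encoded against an inventory of size ", seq$inv_size,
         ", not ", inventory$size)
  }
  inventory$tokens[seq$tokens + 1L]
}

#' Summary statistics of a Feature Sequence
#'
#' Counts the sequence properties the representation was designed to carry:
#' pausing (silence tokens and maximal silence runs), repetition (immediate
#' token repeats), and vocabulary diversity (unique tokens), plus overall
#' length, which is proportional to amount and speed of speech.
#'
#' @param seq a [feature_sequence()].
#' @param inventory the matching [token_inventory()].
#' @return a list with `length`, `silence_count`, `non_silence_count`,
#'   `unique_token_count`, `immediate_repeat_count`, `silence_run_count`.
#' @export
sequence_summary <- function(seq, inventory) {
  toks <- seq$tokens
  sil <- inventory$silence_id
  n <- length(toks)
  is_sil <- toks == sil
  runs <- if (n > 0) rle(is_sil) else list(values = logical(0))
  list(
    length = n,
    silence_count = sum(is_sil),
    non_silence_count = n - sum(is_sil),
    unique_token_count = length(unique(toks)),
    immediate_repeat_count = if (n > 1) sum(toks[-1] == toks[-n]) else 0L,
    silence_run_count = sum(runs$values)
  )
}

#' Write / read Feature Sequence text files
#'
#' Plain-text format: whitespace-separated token strings, one sample per
#' file.
#'
#' @param seq a [feature_sequence()].
#' @param path file path.
#' @param inventory the matching [token_inventory()].
#' @return `write_sequence` returns `path` invisibly; `read_sequence`
#'   returns a [feature_sequence()].
#' @export
write_sequence <- function(seq, path, inventory) {
  writeLines(paste(decode_tokens(seq, inventory), collapse = " "), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sequence
#' @inheritParams feature_sequence
#' @export
read_sequence <- function(path, inventory, sample_id = NA_character_,
                          label = NULL) {
  if (!file.exists(path)) stop("sequence file not found: ", path)
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = " ")
  strings <- strsplit(trimws(txt), "\\s+")[[1]]
  strings <- strings[nzchar(strings)]
  encode_tokens(strings, inventory, sample_id = sample_id, label = label)
}

# Stable content hash of an inventory (polynomial rolling hash over UTF-8
# code points, mod 2^31-1), used to guard checkpoints against being applied
# to a different token space.
inventory_hash <- function(inventory) {
  codes <- utf8ToInt(paste(inventory$tokens, collapse = "\n"))
  h <- 17
  for (b in codes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
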