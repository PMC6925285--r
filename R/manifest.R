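#' Load a JSONL sample manifest
#'
#' One JSON record per line with fields `id` (required, unique), `path`
#' (WAV or sequence file), `label` (0 = CH, 1 = AD, or absent) and
#' `test_type`. Malformed lines are reported with their line number.
#'
#' @param path JSONL file path.
#' @param require_labels error unless every record carries a 0/1 label
#'   (training/evaluation commands need labels).
#' @param check_paths error if a record's `path` does not exist on disk.
#' @return data frame with columns id, path, label, test_type.
#' @export
load_manifest <- function(path, require_labels = FALSE, check_paths = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) {
    warning("manifest '", path, "' is empty")
    return(data.frame(id = character(0), path = character(0),
                      label = integer(0), test_type = character(0)))
  }
  records <- lapply(lines_keep, function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(lines[ln]),
                    error = function(e) {
                      stop("malformed JSON on line ", ln, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$id)) stop("missing 'id' on line ", ln, " of ", path)
    lab <- rec$label
    if (!is.null(lab)) {
      if (length(lab) != 1 || !(lab %in% c(0, 1))) {
        stop("invalid label '", paste(lab, collapse = ","), "' on line ", ln,
             " of ", path, " (must be 0 or 1)")
      }
      lab <- as.integer(lab)
    } else {
      lab <- NA_integer_
    }
    data.frame(id = as.character(rec$id),
               path = if (is.null(rec$path)) NA_character_
                      else as.character(rec$path),
               label = lab,
               test_type = if (is.null(rec$test_type)) NA_character_
                           else as.character(rec$test_type))
  })
  m <- do.call(rbind, records)
  dup <- unique(m$id[duplicated(m$id)])
  if (length(dup) > 0) {
    stop("duplicate id(s) in manifest: ", paste(dup, collapse = ", "))
  }
  if (require_labels && anyNA(m$label)) {
    stop("manifest records without labels: ",
         paste(m$id[is.na(m$label)], collapse = ", "))
  }
  if (check_paths) {
    rel <- m$path[!is.na(m$path)]
    missing <- rel[!file.exists(rel)]
    if (length(missing) > 0) {
      stop("manifest paths do not exist: ", paste(missing, collapse = ", "))
    }
  }
  m
}

#' Write a JSONL manifest
#'
#' @param manifest data frame with at least an `id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(manifest))) {
    rec <- as.list(manifest[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(x) is.na(x) || is.null(x), logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
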