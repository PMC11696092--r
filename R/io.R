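#' @title Plain-text persistence
#' @description Readers and writers for the study's on-disk interchange
#'   formats, all plain text: events and token-word maps as TSV, toy
#'   corpora as JSONL, numeric matrices (hidden states, feature matrices,
#'   RSMs) as TSV, and score/decline tables as CSV via `utils::write.csv`.
#' @name io
NULL

#' Write / read an events table (TSV)
#'
#' Columns: `onset_s`, `duration_s`, `word_index`, `word`.
#'
#' @param events Data frame of events.
#' @param path File path.
#' @return `read_events_tsv` returns the data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a token-word map (TSV)
#'
#' Columns: `token_index`, `word_index`, `token_text`.
#'
#' @param token_map Data frame mapping tokens to words.
#' @param path File path.
#' @export
write_token_map_tsv <- function(token_map, path) {
  utils::write.table(token_map, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_token_map_tsv
#' @export
read_token_map_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a toy corpus (JSONL)
#'
#' One JSON object per line with fields `doc`, `reference`, `candidate`
#' (token arrays).
#'
#' @param corpus List of records as from [generate_toy_corpus()].
#' @param path File path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(rec) {
    jsonlite::toJSON(list(doc = rec$doc, reference = rec$reference,
                          candidate = rec$candidate))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    list(doc = as.character(x$doc), reference = as.character(x$reference),
         candidate = as.character(x$candidate))
  })
}

#' Write / read a numeric matrix (TSV)
#'
#' Plain tab-separated values without headers; used for hidden-state
#' matrices, EEG feature matrices and RSMs.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, header = FALSE))
}
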