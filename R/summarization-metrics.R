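#' @title Summarization metrics
#' @description ROUGE-1/2/L between candidate and reference summaries,
#'   perplexity from token log-probabilities, and per-layer
#'   performance-decline bookkeeping for layer-manipulation experiments.
#' @name summarization_metrics
NULL

#' Tokenize text for ROUGE scoring
#'
#' Lowercases, strips punctuation, and splits on whitespace. Inputs that are
#' already token vectors (length > 1) pass through lowercased.
#'
#' @param text Character scalar, or a character vector of tokens.
#' @return Character vector of tokens (possibly empty).
#' @export
rouge_tokenize <- function(text) {
  if (length(text) == 0L) return(character(0))
  if (length(text) > 1L) return(tolower(as.character(text)))
  x <- tolower(as.character(text))
  x <- gsub("[[:punct:]]", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

rouge_result <- function(precision, recall, variant) {
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 variant = variant),
            class = "rouge_score")
}

#' @export
print.rouge_score <- function(x, ...) {
  cat(sprintf("%s  P=%.4f R=%.4f F1=%.4f\n",
              x$variant, x$precision, x$recall, x$f1))
  invisible(x)
}

ngrams <- function(tokens, n) {
  m <- length(tokens) - n + 1L
  if (m <= 0L) return(character(0))
  vapply(seq_len(m), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\x01")
  }, character(1))
}

#' ROUGE-N: clipped n-gram overlap
#'
#' Recall is the clipped overlap count divided by the number of reference
#' n-grams, precision divides by the number of candidate n-grams; empty
#' denominators give 0. `n = 1` counts unigrams, `n = 2` bigrams.
#'
#' @param candidate,reference Token vectors (or raw strings, tokenized via
#'   [rouge_tokenize()]).
#' @param n N-gram order (>= 1).
#' @return A `rouge_score` with precision, recall, f1.
#' @export
rouge_n <- function(candidate, reference, n = 1L) {
  if (n < 1L) stop_invalid("rouge_n() needs n >= 1")
  cand <- ngrams(rouge_tokenize(candidate), n)
  ref <- ngrams(rouge_tokenize(reference), n)
  if (length(cand) == 0L || length(ref) == 0L) {
    return(rouge_result(0, 0, paste0("rouge", n)))
  }
  ct <- table(cand)
  rt <- table(ref)
  shared <- intersect(names(ct), names(rt))
  overlap <- sum(pmin(as.numeric(ct[shared]), as.numeric(rt[shared])))
  rouge_result(overlap / length(cand), overlap / length(ref),
               paste0("rouge", n))
}

# iterative longest-common-subsequence length (O(m n) dynamic programme)
lcs_length <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) return(0L)
  prev <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    match_row <- a[i] == b
    for (j in seq_len(n)) {
      cur[j + 1L] <- if (match_row[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[n + 1L]
}

#' ROUGE-L: longest common subsequence
#'
#' Recall is LCS length over the reference length, precision over the
#' candidate length; captures in-order structural overlap without requiring
#' contiguity.
#'
#' @inheritParams rouge_n
#' @return A `rouge_score`.
#' @export
rouge_l <- function(candidate, reference) {
  cand <- rouge_tokenize(candidate)
  ref <- rouge_tokenize(reference)
  if (length(cand) == 0L || length(ref) == 0L) {
    return(rouge_result(0, 0, "rougeL"))
  }
  l <- lcs_length(cand, ref)
  rouge_result(l / length(cand), l / length(ref), "rougeL")
}

#' Perplexity from natural-log token probabilities
#'
#' `exp(-mean(log p))`; lower is better. Log-probabilities must be <= 0.
#'
#' @param token_logprobs Non-empty numeric vector of natural-log
#'   probabilities.
#' @return Perplexity (numeric scalar >= 1).
#' @export
perplexity <- function(token_logprobs) {
  lp <- as.numeric(token_logprobs)
  if (length(lp) == 0L) stop_invalid("perplexity() needs a non-empty vector")
  if (any(!is.finite(lp)) || any(lp > 0)) {
    stop_invalid("log-probabilities must be finite and <= 0")
  }
  exp(-mean(lp))
}

#' Per-layer performance-decline table
#'
#' Joins a baseline (unmanipulated, "w/o") metric set with per-(layer,
#' surgery) manipulated metric sets, computing decline = baseline metric
#' minus manipulated metric for each ROUGE variant. Negative declines
#' (improvements after manipulation) are preserved.
#'
#' @param baseline Named numeric vector with entries `rouge1`, `rouge2`,
#'   `rougeL`, plus the baseline `perplexity`.
#' @param manipulated Data frame with columns `layer` (integer or `"all"`),
#'   `surgery`, `rouge1`, `rouge2`, `rougeL`, `perplexity`.
#' @param layers Optional vector of layer labels expected per surgery;
#'   missing rows are reported via a warning and omitted.
#' @return Data frame with columns `layer`, `surgery`, `rouge1`, `rouge2`,
#'   `rougeL`, `perplexity`, `rouge1_decline`, `rouge2_decline`,
#'   `rougeL_decline`, sorted by surgery then layer, with a single leading
#'   `"w/o"` baseline row.
#' @export
compute_decline <- function(baseline, manipulated, layers = NULL) {
  need <- c("rouge1", "rouge2", "rougeL", "perplexity")
  if (!all(need %in% names(baseline))) {
    stop_invalid("baseline must name rouge1, rouge2, rougeL, perplexity")
  }
  manipulated <- as.data.frame(manipulated)
  if (!all(c("layer", "surgery", need) %in% names(manipulated))) {
    stop_invalid("manipulated table missing required columns")
  }
  if (!is.null(layers)) {
    for (s in unique(manipulated$surgery)) {
      have <- manipulated$layer[manipulated$surgery == s]
      miss <- setdiff(as.character(layers), as.character(have))
      if (length(miss)) {
        warning("missing layer rows for surgery '", s, "': ",
                paste(miss, collapse = ", "), call. = FALSE)
      }
    }
  }
  base_row <- data.frame(layer = "w/o", surgery = "none",
                         rouge1 = baseline[["rouge1"]],
                         rouge2 = baseline[["rouge2"]],
                         rougeL = baseline[["rougeL"]],
                         perplexity = baseline[["perplexity"]],
                         stringsAsFactors = FALSE)
  manipulated$layer <- as.character(manipulated$layer)
  ord <- order(manipulated$surgery,
               suppressWarnings(as.numeric(manipulated$layer)),
               manipulated$layer, na.last = TRUE)
  out <- rbind(base_row, manipulated[ord, names(base_row)])
  for (v in c("rouge1", "rouge2", "rougeL")) {
    out[[paste0(v, "_decline")]] <- baseline[[v]] - out[[v]]
  }
  rownames(out) <- NULL
  out
}
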