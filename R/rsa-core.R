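#' @title Representational similarity core
#' @description Cosine representational similarity matrices (RSMs) over token
#'   feature vectors, Spearman RSA scores on strict upper triangles,
#'   participant averaging, cross-layer RSA and rank heatmap transforms.
#' @name rsa_core
NULL

#' Cosine representational similarity matrix
#'
#' Computes the n x n matrix of pairwise cosine similarities between the rows
#' of `features` (one row per token). The result is symmetric with a unit
#' diagonal and entries in \[-1, 1\].
#'
#' @param features Numeric matrix, tokens x feature dimension (n >= 2).
#' @param source Optional label describing where the features came from
#'   (e.g. a layer index or participant/condition pair).
#' @return An object of class `rsm`: the similarity matrix with attributes
#'   `n` and `source`.
#' @export
cosine_rsm <- function(features, source = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || nrow(features) < 2L) {
    stop_invalid("cosine_rsm() needs a numeric matrix with >= 2 rows")
  }
  norms <- sqrt(rowSums(features^2))
  bad <- which(norms == 0)
  if (length(bad)) {
    stop_invalid("cosine similarity undefined for zero-norm row(s): ",
                 paste(bad, collapse = ", "))
  }
  x <- features / norms
  v <- tcrossprod(x)
  v <- (v + t(v)) / 2
  v[v > 1] <- 1
  v[v < -1] <- -1
  diag(v) <- 1
  structure(v, n = nrow(v), source = source, class = c("rsm", "matrix"))
}

as_rsm_matrix <- function(m) {
  m <- unclass(m)
  attr(m, "n") <- NULL
  attr(m, "source") <- NULL
  m
}

#' Strict upper triangle of an RSM, in a fixed vectorization order
#'
#' Uses R's column-major `upper.tri()` order throughout the package; any
#' single consistent order yields identical Spearman correlations.
#'
#' @param rsm An `rsm` or plain symmetric matrix.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
upper_triangle <- function(rsm) {
  m <- as_rsm_matrix(as.matrix(rsm))
  m[upper.tri(m, diag = FALSE)]
}

#' RSA score: Spearman correlation of two RSMs' upper triangles
#'
#' The two similarity matrices are vectorized over their strict upper
#' triangles (the diagonal is identically 1 and both matrices are symmetric)
#' and compared by Spearman rank correlation with average ranks on ties.
#'
#' @param rsm_a,rsm_b RSMs (or plain symmetric matrices) of equal size.
#' @param layer,participant,condition Optional bookkeeping labels carried on
#'   the result.
#' @return An object of class `rsa_score` with fields `rho`, `n_pairs`,
#'   `layer`, `participant`, `condition`.
#' @export
rsa_score <- function(rsm_a, rsm_b, layer = NA, participant = NA,
                      condition = NA) {
  a <- upper_triangle(rsm_a)
  b <- upper_triangle(rsm_b)
  if (length(a) != length(b)) {
    stop_invalid("RSM size mismatch: ", length(a), " vs ", length(b), " pairs")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_invalid("constant upper triangle; rank correlation undefined")
  }
  rho <- stats::cor(a, b, method = "spearman")
  structure(
    list(rho = rho, n_pairs = length(a), layer = layer,
         participant = participant, condition = condition),
    class = "rsa_score"
  )
}

#' @export
print.rsa_score <- function(x, ...) {
  cat("RSA score rho =", format(x$rho, digits = 5),
      "over", x$n_pairs, "token pairs\n")
  invisible(x)
}

#' Average RSA scores across participants
#'
#' Arithmetic mean of the correlation coefficients, mirroring the
#' participant-averaging step of the analysis. An optional Fisher-z average
#' (tanh of the mean of atanh(rho)) is available but off by default.
#'
#' @param scores Non-empty list of `rsa_score` objects (or numeric rho
#'   values) for a single layer/condition.
#' @param fisher_z Average on the Fisher-z scale instead of raw rho.
#' @return The averaged correlation (numeric scalar).
#' @export
average_participant_scores <- function(scores, fisher_z = FALSE) {
  if (length(scores) == 0L) stop_invalid("no scores to average")
  rho <- vapply(scores, function(s) {
    if (inherits(s, "rsa_score")) s$rho else as.numeric(s)
  }, numeric(1))
  if (fisher_z) tanh(mean(atanh(rho))) else mean(rho)
}

#' Cross-layer RSA between two stacks of hidden states
#'
#' Entry (i, j) is the RSA score between the cosine RSM of layer i of
#' `states_a` and layer j of `states_b`.
#'
#' @param states_a,states_b Lists of token feature matrices (tokens x dim),
#'   all with the same number of tokens.
#' @return Numeric matrix of size `length(states_a)` x `length(states_b)`.
#' @export
cross_layer_rsa <- function(states_a, states_b) {
  n_tok <- unique(c(vapply(states_a, nrow, integer(1)),
                    vapply(states_b, nrow, integer(1))))
  if (length(n_tok) != 1L) {
    stop_invalid("token-count mismatch across layers: ",
                 paste(n_tok, collapse = ", "))
  }
  rsm_a <- lapply(states_a, cosine_rsm)
  rsm_b <- lapply(states_b, cosine_rsm)
  out <- matrix(NA_real_, length(rsm_a), length(rsm_b))
  for (i in seq_along(rsm_a)) {
    for (j in seq_along(rsm_b)) {
      out[i, j] <- rsa_score(rsm_a[[i]], rsm_b[[j]])$rho
    }
  }
  out
}

#' Rank-transform an RSM for rank-ordered heatmaps
#'
#' Replaces the strict upper triangle by its average ranks (mirrored to the
#' lower triangle); the diagonal is set to the maximal rank label so that
#' self-similarity stays on top of the ordering.
#'
#' @param rsm An `rsm` or plain symmetric matrix.
#' @return Numeric matrix of ranks, symmetric.
#' @export
rank_transform <- function(rsm) {
  m <- as_rsm_matrix(as.matrix(rsm))
  ut <- upper.tri(m, diag = FALSE)
  r <- rank(m[ut])
  out <- matrix(0, nrow(m), ncol(m))
  out[ut] <- r
  out <- out + t(out)
  diag(out) <- length(r) + 1
  out
}
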