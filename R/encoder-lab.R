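#' @title Deterministic toy transformer encoder
#' @description A minimal single-head, post-norm transformer encoder with
#'   exposed per-layer hidden states, plus the two layer surgeries used in
#'   the manipulation experiments: attention ablation (uniform attention via
#'   W_Q = W_K = 0, W_V = I) and relative-scale Gaussian weight noise. The
#'   encoder exists so that every surgery and every downstream statistic is
#'   testable offline; hidden states exported from full-scale summarization
#'   models can be fed to the RSA stage through the same matrix interface.
#' @name encoder_lab
NULL

WEIGHT_MATRICES <- c("W_Q", "W_K", "W_V", "W_O", "W1", "W2")

#' Seeded random weights for one encoder layer
#'
#' @param d_model Model width (all attention projections are
#'   `d_model x d_model`; single-head, so `d_k = d_model`).
#' @param d_ff Feed-forward inner width (default `4 * d_model`).
#' @param resid_scale Extra scaling of the residual-branch output
#'   projections `W_O` and `W2`. Depth-scaled initialisation
#'   (`1 / sqrt(2 L)`) keeps the residual stream dominant so token identity
#'   survives a deep randomly-initialised stack instead of rank-collapsing.
#' @return A list of weight matrices `W_Q`, `W_K`, `W_V`, `W_O`, FFN
#'   weights `W1`, `b1`, `W2`, `b2`, and layer-norm parameters.
#' @keywords internal
random_layer_weights <- function(d_model, d_ff = 4L * d_model,
                                 resid_scale = 1) {
  g <- function(nr, nc, scale = 1) {
    matrix(stats::rnorm(nr * nc, sd = scale / sqrt(nr)), nr, nc)
  }
  list(
    W_Q = g(d_model, d_model), W_K = g(d_model, d_model),
    W_V = g(d_model, d_model),
    W_O = g(d_model, d_model, resid_scale),
    W1 = g(d_model, d_ff), b1 = stats::rnorm(d_ff, sd = 0.01),
    W2 = g(d_ff, d_model, resid_scale),
    b2 = stats::rnorm(d_model, sd = 0.01),
    ln1_g = rep(1, d_model), ln1_b = rep(0, d_model),
    ln2_g = rep(1, d_model), ln2_b = rep(0, d_model)
  )
}

#' Build a seeded stack of encoder layer weights
#'
#' @param n_layers Number of encoder layers (>= 1).
#' @param d_model Model width.
#' @param d_ff Feed-forward width.
#' @param seed Integer seed; fully determines all weights.
#' @param resid_scale Residual-branch init scaling; default `1/sqrt(2 L)`
#'   (see [random_layer_weights()]).
#' @return List of `n_layers` weight bundles (class `encoder_weights`).
#' @export
encoder_weights <- function(n_layers, d_model, d_ff = 4L * d_model,
                            seed = 1L,
                            resid_scale = 1 / sqrt(2 * n_layers)) {
  stopifnot(n_layers >= 1L, d_model >= 2L)
  layers <- with_seed(seed, {
    lapply(seq_len(n_layers), function(i) {
      random_layer_weights(d_model, d_ff, resid_scale)
    })
  })
  structure(layers, d_model = d_model, class = "encoder_weights")
}

row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Scaled dot-product self-attention for one layer
#'
#' Computes `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V` with
#' `Q = X W_Q`, `K = X W_K`, `V = X W_V`; single head, `d_k = d_model`.
#'
#' @param X Input matrix, tokens x d_model.
#' @param w Layer weight bundle (see [random_layer_weights()]).
#' @return List with `output` (tokens x d_model, before the output
#'   projection) and `attention` (tokens x tokens, rows summing to 1).
#' @export
self_attention <- function(X, w) {
  X <- as.matrix(X)
  d_model <- ncol(X)
  if (nrow(w$W_Q) != d_model) {
    stop_invalid("input width ", d_model, " does not match weights (",
                 nrow(w$W_Q), ")")
  }
  Q <- X %*% w$W_Q
  K <- X %*% w$W_K
  V <- X %*% w$W_V
  A <- row_softmax(Q %*% t(K) / sqrt(d_model))
  list(output = A %*% V, attention = A)
}

#' Attention ablation: force uniform attention
#'
#' Returns a copy of the weights in which `W_Q` and `W_K` are zero matrices
#' and `W_V` is the identity, so the softmax sees all-zero logits and every
#' attention probability becomes exactly `1/n`; the value matrix passes the
#' input through unchanged. All other parameters are untouched.
#'
#' @param w A single layer weight bundle.
#' @return The ablated copy.
#' @export
ablate_attention <- function(w) {
  d <- nrow(w$W_Q)
  w$W_Q <- matrix(0, d, d)
  w$W_K <- matrix(0, d, d)
  w$W_V <- diag(d)
  w
}

#' Add relative-scale Gaussian noise to layer weights
#'
#' Each selected weight matrix `M` receives i.i.d. additive noise with
#' standard deviation `sigma_rel * sd(M)` (elementwise sd of that matrix),
#' making the perturbation scale-free across matrices of different
#' magnitude. Deterministic given `seed`; the original is untouched.
#'
#' @param w A single layer weight bundle.
#' @param sigma_rel Relative noise scale (>= 0).
#' @param seed Integer seed.
#' @param which Names of the matrices to perturb (default: all attention
#'   projections and FFN weights).
#' @return The perturbed copy.
#' @export
add_noise <- function(w, sigma_rel, seed = 1L, which = WEIGHT_MATRICES) {
  if (sigma_rel < 0) stop_invalid("sigma_rel must be >= 0")
  if (sigma_rel == 0) return(w)
  with_seed(seed, {
    for (nm in which) {
      M <- w[[nm]]
      s <- stats::sd(as.vector(M))
      w[[nm]] <- M + matrix(stats::rnorm(length(M), sd = sigma_rel * s),
                            nrow(M), ncol(M))
    }
    w
  })
}

layer_norm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  ((X - mu) / sqrt(v + eps)) * rep(g, each = nrow(X)) +
    rep(b, each = nrow(X))
}

gelu <- function(x) x * stats::pnorm(x)

#' Forward pass of the toy encoder with optional layer surgery
#'
#' Standard post-norm layers: `X <- LN(X + Attn(X) W_O)` then
#' `X <- LN(X + FFN(X))` with a GELU feed-forward block. Hidden states are
#' recorded after every layer (with the embedding input as state 0), along
#' with every layer's attention matrix. At most one surgery is applied, to
#' exactly one layer or to all layers.
#'
#' @param X0 Input embeddings, tokens x d_model.
#' @param layers An [encoder_weights()] stack.
#' @param manipulate Optional list: `layer` (1-based index, or `"all"`),
#'   `surgery` (`"ablate"` or `"noise"`), and for noise `sigma_rel` and
#'   `seed`.
#' @return List with `states` (list of length `n_layers + 1`; element 1 is
#'   `X0`, element `l + 1` is the output of layer `l`) and `attention`
#'   (list of per-layer attention matrices).
#' @export
encode <- function(X0, layers, manipulate = NULL) {
  X0 <- as.matrix(X0)
  L <- length(layers)
  target <- integer(0)
  if (!is.null(manipulate)) {
    stopifnot(is.list(manipulate), !is.null(manipulate$surgery))
    if (identical(manipulate$layer, "all")) {
      target <- seq_len(L)
    } else {
      idx <- as.integer(manipulate$layer)
      if (is.na(idx) || idx < 1L || idx > L) {
        stop_invalid("manipulated layer index out of range: ",
                     manipulate$layer)
      }
      target <- idx
    }
  }
  states <- vector("list", L + 1L)
  states[[1L]] <- X0
  attn <- vector("list", L)
  X <- X0
  for (l in seq_len(L)) {
    w <- layers[[l]]
    if (l %in% target) {
      w <- switch(manipulate$surgery,
        ablate = ablate_attention(w),
        noise = add_noise(w,
                          sigma_rel = manipulate$sigma_rel %||% 0.5,
                          seed = manipulate$seed %||% 1L),
        stop_invalid("unknown surgery: ", manipulate$surgery)
      )
    }
    sa <- self_attention(X, w)
    attn[[l]] <- sa$attention
    X <- layer_norm(X + sa$output %*% w$W_O, w$ln1_g, w$ln1_b)
    ff <- gelu(sweep(X %*% w$W1, 2L, w$b1, "+")) %*% w$W2
    ff <- sweep(ff, 2L, w$b2, "+")
    X <- layer_norm(X + ff, w$ln2_g, w$ln2_b)
    states[[l + 1L]] <- X
  }
  list(states = states, attention = attn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hidden states of an encoder run, one matrix per layer
#'
#' Convenience accessor returning the states after each layer (dropping the
#' embedding input), as consumed by the RSA stage.
#'
#' @param encoded Result of [encode()].
#' @return List of token feature matrices, one per layer.
#' @export
layer_states <- function(encoded) {
  encoded$states[-1L]
}
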