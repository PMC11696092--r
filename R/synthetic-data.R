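#' @title Synthetic study generators
#' @description Seeded generators that plant a known shared representational
#'   geometry in both "brain" and "model" data: a latent token geometry
#'   (clusters on a hypersphere), per-layer hidden states whose alignment
#'   with that geometry follows a configurable depth schedule, word-locked
#'   multichannel EEG with a fixed spatiotemporal forward model plus
#'   band-limited noise, a toy corpus with brute-force ROUGE ground truth,
#'   and a planted coupling between per-layer brain similarity and
#'   performance decline. Every output is a pure function of its config and
#'   seed.
#' @name synthetic_data
NULL

#' Latent token geometry: clusters on a hypersphere
#'
#' Cluster means are drawn uniformly on the unit hypersphere; tokens get a
#' cluster mean plus isotropic Gaussian spread, so within-cluster pairs are
#' more similar (higher cosine) than between-cluster pairs in expectation.
#' The target RSM is the cosine similarity matrix of the latent vectors.
#'
#' @param n_tokens Number of tokens (>= 2).
#' @param n_clusters Number of clusters (1 <= n_clusters <= n_tokens).
#' @param seed Integer seed; fully determines the geometry.
#' @param d_latent Latent dimensionality (default 8).
#' @param cluster_spread Within-cluster Gaussian sd (default 0.35).
#' @return A `latent_geometry`: `n_tokens`, `latent` (n_tokens x d_latent),
#'   `target_rsm` (cosine RSM), `cluster` (assignments).
#' @export
generate_latent_token_geometry <- function(n_tokens, n_clusters, seed,
                                           d_latent = 8L,
                                           cluster_spread = 0.35) {
  if (n_tokens < 2L) stop_invalid("n_tokens must be >= 2")
  if (n_clusters < 1L || n_clusters > n_tokens) {
    stop_invalid("need 1 <= n_clusters <= n_tokens")
  }
  with_seed(seed, {
    means <- matrix(stats::rnorm(n_clusters * d_latent), n_clusters)
    means <- means / sqrt(rowSums(means^2))
    cluster <- sort(rep_len(seq_len(n_clusters), n_tokens))
    latent <- means[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n_tokens * d_latent, sd = cluster_spread),
             n_tokens)
    structure(list(n_tokens = n_tokens, latent = latent,
                   target_rsm = cosine_rsm(latent, source = "latent"),
                   cluster = cluster, d_latent = d_latent),
              class = "latent_geometry")
  })
}

#' Alignment schedule across encoder depth
#'
#' Per-layer alignment weights `a_l` in \[0, 1\] controlling how strongly
#' each synthetic layer's hidden states embed the latent geometry. The
#' `"monotone"` default, `a_l = l / L`, emulates the empirical pattern that
#' brain-model similarity rises with encoder depth; `"constant"` is the
#' no-trend null.
#'
#' @param n_layers Number of layers L (>= 1).
#' @param kind `"monotone"` or `"constant"`.
#' @param noise_scale Non-negative sd of the non-aligned state component
#'   (default 1, chosen so the per-layer alignment with the target geometry
#'   rises gradually across the whole depth rather than saturating early).
#' @param constant_level Alignment used by the constant schedule.
#' @return List with `per_layer_alignment` and `noise_scale`.
#' @export
alignment_schedule <- function(n_layers, kind = c("monotone", "constant"),
                               noise_scale = 1, constant_level = 0.5) {
  kind <- match.arg(kind)
  if (n_layers < 1L) stop_invalid("n_layers must be >= 1")
  if (noise_scale < 0) stop_invalid("noise_scale must be >= 0")
  a <- switch(kind,
              monotone = seq_len(n_layers) / n_layers,
              constant = rep(constant_level, n_layers))
  list(per_layer_alignment = a, noise_scale = noise_scale)
}

#' Per-layer hidden states with scheduled geometry alignment
#'
#' Layer l is `a_l * (latent %*% t(R_l)) + (1 - a_l) * E_l`, where `R_l` is
#' a random `dim x d_latent` matrix with orthonormal columns (so the
#' rotation embedding preserves all inner products and norms, and with
#' `a_l = 1`, `noise_scale = 0` the layer's cosine RSM equals the target
#' RSM exactly), and `E_l` is independent Gaussian noise with row norm
#' ~ `noise_scale`. Latent rows are rescaled to unit mean norm first so the
#' mixing weights are comparable.
#'
#' @param geometry A `latent_geometry`.
#' @param schedule An [alignment_schedule()].
#' @param dim Hidden-state width (>= latent dimensionality).
#' @param seed Integer seed.
#' @return List of token feature matrices, one per layer.
#' @export
generate_layer_states <- function(geometry, schedule, dim, seed) {
  stopifnot(inherits(geometry, "latent_geometry"))
  a <- schedule$per_layer_alignment
  if (length(a) == 0L) stop_invalid("empty alignment schedule")
  if (any(a < 0 | a > 1)) stop_invalid("alignments must lie in [0, 1]")
  d_latent <- ncol(geometry$latent)
  if (dim < d_latent) stop_invalid("dim must be >= latent dimensionality")
  z <- geometry$latent
  z <- z / mean(sqrt(rowSums(z^2)))
  with_seed(seed, {
    lapply(seq_along(a), function(l) {
      R <- qr.Q(qr(matrix(stats::rnorm(dim * d_latent), dim)))[, seq_len(d_latent), drop = FALSE]
      signal <- z %*% t(R)
      noise <- matrix(stats::rnorm(geometry$n_tokens * dim,
                                   sd = schedule$noise_scale / sqrt(dim)),
                      geometry$n_tokens)
      a[l] * signal + (1 - a[l]) * noise
    })
  })
}

#' Synthetic EEG study configuration
#'
#' Defaults emulate the recording setup of the reference study (28-channel
#' 10-20 montage, 250 Hz, 13 effective participants) at a desk-scale word
#' count so that replicated end-to-end runs stay fast.
#'
#' @param n_participants Number of participants (default 13).
#' @param n_words Number of words presented (default 60).
#' @param tokens_per_word Integer (deterministic count, default 1) or an
#'   integer vector from which each word's token count is drawn uniformly.
#' @param montage Electrode name vector (default [default_montage()]).
#' @param sampling_rate Hz (default 250).
#' @param snr Signal-to-noise amplitude ratio of the word-locked response
#'   versus the background noise (default 1; must be > 0).
#' @param seed Integer seed; fully determines all draws.
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(n_participants = 13L, n_words = 60L,
                                   tokens_per_word = 1L,
                                   montage = default_montage(),
                                   sampling_rate = 250,
                                   snr = 1, seed = 1L) {
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  if (n_participants < 1L) stop_invalid("n_participants must be >= 1")
  if (snr <= 0) stop_invalid("snr must be > 0")
  structure(list(n_participants = as.integer(n_participants),
                 n_words = as.integer(n_words),
                 tokens_per_word = as.integer(tokens_per_word),
                 montage = montage, sampling_rate = sampling_rate,
                 snr = snr, seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Token counts per word implied by a study config
#'
#' @param config A [synthetic_study_config()].
#' @return Integer vector of length `n_words`; deterministic given the
#'   config seed.
#' @export
token_counts <- function(config) {
  tpw <- config$tokens_per_word
  if (length(tpw) == 1L) return(rep(tpw, config$n_words))
  with_seed(derive_seed(config$seed, 17L), {
    sample(tpw, config$n_words, replace = TRUE)
  })
}

# magnitude response of the order-4 Butterworth 0.5-30 Hz band at the FFT
# bin frequencies of an n-sample record (two-sided, real-symmetric)
band_gain <- function(n, fs) {
  bf <- signal::butter(4, c(0.5, 30) / (fs / 2), type = "pass")
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f) * fs            # folded bin frequencies in Hz
  w <- exp(-1i * 2 * pi * f / fs)
  hb <- outer(w, seq_along(bf$b) - 1, "^") %*% bf$b
  ha <- outer(w, seq_along(bf$a) - 1, "^") %*% bf$a
  abs(drop(hb / ha))
}

# canonical temporal response kernel: smooth bump on 100-1200 ms,
# peaking at 650 ms (inside the 250-800 ms analysis windows)
response_kernel <- function(fs, dur_s = 1.5) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  k <- numeric(length(t))
  on <- t >= 0.1 & t <= 1.2
  k[on] <- sin(pi * (t[on] - 0.1) / 1.1)^2
  k
}

#' Generate a synthetic word-locked EEG study
#'
#' Each word is presented for 1500 ms with onsets 1700 ms apart, so every
#' epoch's pre-onset \[-200, 0) ms interval falls after the previous word's
#' response has ended and carries noise only. During 0-1500 ms the
#' recording embeds the word's latent vector through a fixed spatiotemporal
#' forward model: an orthonormal electrode mixing matrix (shared across
#' participants) times a canonical temporal kernel peaking at 650 ms. Noise
#' is white noise band-limited to 0.5-30 Hz (zero-phase spectral shaping by
#' the order-4 Butterworth band magnitude), scaled per participant to
#' amplitude `1 / snr` relative to the unit-RMS signal.
#'
#' @param geometry A `latent_geometry` whose `n_tokens` equals the total
#'   token count implied by `config` (see [token_counts()]).
#' @param config A [synthetic_study_config()].
#' @return List with `recordings` (one [continuous_recording()] per
#'   participant), `events` (data frame `onset_s`, `duration_s`,
#'   `word_index`, `word`), `token_map` (data frame `token_index`,
#'   `word_index`, `token_text`).
#' @export
generate_eeg_study <- function(geometry, config) {
  stopifnot(inherits(geometry, "latent_geometry"),
            inherits(config, "synthetic_study_config"))
  if (config$snr <= 0) stop_invalid("snr must be > 0")
  counts <- token_counts(config)
  if (sum(counts) != geometry$n_tokens) {
    stop_invalid("geometry has ", geometry$n_tokens, " tokens but config ",
                 "implies ", sum(counts))
  }
  fs <- config$sampling_rate
  n_ch <- length(config$montage)
  n_words <- config$n_words
  lead_in <- 2
  onset_s <- lead_in + (seq_len(n_words) - 1) * 1.7
  n_samp <- round((lead_in + n_words * 1.7 + 1) * fs)
  events <- data.frame(onset_s = onset_s, duration_s = 1.5,
                       word_index = seq_len(n_words),
                       word = paste0("w", seq_len(n_words)))
  token_map <- data.frame(token_index = seq_len(sum(counts)),
                          word_index = rep(seq_len(n_words), counts))
  token_map$token_text <- paste0("w", token_map$word_index, ".",
                                 sequence(counts))

  # word latent = mean of its tokens' latent rows, normalized
  word_latent <- t(vapply(seq_len(n_words), function(w) {
    rows <- which(token_map$word_index == w)
    colMeans(geometry$latent[rows, , drop = FALSE])
  }, numeric(ncol(geometry$latent))))
  word_latent <- word_latent / sqrt(rowSums(word_latent^2))

  kernel <- response_kernel(fs)
  A <- with_seed(derive_seed(config$seed, 23L), {
    qr.Q(qr(matrix(stats::rnorm(n_ch * ncol(word_latent)), n_ch)))[,
      seq_len(ncol(word_latent)), drop = FALSE]
  })
  signal <- matrix(0, n_ch, n_samp)
  active <- logical(n_samp)
  for (w in seq_len(n_words)) {
    i0 <- round(onset_s[w] * fs) + 1L
    idx <- i0:(i0 + length(kernel) - 1L)
    signal[, idx] <- signal[, idx] + drop(A %*% word_latent[w, ]) %o% kernel
    active[idx] <- TRUE
  }
  rms <- sqrt(mean(signal[, active]^2))
  signal <- signal / rms

  gain <- band_gain(n_samp, fs)
  recordings <- lapply(seq_len(config$n_participants), function(k) {
    noise <- with_seed(derive_seed(config$seed, 100L + k), {
      matrix(stats::rnorm(n_samp * n_ch), n_samp)
    })
    # zero-phase band-limiting: shape the white spectrum by the order-4
    # Butterworth 0.5-30 Hz magnitude response (all channels in one FFT)
    noise <- Re(stats::mvfft(stats::mvfft(noise) * gain, inverse = TRUE)) /
      n_samp
    noise <- t(noise) / sqrt(mean(noise^2)) / config$snr
    continuous_recording(signal + noise, fs, config$montage)
  })
  list(recordings = recordings, events = events, token_map = token_map)
}

# naive greedy clipped overlap count used for generation-time ground truth
naive_overlap <- function(cand, ref) {
  used <- logical(length(ref))
  hits <- 0L
  for (tok in cand) {
    j <- which(!used & ref == tok)
    if (length(j)) {
      used[j[1]] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

naive_bigrams <- function(tokens) {
  if (length(tokens) < 2L) return(character(0))
  paste(tokens[-length(tokens)], tokens[-1])
}

# memoized recursive LCS, independent of the iterative DP in rouge_l()
naive_lcs <- function(a, b) {
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (a[i] == b[j]) rec(i - 1L, j - 1L) + 1L else {
      max(rec(i - 1L, j), rec(i, j - 1L))
    }
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

#' Toy summarization corpus with stored ROUGE ground truth
#'
#' Generates documents with reference summaries and candidate summaries of
#' four kinds (identical copy, token-mutated, vocabulary-disjoint,
#' shuffled), cycling over documents. Unigram/bigram clipped overlap counts
#' and the LCS length for every candidate/reference pair are computed at
#' generation time by naive counting and memoized recursion, so metric
#' implementations can be checked against independently derived truth.
#'
#' @param n_docs Number of documents (>= 1).
#' @param seed Integer seed.
#' @param ref_len Reference summary length in tokens (default 8).
#' @return List of records, each with `doc`, `reference`, `candidate`
#'   (token vectors) and `truth` (list `unigram_overlap`, `bigram_overlap`,
#'   `lcs`, `kind`).
#' @export
generate_toy_corpus <- function(n_docs, seed, ref_len = 8L) {
  if (n_docs < 1L) stop_invalid("n_docs must be >= 1")
  kinds <- c("identical", "mutated", "disjoint", "shuffled")
  with_seed(seed, {
    lapply(seq_len(n_docs), function(d) {
      vocab <- paste0("tok", 1:30)
      alt_vocab <- paste0("alt", 1:30)
      doc <- sample(vocab, 30, replace = TRUE)
      reference <- sample(vocab, ref_len, replace = TRUE)
      kind <- kinds[(d - 1L) %% length(kinds) + 1L]
      candidate <- switch(kind,
        identical = reference,
        mutated = {
          cand <- reference
          flip <- sample(ref_len, max(1L, ref_len %/% 3L))
          cand[flip] <- sample(alt_vocab, length(flip), replace = TRUE)
          cand
        },
        disjoint = sample(alt_vocab, ref_len, replace = TRUE),
        shuffled = sample(reference)
      )
      truth <- list(
        unigram_overlap = naive_overlap(candidate, reference),
        bigram_overlap = naive_overlap(naive_bigrams(candidate),
                                       naive_bigrams(reference)),
        lcs = naive_lcs(candidate, reference),
        kind = kind
      )
      list(doc = doc, reference = reference, candidate = candidate,
           truth = truth)
    })
  })
}

#' Planted coupling between per-layer RSA scores and performance decline
#'
#' Generates a per-layer decline table in which decline is a positive
#' linear function of the layer's brain-similarity score plus a perplexity
#' contribution and noise:
#' `decline_l = beta * rsa_l + gamma * (pplx_l - mean(pplx)) + eps_l`,
#' `eps_l ~ N(0, (noise_frac * sd(beta * rsa))^2)`. Used to verify that the
#' partial-correlation stage recovers a planted positive association after
#' controlling for perplexity.
#'
#' @param rsa_scores Numeric vector of per-layer RSA scores.
#' @param beta Coupling strength (default 1).
#' @param gamma Perplexity contribution (default 0.02).
#' @param noise_frac Noise sd as a fraction of the signal sd (default 0.3).
#' @param seed Integer seed.
#' @return Data frame with `layer`, `decline`, `perplexity`.
#' @export
simulate_decline_coupling <- function(rsa_scores, beta = 1, gamma = 0.02,
                                      noise_frac = 0.3, seed = 1L) {
  L <- length(rsa_scores)
  if (L < 4L) stop_invalid("need >= 4 layers")
  with_seed(seed, {
    pplx <- 5 + 0.3 * stats::rnorm(L)
    eps <- stats::rnorm(L, sd = noise_frac * stats::sd(beta * rsa_scores))
    data.frame(layer = seq_len(L),
               decline = beta * rsa_scores + gamma * (pplx - mean(pplx)) + eps,
               perplexity = pplx)
  })
}
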