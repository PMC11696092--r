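# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use different algorithms (explicit
# sorting, naive loops, enumeration, permutation sampling) from the code
# under test.

# average ranks by explicit sorted-position averaging
oracle_ranks <- function(v) {
  n <- length(v)
  ord <- order(v)
  pos <- numeric(n)
  pos[ord] <- seq_len(n)
  r <- numeric(n)
  for (val in unique(v)) {
    idx <- which(v == val)
    r[idx] <- mean(pos[idx])
  }
  r
}

# Spearman rho as Pearson on oracle ranks, via explicit sums
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2)) * sqrt(sum((ry - my)^2))
  num / den
}

# naive step-by-step scaled dot-product attention with explicit loops
oracle_attention <- function(X, w) {
  n <- nrow(X)
  d <- ncol(X)
  Q <- X %*% w$W_Q
  K <- X %*% w$W_K
  V <- X %*% w$W_V
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- exp(S[i, ] - max(S[i, ]))
    A[i, ] <- e / sum(e)
  }
  list(output = A %*% V, attention = A)
}

# brute-force LCS by enumerating every subsequence of `a` (use only for
# length(a) <= 12)
oracle_lcs <- function(a, b) {
  is_subseq <- function(s, t) {
    j <- 1L
    for (x in t) {
      if (j <= length(s) && identical(s[j], x)) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  n <- length(a)
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    s <- a[sel]
    if (length(s) > best && is_subseq(s, b)) best <- length(s)
  }
  best
}

# J statistic for a list of groups (independent loop-based count)
oracle_jstat <- function(groups) {
  j <- 0
  k <- length(groups)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      for (xa in groups[[a]]) {
        for (xb in groups[[b]]) {
          if (xa < xb) j <- j + 1 else if (xa == xb) j <- j + 0.5
        }
      }
    }
  }
  j
}

# Monte-Carlo permutation p-value for the Jonckheere-Terpstra test:
# randomly reassigns pooled observations to groups, two-sided via
# distance from the permutation mean
oracle_jt_permutation_p <- function(groups, n_draws, seed) {
  pooled <- unlist(groups)
  sizes <- vapply(groups, length, integer(1))
  lab <- rep(seq_along(sizes), sizes)
  mask <- outer(lab, lab, "<")
  cmp <- outer(pooled, pooled, function(p, q) (p < q) + 0.5 * (p == q))
  j_of <- function(perm) sum(cmp[perm, perm][mask])
  j_obs <- j_of(seq_along(pooled))
  withr::with_seed(seed, {
    js <- vapply(seq_len(n_draws), function(i) {
      j_of(sample(length(pooled)))
    }, numeric(1))
    ej <- mean(js)
    mean(abs(js - ej) >= abs(j_obs - ej) - 1e-9)
  })
}

# Monte-Carlo sign-flip permutation p-value for the Wilcoxon signed-rank
# test (zeros dropped, average ranks), two-sided around the null mean
oracle_wilcoxon_permutation_p <- function(x, y, n_draws, seed) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  withr::with_seed(seed, {
    signs <- matrix(stats::runif(n_draws * n) < 0.5, n_draws, n)
    ws <- as.vector(signs %*% r)
    mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9)
  })
}

# random symmetric unit-diagonal matrix with entries in [-1, 1]
random_rsm <- function(n, seed = NULL) {
  gen <- function() {
    m <- matrix(stats::runif(n * n, -1, 1), n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    m
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# small synthetic recording with known sinusoidal content
sine_recording <- function(freqs, fs = 250, dur = 8, n_ch = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- t(vapply(seq_len(n_ch), function(ch) {
    rowSums(vapply(freqs, function(f) sin(2 * pi * f * t), numeric(length(t))))
  }, numeric(length(t))))
  continuous_recording(data, fs, paste0("ch", seq_len(n_ch)))
}

# amplitude at a given frequency from the discrete spectrum
amplitude_at <- function(x, fs, f) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  bin <- round(f * n / fs) + 1L
  max(sp[(bin - 1):(bin + 1)])
}
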