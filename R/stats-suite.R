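#' @title Nonparametric inference suite
#' @description Trend, paired and omnibus rank tests plus residual-based
#'   partial Spearman correlation, with the tie-handling and two-sided
#'   normal-approximation conventions common in commercial statistics
#'   packages (uncorrected signed Z, average ranks, ties-corrected
#'   variances). All tests return a [summarsa_test] object.
#' @name stats_suite
NULL

summarsa_test <- function(statistic, p_value, method, n, tails = "two",
                          estimate = NULL, note = NULL) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n = n, tails = tails, estimate = estimate, note = note),
    class = "summarsa_test"
  )
}

#' @export
print.summarsa_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 5),
      " p =", format(x$p_value, digits = 4),
      " (", x$tails, "-sided )\n", sep = "")
  if (!is.null(x$estimate)) {
    cat("  estimate =", format(x$estimate, digits = 5), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Jonckheere-Terpstra test for an ordered monotone trend
#'
#' Tests whether the location of `groups` increases (or decreases) along the
#' given group ordering. The statistic counts concordant cross-group pairs,
#' J = sum over ordered group pairs of #\{x_a < x_b\} + 1/2 #\{x_a = x_b\},
#' with expectation `(N^2 - sum n_i^2) / 4` and a ties-corrected variance
#' (Hollander-Wolfe form). A positive Z indicates an increasing trend.
#'
#' @param groups List of numeric vectors, one per ordered group (e.g. one
#'   vector of per-participant RSA scores per encoder layer, ordered by
#'   depth).
#' @param method `"normal"` for the two-sided normal approximation (default)
#'   or `"exact"` for full enumeration of group assignments (only for total
#'   N <= 12).
#' @param correct Apply a 0.5 continuity correction to the normal
#'   approximation (default `FALSE`, the convention of the major commercial
#'   packages; switch on for closer agreement with the exact permutation
#'   distribution at small N).
#' @return A [summarsa_test] with the Z statistic (or J for the exact test)
#'   and two-sided p-value.
#' @export
jonckheere_terpstra <- function(groups, method = c("normal", "exact"),
                                correct = FALSE) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L) {
    stop_invalid("jonckheere_terpstra() needs a list of >= 2 ordered groups")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop_invalid("empty group in jonckheere_terpstra()")
  values <- lapply(groups, function(g) {
    g <- as.numeric(g)
    if (anyNA(g)) stop_invalid("NA values in jonckheere_terpstra()")
    g
  })
  N <- sum(sizes)
  k <- length(values)

  jstat <- function(vals) {
    j <- 0
    for (a in seq_len(k - 1L)) {
      xa <- vals[[a]]
      for (b in (a + 1L):k) {
        xb <- vals[[b]]
        cmp <- outer(xa, xb, "<")
        eq <- outer(xa, xb, "==")
        j <- j + sum(cmp) + 0.5 * sum(eq)
      }
    }
    j
  }
  J <- jstat(values)
  EJ <- (N^2 - sum(sizes^2)) / 4

  pooled <- unlist(values)
  if (length(unique(pooled)) == 1L) {
    return(summarsa_test(0, 1, "Jonckheere-Terpstra trend test", N,
                         note = "all observations identical"))
  }

  if (method == "exact") {
    if (N > 12L) stop_invalid("exact Jonckheere-Terpstra limited to N <= 12")
    perms <- group_assignments(sizes)
    js <- vapply(perms, function(idx) {
      jstat(split(pooled, idx))
    }, numeric(1))
    p_ge <- mean(js >= J - 1e-12)
    p_le <- mean(js <= J + 1e-12)
    p <- min(1, 2 * min(p_ge, p_le))
    return(summarsa_test(J, p, "Jonckheere-Terpstra trend test (exact)", N))
  }

  # ties-corrected variance over the pooled sample (Hollander-Wolfe)
  tie <- as.numeric(table(pooled))
  n_i <- as.numeric(sizes)
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
           sum(tie * (tie - 1) * (2 * tie + 5))) / 72
  v2 <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(tie * (tie - 1) * (tie - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n_i * (n_i - 1)) * sum(tie * (tie - 1)) / (8 * N * (N - 1))
  v <- v1 + v2 + v3
  if (v <= 0) {
    return(summarsa_test(0, 1, "Jonckheere-Terpstra trend test", N,
                         note = "degenerate variance"))
  }
  num <- J - EJ
  if (correct && num != 0) num <- num - sign(num) * 0.5
  z <- num / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  summarsa_test(z, p, "Jonckheere-Terpstra trend test", N)
}

# Enumerate all distinct assignments of N pooled positions to ordered groups
# with the given sizes; returns a list of integer group-label vectors.
group_assignments <- function(sizes) {
  N <- sum(sizes)
  out <- list()
  recurse <- function(remaining, gi, labels) {
    if (gi > length(sizes)) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    if (gi == length(sizes)) {
      labels[remaining] <- gi
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (p in picks) {
      lab <- labels
      lab[p] <- gi
      recurse(setdiff(remaining, p), gi + 1L, lab)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  out
}

#' Spearman rank correlation with a two-sided t-approximation p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return A [summarsa_test]; `statistic` and `estimate` are rho.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 3L) {
    stop_invalid("spearman() needs equal-length vectors of length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("spearman() undefined for constant input")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  summarsa_test(rho, p, "Spearman rank correlation", n, estimate = rho)
}

#' Wilcoxon signed-rank test (normal approximation, signed Z)
#'
#' Paired test on `x - y`. Zero differences are dropped (the classical
#' convention; `zero_method = "pratt"` keeps them in the ranking), absolute
#' differences receive average ranks, and the variance is ties-corrected.
#' The sign of Z follows `x - y`: positive Z means `x` tends to exceed `y`.
#'
#' @param x,y Paired numeric vectors.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param correct Apply a 0.5 continuity correction to Z (default `FALSE`).
#' @return A [summarsa_test] with Z and the two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("wilcox", "pratt"),
                                 correct = FALSE) {
  zero_method <- match.arg(zero_method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_invalid("paired vectors differ in length")
  d <- x - y
  if (all(d == 0)) stop_invalid("all paired differences are zero")
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    w_plus <- sum(r[d > 0])
    e_w <- n * (n + 1) / 4
    tie <- as.numeric(table(r))
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  } else {
    r <- rank(abs(d))
    n_nz <- sum(d != 0)
    n0 <- sum(d == 0)
    w_plus <- sum(r[d > 0])
    n <- length(d)
    e_w <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    tie <- as.numeric(table(r[d != 0]))
    v <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie^3 - tie) / 48
    n <- n_nz
  }
  if (v <= 0) {
    return(summarsa_test(0, 1, "Wilcoxon signed-rank test", n,
                         note = "degenerate variance"))
  }
  num <- w_plus - e_w
  if (correct) num <- num - sign(num) * 0.5
  z <- num / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  summarsa_test(z, p, "Wilcoxon signed-rank test", n)
}

#' Friedman test with ties-corrected chi-square statistic
#'
#' Ranks treatments within each block (row), then compares mean ranks. With
#' ties the statistic is `(k-1) * sum((R_j - n(k+1)/2)^2) / (A - C)` where
#' `A` is the sum of squared ranks and `C = n k (k+1)^2 / 4`; without ties
#' this reduces to the textbook `12/(nk(k+1)) sum R_j^2 - 3n(k+1)`.
#'
#' @param blocks Numeric matrix, subjects/blocks in rows, treatments in
#'   columns (>= 2 of each).
#' @return A [summarsa_test] with the chi-square statistic; degrees of
#'   freedom are `ncol(blocks) - 1`.
#' @export
friedman <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (!is.numeric(blocks) || nrow(blocks) < 2L || ncol(blocks) < 2L) {
    stop_invalid("friedman() needs a numeric matrix with >= 2 rows and columns")
  }
  n <- nrow(blocks); k <- ncol(blocks)
  r <- t(apply(blocks, 1L, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 0) {
    return(summarsa_test(0, 1, "Friedman rank sum test", n,
                         note = "all within-block ranks tied"))
  }
  chi2 <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  summarsa_test(chi2, p, "Friedman rank sum test", n)
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return `pmin(1, p * m)` where `m = length(p_values)`.
#' @export
bonferroni <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Partial Spearman correlation via linear residualization
#'
#' Regresses `x` and `y` each on an intercept plus `covariate` by ordinary
#' least squares, then returns the Spearman correlation (and two-sided
#' p-value) of the two residual vectors. This is the approximate
#' nonparametric partial correlation used to control a nuisance variable
#' (here, perplexity) when relating per-layer brain similarity to per-layer
#' performance decline.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param covariate Numeric covariate of the same length. A constant
#'   covariate removes only the mean, so the result falls back to the plain
#'   Spearman correlation (noted on the result).
#' @return A [summarsa_test]; `estimate` is the partial rho (r').
#' @export
partial_spearman_residual <- function(x, y, covariate) {
  x <- as.numeric(x); y <- as.numeric(y); covariate <- as.numeric(covariate)
  n <- length(x)
  if (length(y) != n || length(covariate) != n || n < 4L) {
    stop_invalid("partial_spearman_residual() needs equal lengths >= 4")
  }
  if (stats::sd(covariate) == 0) {
    res <- spearman(x, y)
    res$note <- "constant covariate; plain Spearman returned"
    res$method <- "Partial Spearman (residual method)"
    return(res)
  }
  rx <- stats::lm.fit(cbind(1, covariate), x)$residuals
  ry <- stats::lm.fit(cbind(1, covariate), y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_invalid("constant residuals; partial correlation undefined")
  }
  res <- spearman(rx, ry)
  res$method <- "Partial Spearman (residual method)"
  res
}
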