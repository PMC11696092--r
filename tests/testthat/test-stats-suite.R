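test_that("Jonckheere-Terpstra counts concordant pairs and detects direction", {
  up <- list(c(1, 2), c(3, 4), c(5, 6))
  down <- rev(up)

  exact_up <- jonckheere_terpstra(up, method = "exact")
  expect_equal(exact_up$statistic, 12)           # all 12 cross pairs concordant
  expect_equal(oracle_jstat(up), 12)
  expect_equal(oracle_jstat(down), 0)

  z_up <- jonckheere_terpstra(up)
  z_down <- jonckheere_terpstra(down)
  expect_gt(z_up$statistic, 0)
  expect_equal(z_down$statistic, -z_up$statistic)
  expect_equal(z_down$p_value, z_up$p_value)

  # E[J] = (N^2 - sum n_i^2)/4 = (36 - 12)/4 = 6: a sample sitting at the
  # null expectation gives Z = 0
  flat <- jonckheere_terpstra(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(jonckheere_terpstra(list(c(1, 2), numeric(0))), "empty")
})

test_that("Jonckheere-Terpstra J matches the loop oracle on random draws", {
  for (s in 1:25) {
    groups <- withr::with_seed(s, {
      lapply(1:3, function(i) round(stats::rnorm(4), 1))
    })
    expect_equal(jonckheere_terpstra(groups, method = "exact")$statistic,
                 oracle_jstat(groups))
  }
})

test_that("spearman matches the explicit rank-and-Pearson oracle", {
  expect_equal(spearman(1:10, (1:10)^3)$estimate, 1)
  expect_equal(spearman(1:10, -(1:10))$estimate, -1)
  x <- c(1.2, 3.1, 3.1, 0.5, 2.2)
  y <- c(0.3, 1.1, 2.0, 2.0, 0.9)
  expect_equal(spearman(x, y)$estimate, oracle_spearman(x, y),
               tolerance = 1e-12)
  for (s in 1:20) {
    withr::with_seed(s, {
      a <- sample(1:5, 8, replace = TRUE)
      b <- stats::rnorm(8)
      if (stats::sd(a) > 0) {
        expect_equal(spearman(a, b)$estimate, oracle_spearman(a, b),
                     tolerance = 1e-12)
      }
    })
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("rank tests are invariant under strictly increasing transforms", {
  withr::with_seed(4, {
    x <- stats::rnorm(12)
    y <- stats::rnorm(12)
    groups <- split(stats::rnorm(12), rep(1:3, each = 4))
  })
  mono <- function(v) exp(v) + v^3
  expect_equal(spearman(x, y)$estimate, spearman(mono(x), mono(y))$estimate)
  expect_equal(jonckheere_terpstra(groups)$statistic,
               jonckheere_terpstra(lapply(groups, mono))$statistic)
  blocks <- cbind(x, y, x + y)
  expect_equal(friedman(blocks)$statistic, friedman(mono(blocks))$statistic)
})

test_that("Wilcoxon signed-rank Z follows x - y and matches base R p-values", {
  withr::with_seed(9, y <- stats::rnorm(10))
  up <- wilcoxon_signed_rank(y + 2, y)
  expect_gt(up$statistic, 0)
  swapped <- wilcoxon_signed_rank(y, y + 2)
  expect_equal(swapped$statistic, -up$statistic)
  expect_equal(swapped$p_value, up$p_value)

  for (s in 1:15) {
    withr::with_seed(s, {
      a <- stats::rnorm(12)
      b <- a + stats::rnorm(12, sd = 0.8)
    })
    ours <- wilcoxon_signed_rank(a, b)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
    )
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("Friedman chi-square handles ties, degeneracy and matches base R", {
  same <- matrix(rep(c(1, 5, 9), 3), nrow = 3, byrow = TRUE)
  ident <- friedman(cbind(same[, 1], same[, 1], same[, 1]))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # 13 blocks all ranking 3 treatments identically: chi2 = 2 n with no ties
  conc <- withr::with_seed(2, {
    t(replicate(13, sort(stats::rnorm(3))))
  })
  expect_equal(friedman(conc)$statistic, 2 * 13)

  for (s in 1:50) {
    m <- withr::with_seed(100 + s, matrix(stats::rnorm(18), 6, 3))
    ours <- friedman(m)
    ref <- stats::friedman.test(m)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("bonferroni multiplies and clips", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroni(c(0.5, 0.9)), c(1, 1))
  expect_equal(bonferroni(0.2), 0.2)
  expect_error(bonferroni(c(0.1, 1.2)), "0, 1")
})

test_that("partial Spearman residualization removes the covariate", {
  withr::with_seed(11, {
    x <- stats::rnorm(50)
    y <- stats::rnorm(50)
  })
  plain <- spearman(x, y)
  const <- partial_spearman_residual(x, y, rep(3, 50))
  expect_equal(const$estimate, plain$estimate)
  expect_match(const$note, "constant covariate")

  # y driven by the covariate: residualizing kills the correlation
  r_kill <- withr::with_seed(13, replicate(30, {
    cov <- stats::rnorm(200)
    y2 <- cov + stats::rnorm(200, sd = 0.05)
    x2 <- stats::rnorm(200)
    partial_spearman_residual(x2, y2, cov)$estimate
  }))
  expect_lt(mean(abs(r_kill)), 0.1)

  # independent covariate: partial rho stays close to plain rho
  diff_r <- withr::with_seed(12, replicate(50, {
    x3 <- stats::rnorm(200); y3 <- stats::rnorm(200); c3 <- stats::rnorm(200)
    abs(partial_spearman_residual(x3, y3, c3)$estimate -
          spearman(x3, y3)$estimate)
  }))
  expect_lt(mean(diff_r), 0.1)
})
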