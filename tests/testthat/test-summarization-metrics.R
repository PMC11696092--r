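test_that("ROUGE-N reproduces hand-enumerated overlap counts", {
  same <- rouge_n("the cat sat", "the cat sat", 1)
  expect_equal(c(same$precision, same$recall, same$f1), c(1, 1, 1))

  r <- rouge_n("the cat sat", "the cat slept", 1)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$precision, 2 / 3)

  expect_equal(rouge_n("aa bb", "cc dd", 1)$f1, 0)
  expect_equal(rouge_n("a b c", "a b c", 2)$recall, 1)
  # clipping: candidate repeats a reference unigram
  rep_r <- rouge_n(c("a", "a", "a"), c("a", "b"), 1)
  expect_equal(rep_r$recall, 1 / 2)
  expect_equal(rep_r$precision, 1 / 3)
  expect_equal(rouge_n("", "a b", 1)$f1, 0)
})

test_that("ROUGE-L uses the longest common subsequence", {
  expect_equal(rouge_l("x y z", "x y z")$f1, 1)
  r <- rouge_l("a b c d", "a c b d")
  expect_equal(r$recall, 3 / 4)   # LCS is a b d (or a c d)
  expect_equal(rouge_l("", "a b")$f1, 0)
  expect_equal(rouge_l("q r s", "x y z")$f1, 0)
})

test_that("LCS matches brute-force subsequence enumeration on 50 cases", {
  for (s in 1:50) {
    withr::with_seed(300 + s, {
      a <- sample(letters[1:4], sample(3:8, 1), replace = TRUE)
      b <- sample(letters[1:4], sample(3:8, 1), replace = TRUE)
    })
    expect_equal(summarsa:::lcs_length(a, b), oracle_lcs(a, b))
  }
})

test_that("swapping candidate and reference swaps precision and recall", {
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      cand <- sample(letters[1:5], 6, replace = TRUE)
      ref <- sample(letters[1:5], 9, replace = TRUE)
    })
    for (fn in list(function(a, b) rouge_n(a, b, 1),
                    function(a, b) rouge_n(a, b, 2),
                    rouge_l)) {
      ab <- fn(cand, ref)
      ba <- fn(ref, cand)
      expect_equal(ab$precision, ba$recall)
      expect_equal(ab$recall, ba$precision)
      expect_equal(ab$f1, ba$f1)
    }
  }
})

test_that("appending a reference n-gram never decreases recall", {
  for (s in 1:20) {
    withr::with_seed(500 + s, {
      cand <- sample(letters[1:4], 5, replace = TRUE)
      ref <- sample(letters[1:4], 7, replace = TRUE)
      extra <- ref[sample(7, 1)]
    })
    expect_gte(rouge_n(c(cand, extra), ref, 1)$recall,
               rouge_n(cand, ref, 1)$recall)
  }
})

test_that("perplexity is exp of the negative mean log-probability", {
  expect_equal(perplexity(rep(log(1 / 4), 10)), 4)
  expect_equal(perplexity(rep(0, 5)), 1)
  expect_equal(perplexity(c(log(1 / 2), log(1 / 8))), 4, tolerance = 1e-9)
  expect_error(perplexity(numeric(0)), "non-empty")
  expect_error(perplexity(c(-1, 0.2)), "<= 0")
})

test_that("generated toy corpus ground truth matches the metric functions", {
  corpus <- generate_toy_corpus(12, seed = 31, ref_len = 7)
  kinds <- vapply(corpus, function(r) r$truth$kind, character(1))
  expect_setequal(unique(kinds), c("identical", "mutated", "disjoint",
                                   "shuffled"))
  for (rec in corpus) {
    n_ref <- length(rec$reference)
    n_cand <- length(rec$candidate)
    r1 <- rouge_n(rec$candidate, rec$reference, 1)
    expect_equal(r1$recall, rec$truth$unigram_overlap / n_ref)
    expect_equal(r1$precision, rec$truth$unigram_overlap / n_cand)
    r2 <- rouge_n(rec$candidate, rec$reference, 2)
    expect_equal(r2$recall, rec$truth$bigram_overlap / (n_ref - 1))
    rl <- rouge_l(rec$candidate, rec$reference)
    expect_equal(rl$recall, rec$truth$lcs / n_ref)
    if (rec$truth$kind == "identical") expect_equal(r1$recall, 1)
    if (rec$truth$kind == "disjoint") {
      expect_equal(rec$truth$unigram_overlap, 0)
      expect_equal(rl$f1, 0)
    }
    if (rec$truth$kind == "shuffled") expect_equal(r1$recall, 1)
  }
})

test_that("stored LCS truth matches brute-force enumeration", {
  corpus <- generate_toy_corpus(8, seed = 77, ref_len = 6)
  for (rec in corpus) {
    expect_equal(rec$truth$lcs, oracle_lcs(rec$candidate, rec$reference))
  }
})

test_that("decline table bookkeeping preserves signs and reports gaps", {
  base <- c(rouge1 = 0.5, rouge2 = 0.3, rougeL = 0.45, perplexity = 5)
  manip <- data.frame(layer = c(1, 2, 3), surgery = "ablate",
                      rouge1 = c(0.5, 0.4, 0.6),
                      rouge2 = c(0.3, 0.2, 0.35),
                      rougeL = c(0.45, 0.35, 0.5),
                      perplexity = c(5, 6, 4.5))
  d <- compute_decline(base, manip)
  expect_equal(d$layer[1], "w/o")
  expect_equal(d$rouge1_decline[1], 0)
  expect_equal(d$rouge1_decline[d$layer == "1"], 0)
  expect_equal(d$rouge1_decline[d$layer == "2"], 0.1)
  expect_equal(d$rouge1_decline[d$layer == "3"], -0.1)

  expect_warning(compute_decline(base, manip, layers = 1:4), "missing layer")
  expect_error(compute_decline(base[1:3], manip), "perplexity")
})
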