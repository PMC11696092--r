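# a small, fast configuration for orchestration unit tests (the documented
# default study conditions are exercised in the acceptance suite)
small_config <- function(seed = 1L, ...) {
  study_config(
    seed = seed,
    study = synthetic_study_config(n_participants = 3L, n_words = 30L,
                                   seed = seed + 1L),
    n_layers = 6L, dim = 32L, ...
  )
}

test_that("the full study run is deterministic given one seed", {
  a <- run_full_study(small_config(5))
  b <- run_full_study(small_config(5))
  expect_identical(a$rsa$avg_scores, b$rsa$avg_scores)
  expect_identical(a$rsa$jt_table, b$rsa$jt_table)
  expect_identical(a$manipulation$decline, b$manipulation$decline)
  expect_identical(a$correlation, b$correlation)
})

test_that("RSA analysis tables have the expected shape and planted trend", {
  res <- run_rsa_analysis(small_config(7))

  expect_setequal(unique(res$avg_scores$condition[
    res$avg_scores$encoder == "trained"]),
    c("full", "early", "late", "baseline"))
  expect_equal(nrow(res$avg_scores[res$avg_scores$encoder == "trained" &
                                     res$avg_scores$condition == "full", ]),
               6)

  jt <- res$jt_table
  for (cond in c("full", "early", "late")) {
    row <- jt[jt$encoder == "trained" & jt$condition == cond, ]
    expect_gt(row$z, 0)
    expect_lt(row$p, 0.05)
  }
  expect_equal(nrow(jt[jt$encoder == "control", ]), 3)

  expect_equal(res$friedman$df, 2)
  expect_equal(nrow(res$posthoc), 3)
  expect_true(all(res$posthoc$p_bonferroni >= res$posthoc$p))
  expect_equal(nrow(res$exp_vs_control), 6)
})

test_that("manipulation experiment bookkeeping matches the layer grid", {
  cfg <- small_config(3)
  res <- run_manipulation_experiment(cfg)
  d <- res$decline

  expect_equal(nrow(d), 2 * (cfg$n_layers + 2) - 1)
  wo <- d[d$layer == "w/o", ]
  expect_equal(nrow(wo), 1)
  expect_equal(wo$rouge1_decline, 0)
  expect_equal(wo$rouge2_decline, 0)
  expect_equal(wo$rougeL_decline, 0)

})

test_that("manipulating every layer is at least as damaging as the worst one", {
  cfg <- study_config(seed = 3)   # default 16-layer toy setup
  d <- run_manipulation_experiment(cfg)$decline
  for (s in c("ablate", "noise")) {
    singles <- d$rouge1_decline[d$surgery == s &
                                  d$layer %in% as.character(1:cfg$n_layers)]
    all_row <- d$rouge1_decline[d$surgery == s & d$layer == "all"]
    expect_gte(all_row, max(singles))
  }
})

test_that("correlation analysis recovers exact and planted relationships", {
  rsa_table <- data.frame(condition = "full", layer = 1:8,
                          rho = seq(0.1, 0.8, by = 0.1))
  # decline strictly increasing in RSA: Spearman r = 1
  dt <- data.frame(layer = 1:8, surgery = "ablate",
                   rouge1_decline = (seq(0.1, 0.8, by = 0.1))^2,
                   rouge2_decline = 0.5 * seq(0.1, 0.8, by = 0.1),
                   rougeL_decline = exp(seq(0.1, 0.8, by = 0.1)),
                   perplexity = rep(c(5, 6), 4))
  out <- run_correlation_analysis(rsa_table, dt)
  expect_equal(out$r[out$variant == "rouge1"], 1)
  expect_equal(out$r[out$variant == "rougeL"], 1)

  # planted coupling with noise: positive and significant partial rho
  rsa <- seq(0.02, 0.9, length.out = 16)
  cp <- simulate_decline_coupling(rsa, seed = 2)
  dt2 <- data.frame(layer = cp$layer, surgery = "noise",
                    rouge1_decline = cp$decline,
                    rouge2_decline = cp$decline,
                    rougeL_decline = cp$decline,
                    perplexity = cp$perplexity)
  out2 <- run_correlation_analysis(
    data.frame(condition = "full", layer = 1:16, rho = rsa), dt2
  )
  expect_gt(out2$r_prime[out2$variant == "rouge1"], 0)
  expect_lt(out2$p_prime[out2$variant == "rouge1"], 0.05)

  expect_error(
    run_correlation_analysis(
      data.frame(condition = "full", layer = 1:3, rho = 1:3 / 10),
      dt[dt$layer <= 3, ]
    ),
    "fewer than 4"
  )
})

test_that("full study writes the complete CSV table set", {
  out_dir <- withr::local_tempdir()
  run_full_study(small_config(9), out_dir = out_dir)
  files <- list.files(out_dir)
  expect_setequal(files, c("rsa_scores.csv", "trend_tests.csv",
                           "friedman.csv", "posthoc_wilcoxon.csv",
                           "exp_vs_control.csv", "decline_table.csv",
                           "rsa_decline_correlation.csv"))
  dec <- utils::read.csv(file.path(out_dir, "decline_table.csv"))
  expect_equal(names(dec)[1:6],
               c("layer", "surgery", "rouge1", "rouge2", "rougeL",
                 "perplexity"))
})
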