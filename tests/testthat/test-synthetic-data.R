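test_that("latent geometry is deterministic with planted cluster contrast", {
  g <- generate_latent_token_geometry(2, 1, seed = 7)
  expect_equal(unname(diag(g$target_rsm)), c(1, 1))

  g1 <- generate_latent_token_geometry(30, 3, seed = 1)
  g2 <- generate_latent_token_geometry(30, 3, seed = 1)
  expect_identical(g1$latent, g2$latent)

  rsm <- unclass(g1$target_rsm)
  same <- outer(g1$cluster, g1$cluster, "==") & upper.tri(rsm)
  diff <- outer(g1$cluster, g1$cluster, "!=") & upper.tri(rsm)
  expect_gt(mean(rsm[same]), mean(rsm[diff]))

  expect_error(generate_latent_token_geometry(5, 6, seed = 1), "n_clusters")
  expect_error(generate_latent_token_geometry(1, 1, seed = 1), "n_tokens")
})

test_that("layer states interpolate between pure geometry and pure noise", {
  geom <- generate_latent_token_geometry(200, 5, seed = 3)

  aligned <- generate_layer_states(
    geom, list(per_layer_alignment = 1, noise_scale = 0), dim = 16, seed = 4
  )
  expect_equal(rsa_score(cosine_rsm(aligned[[1]]), geom$target_rsm)$rho, 1,
               tolerance = 1e-9)

  nulls <- vapply(1:20, function(s) {
    st <- generate_layer_states(
      geom, list(per_layer_alignment = 0, noise_scale = 1), dim = 16,
      seed = 40 + s
    )
    rsa_score(cosine_rsm(st[[1]]), geom$target_rsm)$rho
  }, numeric(1))
  expect_lt(mean(abs(nulls)), 0.1)

  expect_error(generate_layer_states(geom,
                                     list(per_layer_alignment = numeric(0),
                                          noise_scale = 0.1), 16, 1),
               "empty")
  expect_error(generate_layer_states(geom,
                                     list(per_layer_alignment = 0.5,
                                          noise_scale = 0.1), 4, 1),
               "dim")
})

test_that("a monotone schedule yields an increasing per-layer RSA trend", {
  geom <- generate_latent_token_geometry(80, 4, seed = 5)
  st <- generate_layer_states(geom, alignment_schedule(8, noise_scale = 0.3),
                              dim = 32, seed = 6)
  scores <- vapply(st, function(s) {
    rsa_score(cosine_rsm(s), geom$target_rsm)$rho
  }, numeric(1))
  jt <- jonckheere_terpstra(as.list(scores))
  expect_gt(jt$statistic, 0)
  expect_lt(jt$p_value, 0.05)
})

test_that("the synthetic EEG study is deterministic and correctly laid out", {
  cfg <- synthetic_study_config(n_participants = 2, n_words = 5, seed = 9)
  geom <- generate_latent_token_geometry(5, 2, seed = 10)
  a <- generate_eeg_study(geom, cfg)
  b <- generate_eeg_study(geom, cfg)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$recordings[[2]]$data, b$recordings[[2]]$data)
  expect_false(identical(a$recordings[[1]]$data, a$recordings[[2]]$data))

  expect_true(all(diff(a$events$onset_s) >= 1.7 - 1e-9))
  expect_equal(nrow(a$token_map), 5)
  expect_equal(length(a$recordings), 2)
  expect_equal(nrow(a$recordings[[1]]$data), 28)

  expect_error(synthetic_study_config(snr = 0), "snr")
  cfg2 <- synthetic_study_config(n_words = 6, tokens_per_word = c(1L, 2L),
                                 seed = 2)
  counts <- token_counts(cfg2)
  expect_length(counts, 6)
  expect_true(all(counts %in% 1:2))
  expect_identical(counts, token_counts(cfg2))
})

test_that("word responses carry the planted geometry, baselines do not", {
  cfg <- synthetic_study_config(n_participants = 1, n_words = 40,
                                snr = 1e6, seed = 21)
  geom <- generate_latent_token_geometry(40, 4, seed = 22)
  eeg <- generate_eeg_study(geom, cfg)
  ep <- average_reference(
    epoch_and_align(bandpass_filter(eeg$recordings[[1]]),
                    eeg$events, eeg$token_map)
  )
  brain <- cosine_rsm(build_condition_vectors(ep, "full")$vectors)
  expect_gt(rsa_score(brain, geom$target_rsm)$rho, 0.9)

  # pre-onset baseline windows contain noise only
  nulls <- vapply(1:5, function(s) {
    cfg_s <- synthetic_study_config(n_participants = 1, n_words = 40,
                                    snr = 1, seed = 30 + s)
    geom_s <- generate_latent_token_geometry(40, 4, seed = 60 + s)
    eeg_s <- generate_eeg_study(geom_s, cfg_s)
    ep_s <- average_reference(
      epoch_and_align(bandpass_filter(eeg_s$recordings[[1]]),
                      eeg_s$events, eeg_s$token_map)
    )
    base <- cosine_rsm(build_condition_vectors(ep_s, "baseline")$vectors)
    rsa_score(base, geom_s$target_rsm)$rho
  }, numeric(1))
  expect_lt(mean(abs(nulls)), 0.1)
})

test_that("mean RSA score is non-decreasing in snr", {
  score_at <- function(snr, seed) {
    cfg <- synthetic_study_config(n_participants = 1, n_words = 40,
                                  snr = snr, seed = seed)
    geom <- generate_latent_token_geometry(40, 4, seed = seed + 500)
    eeg <- generate_eeg_study(geom, cfg)
    ep <- average_reference(
      epoch_and_align(bandpass_filter(eeg$recordings[[1]]),
                      eeg$events, eeg$token_map)
    )
    brain <- cosine_rsm(build_condition_vectors(ep, "full")$vectors)
    rsa_score(brain, geom$target_rsm)$rho
  }
  means <- vapply(c(0.1, 1, 10), function(snr) {
    mean(vapply(1:3, function(s) score_at(snr, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("decline coupling plants a recoverable positive association", {
  rsa <- seq(0.05, 0.8, length.out = 16)
  d1 <- simulate_decline_coupling(rsa, seed = 1)
  d2 <- simulate_decline_coupling(rsa, seed = 1)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 16)
  ps <- partial_spearman_residual(rsa, d1$decline, d1$perplexity)
  expect_gt(ps$estimate, 0)
  expect_error(simulate_decline_coupling(rsa[1:3]), ">= 4")
})
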