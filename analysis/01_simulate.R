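#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study inputs.
#
# Generates the latent token geometry shared between "brain" and "model",
# the word-locked 28-channel EEG recordings for 13 participants, the
# encoder layer states with a monotone depth-alignment schedule, and a toy
# corpus with stored ROUGE ground truth. Writes the text-format interchange
# files under results/simulated/.

suppressPackageStartupMessages(library(summarsa))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(seed = seed)
counts <- token_counts(cfg$study)
geometry <- generate_latent_token_geometry(
  sum(counts), cfg$n_clusters, seed = summarsa:::derive_seed(seed, 1L),
  d_latent = cfg$d_latent
)
eeg <- generate_eeg_study(geometry, cfg$study)

write_events_tsv(eeg$events, file.path(out_dir, "events.tsv"))
write_token_map_tsv(eeg$token_map, file.path(out_dir, "token_map.tsv"))
write_matrix_tsv(unclass(geometry$target_rsm),
                 file.path(out_dir, "target_rsm.tsv"))
# one participant's recording as an example of the continuous format
write_matrix_tsv(eeg$recordings[[1]]$data[, 1:500],
                 file.path(out_dir, "participant01_excerpt.tsv"))

corpus <- generate_toy_corpus(8, seed = summarsa:::derive_seed(seed, 6L))
write_corpus_jsonl(corpus, file.path(out_dir, "toy_corpus.jsonl"))

cat("Simulated", cfg$study$n_participants, "participants x",
    cfg$study$n_words, "words (", sum(counts), "tokens ) at",
    cfg$study$sampling_rate, "Hz;", cfg$n_layers,
    "encoder layers with a monotone alignment schedule.\n")
cat("Interchange files written to", out_dir, "\n")
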