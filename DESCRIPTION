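Package: summarsa
Title: Representational Similarity Between EEG and Summarization Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for representational similarity analysis (RSA)
    between word-locked EEG responses and the per-layer hidden states of a
    transformer encoder used for abstractive summarization. Provides ERP-style
    EEG preprocessing (band-pass filtering, epoching, baseline correction,
    average re-referencing) and spatiotemporal condition vectors (full window,
    N400-like early window, P600-like late window, pre-stimulus baseline);
    cosine representational similarity matrices and Spearman RSA scores; a
    deterministic toy transformer encoder with layer-wise attention ablation
    and weight-noise surgeries; ROUGE-1/2/L and perplexity scoring with
    per-layer performance-decline bookkeeping; a nonparametric inference suite
    (Jonckheere-Terpstra trend test, Friedman, Wilcoxon signed-rank, Bonferroni
    correction, residual-based partial Spearman); and seeded synthetic-data
    generators that plant a shared representational geometry so the whole
    pipeline is testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
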