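# summarsa

Representational similarity analysis (RSA) between word-locked EEG and the
per-layer hidden states of a transformer encoder used for abstractive
summarization — as a reusable, tested R package plus a small analysis
workflow.

## The problem

When people read a text word by word, their EEG carries a representation of
the unfolding stimuli; a summarization model's encoder builds its own
representation of the same tokens, layer by layer. RSA compares the two
systems without mapping one feature space onto the other. Each system is
reduced to an n x n **representational similarity matrix** over the n
tokens,

    S_ij = cos(h_i, h_j)            (model layer: hidden states h)
    B_ij = cos(e_i, e_j)            (participant: EEG condition vectors e)

and the **RSA score** of a layer and a participant is the Spearman rank
correlation rho of the strict upper triangles of S and B, averaged over
participants. EEG vectors are built under four spatiotemporal conditions
(full window 0–1500 ms over all 28 electrodes; an N400-like early window,
250–450 ms over centro-parietal sites; a P600-like late window, 500–800 ms;
and a pre-stimulus baseline control).

Three analyses sit on top:

1. **Depth trend** — does the layer-wise RSA score increase with encoder
   depth? (Jonckheere–Terpstra trend test on the participant-averaged layer
   scores; Friedman + Wilcoxon/Bonferroni comparisons across conditions and
   against baseline and randomly-initialized controls.)
2. **Layer manipulation** — how much does summarization quality (ROUGE-1/2/L)
   drop when one layer's attention is ablated (W_Q = W_K = 0, W_V = I, i.e.
   exactly uniform attention) or its weights receive relative-scale Gaussian
   noise?
3. **Coupling** — is a layer's brain similarity correlated with the damage
   its manipulation causes, after controlling per-layer perplexity with a
   residual-based partial Spearman correlation (r')?

Everything runs on seeded synthetic data with a planted shared geometry, so
the whole chain is testable offline; exported hidden states and preprocessed
EEG from real experiments can be substituted through the same matrix
interfaces. See `vignettes/summarsa-methods.Rmd` for the full methods
account.

## Worked example

```r
library(summarsa)

cfg <- study_config(seed = 1)        # 13 participants, 60 words, 16 layers
res <- run_full_study(cfg)

res$rsa$jt_table
#>   encoder condition     z        p
#> 1 trained  baseline  1.71 8.71e-02
#> 2 trained     early  5.13 2.86e-07
#> 3 trained      full  5.40 6.56e-08
#> 4 trained      late  5.22 1.76e-07
#> 5 control     early  0.18 8.57e-01
#> 6 control      full -0.45 6.53e-01
#> 7 control      late  0.72 4.71e-01
```

The trained-equivalent encoder shows the planted positive depth trend in
every signal-bearing condition (z > 0 at tiny p), and the
randomly-initialized control does not. The manipulation stage yields a
per-layer decline table shaped like a layer-ablation results table:

```r
head(res$manipulation$decline[, c("layer", "surgery", "rouge1",
                                  "rouge1_decline", "perplexity")], 3)
#>   layer surgery rouge1 rouge1_decline perplexity
#> 1   w/o    none   0.43           0.00      4.623
#> 2     1  ablate   0.43           0.00      4.612
#> 3     2  ablate   0.41           0.02      4.623
```

and `res$correlation` reports r/p and partial r'/p' per condition, surgery
and ROUGE variant. With the planted decline–RSA coupling the partial
correlation is recovered in essentially every seeded replicate:

```r
reps <- replicate_study(20, seed = 1)
sum(reps$jt_p < 0.05 & reps$jt_z > 0)        # 20 of 20: depth trend
sum(reps$p_prime < 0.05 & reps$r_prime > 0)  # 20 of 20: planted coupling
```

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R`, `02_rsa.R`, `03_manipulate.R`, `04_correlate.R`;
each takes an optional seed argument) and write their tables under
`results/`.

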