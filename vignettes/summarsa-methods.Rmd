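---
title: "Brain-model representational similarity for summarization encoders: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-model representational similarity for summarization encoders: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(summarsa)
```

## The scientific question

Transformer encoders used for abstractive summarization build a
representation of a document layer by layer. EEG recorded while people read
the same text word by word gives an independent representation of the same
stimuli. Representational similarity analysis (RSA) compares the two systems
without requiring any common feature space: each system is summarized by an
n x n matrix of pairwise similarities between its responses to the n tokens
(a representational similarity matrix, RSM), and the two geometries are
compared by rank correlation of those matrices. `summarsa` implements this
comparison as a tested pipeline, together with the two follow-up analyses it
supports: layer-wise weight surgeries that measure each encoder layer's
contribution to summarization quality, and the correlation between a layer's
brain similarity and the damage its manipulation causes, controlling for
perplexity.

Because recorded EEG and full-scale pretrained checkpoints are not required
for any of the package's claims, the package ships a seeded synthetic-data
module that plants a known shared geometry in both systems. Every stage is
tested against that planted ground truth; hidden states exported from real
models and real preprocessed EEG can be substituted through the same matrix
interfaces.

## Models and procedures

### EEG pipeline

The pipeline follows standard ERP practice, in this order:

1. **Band-pass filtering**, 0.5-30 Hz, order-4 Butterworth applied
   forward and backward (zero phase). The implementation is a filtfilt with
   odd-reflection edge padding and steady-state initial conditions, with the
   per-channel recursion in C++; it agrees with `signal::filtfilt` away from
   record edges and satisfies passband/stopband checks in the tests
   (DC < 1%, 10 Hz within 5%, 60 Hz attenuated by > 20 dB).
2. **Epoching**: a 1700 ms window per word (-200 to +1500 ms around onset;
   425 samples at 250 Hz), with the channel-wise mean of the [-200, 0) ms
   interval subtracted from the whole epoch. Tokens of a multi-token word
   share the word's epoch verbatim.
3. **Average re-referencing**: each sample re-expressed relative to the
   instantaneous mean over all electrodes.
4. **Condition vectors**: electrode-major concatenation of the samples in a
   spatiotemporal window.

The four conditions are:

| condition | electrodes | window (ms) | dimension at 250 Hz |
|---|---|---|---|
| full | all 28 | 0-1500 | 28 x 375 = 10500 |
| early (N400-like) | C3, Cz, C4, P3, Pz, P4, CP1, CP2 | 250-450 | 8 x 50 = 400 |
| late (P600-like) | C3, Cz, C4, P3, Pz, P4 | 500-800 | 6 x 75 = 450 |
| baseline (pre-stimulus control) | all 28 | -200-0 | 28 x 50 = 1400 |

Windows are half-open `[start, end)` in milliseconds, which makes the full
window exactly 375 samples at 250 Hz. The baseline condition uses all
electrodes and the 50 pre-onset samples, hence dimension 1400; it is a
control whose windows carry no stimulus-locked signal.

### RSA

Model-side and brain-side RSMs use cosine similarity between token feature
vectors. The RSA score between two RSMs is the Spearman rank correlation
(average ranks on ties) of their strict upper triangles, vectorized in R's
column-major `upper.tri()` order — any fixed consistent order gives the same
correlation. Scores are computed per participant and then averaged
arithmetically (a Fisher-z option exists but is off by default, because the
analysis averages correlations directly). Duplicate token rows from shared
word epochs are retained, including their similarity-1 pairs.

### Encoder and surgeries

The package includes a minimal deterministic single-head, post-norm
transformer encoder (`LN(X + Attn(X) W_O)` then `LN(X + FFN(X))`, GELU FFN)
whose per-layer hidden states and attention matrices are exposed. It exists
to make the two surgeries testable offline:

* **Attention ablation** sets `W_Q = W_K = 0` and `W_V = I`, so the softmax
  sees all-zero logits and every attention probability is exactly `1/n`.
* **Noise addition** perturbs each weight matrix `M` with i.i.d. Gaussian
  noise of sd `sigma_rel * sd(M)`. The relative parameterization makes one
  `sigma_rel` meaningful across matrices of different scale; the default
  surgery strength is `sigma_rel = 1`, applied to all attention projections
  and FFN weights (configurable subset).

Weight initialization scales the residual-branch output projections `W_O`
and `W2` by `1/sqrt(2L)` by default. An unscaled deep random post-norm stack
suffers rank collapse — all token states converge and token identity becomes
unrecoverable — which is a property of untrained stacks, not of the trained
models the encoder stands in for; depth-scaled initialization keeps the
residual stream informative at any depth.

### Summarization metrics

ROUGE-1/2/L are implemented from first principles (clipped n-gram overlap;
LCS by dynamic programming) on lowercased, punctuation-stripped,
whitespace-split tokens; no stemming or stopword removal. Precision, recall
and f1 are always reported; f1 is the headline value. Perplexity is
`exp(-mean(log p))` over token log-probabilities. The decline table records
`baseline - manipulated` per ROUGE variant, preserving negative declines
(improvements), with a single shared `"w/o"` baseline row.

### Statistics

All tests are two-sided with the conventions of the major commercial
packages: average ranks, ties-corrected variances, uncorrected signed Z.

* **Jonckheere-Terpstra**: concordant cross-group pair count J with
  `E[J] = (N^2 - sum n_i^2)/4` and the Hollander-Wolfe ties-corrected
  variance; exact enumeration available for N <= 12. Verified against a
  permutation oracle and calibrated to 0.05 +/- 0.02 type-I error on
  exchangeable groups.
* **Wilcoxon signed-rank**: zeros dropped (Pratt variant available),
  ties-corrected normal approximation, Z signed by `x - y`, continuity
  correction off by default.
* **Friedman**: ties-corrected chi-square over within-block ranks.
* **Partial Spearman (residual method)**: each variable is regressed on an
  intercept plus the covariate by OLS; the Spearman correlation of the two
  residual vectors is the partial coefficient r'.

## The synthetic study and its defaults

The generator plants a latent geometry and expresses it in both systems:

* **Latent geometry**: `n_clusters = 5` cluster means on the unit
  hypersphere in `d_latent = 8` dimensions, tokens scattered around their
  mean with sd 0.35. This gives a controllable RSM contrast with two
  parameters.
* **Layer states**: layer l is `a_l * (Z R_l') + (1 - a_l) * E_l`, with
  `R_l` a random orthonormal embedding into `dim = 64` (inner products of
  the latent rows are preserved exactly, so `a_l = 1` with no noise
  reproduces the target RSM to machine precision) and `E_l` independent
  noise. The default monotone schedule `a_l = l/L` over `L = 16` layers
  emulates similarity that rises with encoder depth; `noise_scale = 1`
  makes the rise gradual over the whole depth rather than saturating after
  a few layers. A constant schedule is the no-trend null.
* **EEG**: 13 participants, 60 words at one token per word, 28-channel
  10-20 montage, 250 Hz, words presented for 1500 ms with onsets 1700 ms
  apart. Each word's 0-1500 ms response is an orthonormal electrode mixing
  of the word's latent vector (shared across participants) times a smooth
  temporal kernel supported on 100-1200 ms and peaking at 650 ms, so both
  the early (250-450 ms) and late (500-800 ms) windows carry signal and
  the pre-onset baseline does not. Noise is white noise spectrally shaped
  to the 0.5-30 Hz band (the same order-4 Butterworth magnitude response
  applied zero-phase in the frequency domain), scaled per participant so
  the signal-to-noise amplitude ratio equals `snr = 1`.
* **Toy summarizer**: documents of 24 tokens with 5 planted keywords from a
  60-token vocabulary. Two linear readouts are ridge-fit on the *intact*
  encoder's final states: a keyword scorer that selects summary positions
  and a token decoder (logits sharpened x8) that maps states back to
  vocabulary tokens and supplies perplexity. Any weight surgery moves the
  states away from the calibration distribution and degrades ROUGE and
  perplexity deterministically. This is a synthetic probe model — a seeded
  stand-in that makes surgery effects measurable — not a trained
  summarizer.
* **Planted coupling**: for correlation-recovery checks, declines are
  generated as `beta * rsa_l + gamma * (pplx_l - mean) + noise` with
  `beta = 1`, `gamma = 0.02` and noise sd equal to 30% of the signal sd.

The word count (60 rather than the ~1400 of a full reading study) and the
replicate counts used in the tests were chosen so that hundred-replicate
calibration loops are routine on a single CPU; the planted-effect strengths
are set so recovery is comfortable but not degenerate (partial r' typically
0.7-0.95 at 16 layers).

### What the generator does and does not emulate

It emulates: the recording geometry and rate, word-locked epoching with
token sharing, signal confined to the post-onset window, band-limited noise,
depth-graded model-brain alignment, and a depth-correlated performance
decline. It does not emulate: ocular/muscle artifacts and bad channels (the
pipeline accepts pre-cleaned data; artifact removal is delegated to standard
preprocessing tools), volume-conduction realism or source geometry, realistic
RSA effect sizes (planted-geometry scores are far larger than the ~1e-2
correlations typical of real EEG-model comparisons), and language itself.
Passing tests therefore demonstrate correctness of the computations and
calibration of the inference under known ground truth — not that real EEG
would show these effects.

## Design choices in the inference pipeline

Three choices deserve explicit justification.

**The depth-trend test runs on participant-averaged layer scores.** The
per-layer scores of different participants share the same model layer
states, so layer-level randomness is common to all participants. Feeding all
participant x layer observations into the trend test treats that shared
variation as if it were independent replication and grossly inflates the
false-positive rate under a no-trend null (in our calibration runs, roughly
half of null replicates rejected). Averaging over participants first and
testing the 16 layer means (the singleton-group limit of the
Jonckheere-Terpstra statistic, equivalent to a Mann-Kendall trend test)
makes layers the exchangeable unit; measured null rejection is at the
nominal level. The per-participant score table is still produced and saved.

**The randomly-initialized control re-initializes per layer.** A single
untrained encoder's geometry converges deterministically as depth grows, so
its similarity to any fixed brain RSM drifts monotonically toward a random
asymptote — an untrained stack fakes depth trends of random sign. Drawing an
independently initialized encoder for each layer (same random embedding
input) gives every control layer an independent drift direction, restoring
exchangeability; measured null rejection is at the nominal level. This is a
property worth knowing about untrained deep stacks: "no training" does not
imply "no depth trend".

**Per-layer perplexity pairs with the intact encoder's RSA scores.** The
correlation analysis relates the *intact* layer's brain similarity to the
damage caused by manipulating that layer, and controls for the perplexity
measured under that same manipulation, mirroring how the decline table is
constructed.

Other conventions: 1-based layer indexing in all outputs; `[start, end)`
sample windows; exact behavior on degenerate inputs (constant rank inputs
raise errors rather than returning NaN; all-zero paired differences raise an
error; a constant covariate falls back to the plain Spearman with a note).

## Numerical choices

* Cosine similarities are clamped to [-1, 1] and symmetrized against
  floating-point asymmetry; zero-norm feature rows are an error naming the
  row.
* The zero-phase filter pads with odd reflection (3 x filter order) and
  starts both passes from the steady-state response, avoiding start-up
  transients; records must exceed the padding length.
* Seeds: every generator takes an explicit integer seed and restores the
  caller's RNG state; child streams are derived arithmetically and stay
  below 2^31.
* Ridge regressions in the toy summarizer use lambda = 0.01 n.

## Known limitations

* The EEG forward model is linear and instantaneous per electrode; no
  volume conduction, latency jitter, or trial-to-trial amplitude variation.
* The toy summarizer's "generation" is token selection plus linear
  decoding; ROUGE differences between its variants are meaningful only
  relative to its own baseline.
* The exact Jonckheere-Terpstra enumeration is limited to N <= 12; beyond
  that the ties-corrected normal approximation is used (verified against
  permutation within Monte-Carlo error).
* Persistence is plain text (TSV/CSV/JSONL) only; binary scientific
  container formats are out of scope for this package.
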