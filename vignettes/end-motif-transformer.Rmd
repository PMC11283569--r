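---
title: "Modelling cfDNA end-motif rankings with a masked-token transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cfDNA end-motif rankings with a masked-token transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endmotif)
library(dplyr)
```

## The problem

Plasma cell-free DNA (cfDNA) is fragmented non-randomly: the 4-nucleotide
sequence at each fragment's 5' terminus (its *end-motif*) reflects the
nuclease milieu and chromatin state of the cells that released it, and motifs
such as CCCA, CCAG and CCTG are enriched in subjects with hepatocellular
carcinoma. `endmotif` models the *ranking* of the 256 possible 4-mer
end-motifs within a sample rather than their raw counts. Rankings are cheap
to compute from raw reads (no alignment, copy-number or mutation calling)
and are insensitive to depth and, to a useful degree, to batch effects.

The pipeline is:

1. count the k-mer at the 5' end of each read (`count_end_motifs()`);
2. sort motifs by frequency, descending, and wrap the top `t` in `CLS`/`SEP`
   tokens (`rank_and_tokenize()`), optionally multiplying datapoints by
   ranking disjoint random read blocks (`build_augmented_corpus()`);
3. pretrain a transformer encoder on these token sequences with a
   masked-token objective (`pretrain_transformer()`);
4. freeze the encoder and linearly probe the CLS representation for
   cancer/control status (`linear_probe_cv()`), comparing against a probe on
   the raw count matrix (`count_baseline_probe()`);
5. interpret the model through the CLS attention row
   (`cls_attention_scores()`, `compare_attention_groups()`,
   `build_attention_network()`).

Two classical statistics complete the toolkit: the motif diversity score
(`motif_diversity()`, the normalized Shannon entropy of the motif
distribution) and the kBET batch-effect acceptance rate
(`kbet_acceptance()`).

## The model

A ranked sequence `M = {CLS, m0, ..., mt', SEP, PAD...}` is embedded by
summing token and position embeddings (`X + P`, both `d`-dimensional). Each
encoder block applies multi-head self-attention,

$$\mathrm{SelfAttn}(Q,K,V) = \mathrm{softmax}\!\left(\frac{QK^{\mathsf T}}{\sqrt{d_k}}\right)V,$$

with `h` heads of width `d_k = d/h` concatenated, a residual connection,
and layer normalization before and after the position-wise feed-forward
network

$$\mathrm{FFN}(x) = \max(0,\; xW_1 + b_1)\,W_2 + b_2,$$

also with a residual. A two-layer projection head (layer normalization
between layers) maps the output `Z` — the same shape as `X + P` — onto the
vocabulary of `4^k` motifs plus the four specials. PAD positions are
excluded from attention, so padding never changes the representation of real
positions (a tested invariant).

Pretraining follows the standard masked-token recipe: 15% of motif positions
are selected per sequence; a selected position becomes `MASK` with
probability 0.8, a uniformly random motif with probability 0.1, and stays
itself with probability 0.1. The loss is the cross-entropy of the original
motif at selected positions only, optimized with Adam (decoupled weight
decay 0.01), batch size 256, peak learning rate 1e-4, one epoch of linear
warmup followed by cosine decay to zero. Fit is tracked as the
**exponentiated cross-entropy** (ECE) on a held-out set corrupted once at
the start of the run: ECE is `exp(mean loss)`, 1 for a perfect predictor and
the vocabulary size (260) for an uninformed one.

### Design choices the architecture leaves open

* **Depth.** The encoder defaults to a single block (`num_layers = 1`).
  With `d = 384/768/1536` and `h = 6/12/24` a single block gives roughly
  2M/8M/32M parameters, matching the published model family's sizes under a
  parameters-in-millions reading; depth is configurable.
* **No output projection after head concatenation.** Multi-head attention is
  the plain concatenation of heads, which already restores width `d`; the
  per-head Q/K/V projections are the only attention parameters.
* **Head activation.** The projection head's nonlinearity is ReLU, matching
  the FFN's activation; the reference description does not fix it.
* **Forced selection.** If the Bernoulli(0.15) draw selects no position, one
  motif position is forced uniformly so every sequence contributes a defined
  loss.
* **Weight decay** is decoupled (AdamW-style) and applies to weight matrices
  only, not biases or layer-norm parameters, as in standard BERT training.
* **ECE scope.** The objective maximizes the likelihood of masked motifs
  only, so ECE is computed over selected positions only.
* **Holdout corruption** is drawn once per run, making the per-epoch ECE
  curve a paired comparison across epochs rather than a re-randomized one.

## Ranking construction

Ties in motif frequency are broken lexicographically (A < C < G < T) so
tokenization is deterministic. Reads whose first `k` bases contain any
non-ACGT character are skipped, not mapped to an ambiguity token: the
dictionary has exactly `4^k` motifs. Corpus augmentation shuffles a sample's
reads once (seeded), partitions them into disjoint blocks — sampling without
replacement — and ranks each block separately; the incomplete trailing block
is dropped. Probing, by contrast, uses **one sequence per sample** built
from all of that sample's reads, because labels are per-sample; augmented
blocks exist to enlarge the pretraining corpus only.

For aligned input two counting modes exist because strand handling is
genuinely ambiguous for raw reads: `raw-read` (default) counts the prefix of
the sequence as stored, while `alignment-oriented` reverse-complements
minus-strand alignments so the motif is always the fragment's 5' terminus.
On forward-strand-only data the two agree (tested). Only first mates are
counted by default; the second mate's 5' end is the fragment's other
terminus.

## Evaluation stack

The linear probe is a ridge-penalized logistic regression on standardized
frozen features under stratified 5-fold cross-validation, with the penalty
**fixed** (`lambda = 0.01`) rather than tuned — tuning would turn a linear
projection into model selection. Pooled out-of-fold probabilities feed:

* AUROC with a 95% CI from DeLong's structural-components estimator
  (implemented in-package; cross-checked in the test suite against both
  exhaustive pair counting and pROC);
* a paired DeLong z-test comparing two scorers on the same samples (e.g.
  representation probe vs. count baseline — sharing the probe seed shares
  the fold partition, which keeps the comparison paired);
* accuracy, sensitivity and specificity at a 0.5 threshold with exact
  Clopper–Pearson 95% intervals (`stats::binom.test`).

Attention interpretation reads the CLS row of the last layer's attention
matrices, keyed by motif identity. Group comparisons use the Wilcoxon
rank-sum test by default — a t-test is available, as both appear in common
practice — with Benjamini–Hochberg adjustment across motifs within each head
(heads are reported separately; a global family is available behind a flag).
Attention networks accumulate `alpha[i, j]` over a group's sequences, summed
over heads, exclude special tokens and self-loops, and keep the top
`ceiling(retention * candidate pairs)` edges (default retention 0.1%) with a
deterministic tie-break.

kBET uses Euclidean K-nearest neighbours (K = 5, alpha = 0.05 by default),
self excluded, distance ties broken by sample index. It is
representation-agnostic: pass frequencies, rankings, or learned features.

## The synthetic cohort generator

Real cfDNA cohorts in this area are controlled-access, so the package ships
a generator that emulates the statistical structure the pipeline consumes: a
Dirichlet-multinomial over the 256 motifs. Each sample draws motif
probabilities from a symmetric Dirichlet (concentration 50 per motif; the
default gives a between-sample coefficient of variation of roughly 14% per
motif frequency, enough to scramble rankings without drowning a real shift);
cancer samples multiply the concentration of the signal motifs
(CCCA/CCAG/CCTG by default) by `1 + effect_size`. `effect_size = 0` is an
exact null. Batch effects tilt a disjoint motif set (TTTG/TTGT/TGTT) the
same way. `write_fastq()` expands profiles to reads whose 5' prefix is the
assigned motif, making the generator an exact oracle for the extraction
stage.

What the generator does **not** emulate: genome-positional fragmentation,
fragment-size profiles, sequencing error in the first k bases, GC bias, or
methylation-dependent end preferences. Passing tests therefore show that the
pipeline recovers plantable ranking signal, not that any particular clinical
AUROC is attainable on real cohorts.

## Desk-scale study conditions

Everything in the test suite runs on one CPU core. The sizes used, chosen as
the smallest at which each claim is meaningful:

* **Training trend:** 2,000 sequences of 32 ranked motifs, 5 epochs, hidden
  sizes 64 vs 128 over 5 seeds; holdout ECE must fall across epochs and the
  wider model must fit better on average. At this scale a peak learning rate
  of 1e-3 replaces the published 1e-4 — with only ~35 optimizer steps the
  published rate would leave the schedule in its warmup regime.
* **Signal recovery:** cohorts of 100 + 100 samples at 50,000 reads each;
  the CLS-representation probe must reach AUROC ≥ 0.9 at `effect_size = 5`
  and stay in [0.4, 0.6] at 0.
* **Masking statistics:** 128,000 motif positions; corruption fraction
  within ±0.5 pp of 15%, MASK share within ±1 pp of 80%. The observed
  "random" share is counted by recorded action because 1/256 of uniform
  redraws coincide with the original token.
* **kBET:** n = 200, two batches, 20 null replicates (> 80% acceptance)
  versus one confounded design (< 5%).

## Numerical notes and limitations

* Layer normalization uses population variance with eps = 1e-5; softmax rows
  subtract the row maximum; fully-masked rows (all keys PAD) return zeros.
* All randomness flows from a single run seed through derived streams;
  results are bit-reproducible on a single thread. BLAS threading can
  perturb the last bits of sums; determinism tests pin one thread.
* Gradients are computed analytically and verified against central finite
  differences to a relative tolerance of 1e-3 in the test suite.
* The probe's fixed ridge penalty (`lambda = 0.01`) is a documented choice,
  not an optimum; it exists to stabilize separable folds, and tuning it is
  deliberately out of scope for a probe.
* `compute_ece()` is exp of an *average* loss: it is comparable across
  models only at a fixed masking scheme and vocabulary.
* Exact Clopper–Pearson bounds are used throughout; note that for x = n the
  lower bound is `(alpha/2)^(1/n)`, e.g. 0.832 for 20/20 — published
  intervals computed by other software occasionally differ in this corner.
* Training is pure R linear algebra: fine at desk scale (tens of seconds per
  run above), not intended for hundreds of thousands of sequences.
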