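# endmotif

Self-supervised transformer modelling of cfDNA 5'-end motif rankings, with a
complete evaluation stack for liquid-biopsy cancer classification.

## What problem this solves

Cell-free DNA (cfDNA) in plasma is cut by nucleases in a cell-type-dependent
way, so the 4-nucleotide motif at each fragment's 5' end carries a signature
of the tissues releasing DNA — including tumors. `endmotif` is for
computational biologists who want to exploit that signal without alignment,
copy-number or mutation calling: it works directly on the *ranking* of the
256 possible 4-mer end-motifs in each sample.

The core model is a transformer encoder trained with a masked-token
(BERT-style) objective on ranked motif sequences
`M = {CLS, m0, m1, ..., mt, SEP}` sorted by descending frequency. Attention
is the standard scaled dot-product over `h` heads of width `d_k = d/h`,

```
SelfAttn(Q, K, V) = softmax(Q Kᵀ / √d_k) V
FFN(x) = max(0, x W₁ + b₁) W₂ + b₂
```

with residual connections and layer normalization around the position-wise
FFN, and a two-layer projection head onto the motif vocabulary. During
pretraining, 15% of motif positions are corrupted (80% `MASK` / 10% random
motif / 10% unchanged) and the model learns to restore them; fit is tracked
as the exponentiated cross-entropy (ECE) on a holdout (1 = perfect, 260 =
uninformed). After pretraining, the frozen CLS representation is probed with
a cross-validated ridge-logistic classifier, with DeLong confidence
intervals and tests for AUROCs and exact Clopper–Pearson intervals for
accuracy/sensitivity/specificity. CLS-attention scores, attention networks,
the motif diversity score (normalized Shannon entropy) and the kBET
batch-effect acceptance rate round out the analysis. A Dirichlet-multinomial
cohort simulator makes the whole pipeline testable without controlled-access
data.

## Worked example

```r
library(endmotif)

# a synthetic cohort: 50 cancer vs 50 control samples, 50k reads each,
# cancer-enriched CCCA/CCAG/CCTG
cohort <- simulate_cohort(n_cancer = 50, n_control = 50,
                          reads_per_sample = 50000, effect_size = 5, seed = 1)

# pretraining corpus of ranked sequences (32 motif slots)
corpus <- simulate_corpus(1000, t = 32, seed = 2, n_cancer = 10,
                          n_control = 10, reads_per_sample = 50000,
                          effect_size = 5)
cfg <- transformer_config(hidden_size = 64, num_heads = 2, num_layers = 1,
                          ffn_dim = 256, vocab_size = 260)
run <- pretrain_transformer(corpus, cfg, epochs = 5, batch_size = 128,
                            peak_lr = 1e-3, seed = 3)
glance(run)
#> # A tibble: 1 × 6
#>   epochs initial_ece final_ece final_train_loss holdout_n  seed
#>    <int>       <dbl>     <dbl>            <dbl>     <int> <dbl>
#> 1      5        263.      242.             5.47       100     3

# probe the frozen CLS representations
seqs <- lapply(cohort$profiles, rank_and_tokenize, t = 32)
reps <- extract_representations(run$model, seqs)
probe <- linear_probe_cv(reps, cohort$labels, folds = 5, seed = 4)
tidy(probe)
#> # A tibble: 4 × 6
#>   metric      estimate conf.low conf.high successes trials
#>   <chr>          <dbl>    <dbl>     <dbl>     <int>  <int>
#> 1 auroc          0.841    0.765     0.916        NA     NA
#> 2 accuracy       0.74     0.643     0.823        74    100
#> 3 sensitivity    0.72     0.575     0.838        36     50
#> 4 specificity    0.76     0.618     0.869        38     50
```

The holdout ECE falling from 263 (≈ the uninformed limit of 260) to 242 in
five epochs shows the model learning ranking structure; the probe AUROC of
0.841 (95% CI 0.765–0.916) says the cancer/control distinction is linearly
decodable from the learned CLS representation after a short desk-scale
pretraining run. The count-matrix baseline uses the same folds when given
the same seed, so the two probes can be compared sample by sample:

```r
base <- count_baseline_probe(cohort$profiles, cohort$labels, seed = 4)
delong_paired_test(probe$predictions$prob, base$predictions$prob,
                   cohort$labels)$p.value
#> [1] 3.4204e-05
```

On this synthetic cohort the raw-count baseline is actually perfect (AUROC
1.0): the generator plants the signal directly in three motif frequencies,
which a linear model on 256 frequencies reads off trivially, while the
ranking compresses it. Planted-frequency signal is exactly the regime where
counts shine; the representation probe's value on real data lies in
robustness properties (depth- and batch-insensitivity of rankings) that
this simple generator does not reward.

Other one-liners:

```r
motif_diversity(cohort$profiles[[1]])          # normalized entropy in [0, 1]
kbet_acceptance(reps, rep(c("b1", "b2"), 50))  # batch-mixing acceptance %
scores <- cls_attention_scores(run$model, seqs)
compare_attention_groups(scores)               # per-motif group tests + BH
```

A command-line wrapper over the same functions ships at
`inst/cli/endmotif.R` (subcommands: `simulate`, `extract`, `build-corpus`,
`pretrain`, `probe`, `attention`, `mds`, `kbet`).

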