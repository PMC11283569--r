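# Shared fixtures, built in code at test time.

dict4 <- motif_dictionary(4)
dict2 <- motif_dictionary(2)

tiny_config <- function(d = 16, h = 2, L = 1, vocab = 260, maxpos = 258) {
  transformer_config(hidden_size = d, num_heads = h, num_layers = L,
                     ffn_dim = 2 * d, vocab_size = vocab,
                     max_positions = maxpos, dropout_rate = 0.1)
}

tiny_model <- function(seed = 1, ...) {
  init_transformer(tiny_config(...), dict4, seed = seed)
}

# Random ranked sequence over the k=4 dictionary with t distinct motifs.
random_sequence <- function(t = 16, seed = 1, pad_to = t) {
  motifs <- withr::with_seed(seed, sample(dict4$motifs, t))
  tokens <- c("CLS", motifs, "SEP", rep("PAD", pad_to - t))
  structure(list(tokens = tokens,
                 attention_mask = as.integer(tokens != "PAD"),
                 t = pad_to, sample_id = paste0("rs", seed), label = NULL,
                 k = 4L),
            class = "end_motif_sequence")
}

# Small labeled cohort of ranked sequences + a lightly trained model, cached
# across test files because pretraining is the slow step.
trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- simulate_cohort(n_cancer = 15, n_control = 15,
                              reads_per_sample = 8000, effect_size = 5,
                              seed = 101)
    corpus <- simulate_corpus(300, t = 16, seed = 102, n_cancer = 6,
                              n_control = 6, reads_per_sample = 8000,
                              effect_size = 5)
    cfg <- tiny_config(d = 32, h = 2)
    run <- pretrain_transformer(corpus, cfg, epochs = 2, batch_size = 64,
                                peak_lr = 1e-3, seed = 103)
    seqs <- lapply(cohort$profiles, rank_and_tokenize, t = 16)
    for (i in seq_along(seqs)) seqs[[i]]$label <- cohort$labels[i]
    cache <<- list(cohort = cohort, corpus = corpus, run = run,
                   model = run$model, sequences = seqs)
    cache
  }
})
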