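#' Simulate a cohort of end-motif profiles with a cancer signal
#'
#' Dirichlet-multinomial generator for per-sample end-motif usage: every
#' sample draws a motif probability vector from a symmetric Dirichlet with
#' concentration `concentration` per motif; in the cancer group the
#' concentration of the `signal_motifs` is multiplied by `1 + effect_size`,
#' shifting those motifs up the ranking (the classic cancer-enriched 5'-end
#' motifs CCCA/CCAG/CCTG are the default signal set). Counts are then drawn
#' multinomially with `reads_per_sample` trials. `effect_size = 0` makes both
#' groups exchangeable — the null cohort. An optional batch effect tilts a
#' disjoint motif set per batch the same way.
#'
#' @param n_cancer,n_control Group sizes.
#' @param reads_per_sample Multinomial trials (reads) per sample.
#' @param signal_motifs Motifs enriched in the cancer group.
#' @param effect_size Non-negative multiplier; signal-motif concentration is
#'   scaled by `1 + effect_size` in cancer samples.
#' @param concentration Symmetric Dirichlet concentration per motif
#'   (default 50; larger = less between-sample variability).
#' @param k Motif length (default 4).
#' @param batches Optional batch label per sample (length
#'   `n_cancer + n_control`).
#' @param batch_motifs Motifs tilted by batch (default TTTG/TTGT/TGTT,
#'   disjoint from the signal set).
#' @param batch_effect_size Per-batch multiplier step: batch `b` scales
#'   `batch_motifs` concentration by `1 + (b - 1) * batch_effect_size`.
#' @param seed Integer seed; the whole cohort is reproducible.
#'
#' @return List with `profiles` (list of [motif_profile()]), `labels`
#'   (character, `"cancer"`/`"control"`), `batches`, and `truth` (tibble of
#'   per-sample generating probabilities for the signal motifs).
#' @export
simulate_cohort <- function(n_cancer = 100, n_control = 100,
                            reads_per_sample = 50000,
                            signal_motifs = c("CCCA", "CCAG", "CCTG"),
                            effect_size = 5, concentration = 50, k = 4,
                            batches = NULL,
                            batch_motifs = c("TTTG", "TTGT", "TGTT"),
                            batch_effect_size = 0, seed = 1L) {
  n_cancer <- check_positive_int(n_cancer, "n_cancer")
  n_control <- check_positive_int(n_control, "n_control")
  reads_per_sample <- check_positive_int(reads_per_sample, "reads_per_sample")
  if (effect_size < 0) {
    abort("`effect_size` must be non-negative.",
          class = "endmotif_error_configuration")
  }
  if (concentration <= 0) {
    abort("`concentration` must be positive.",
          class = "endmotif_error_configuration")
  }
  dict <- motif_dictionary(k)
  if (!all(signal_motifs %in% dict$motifs)) {
    abort("`signal_motifs` must be valid k-mers.",
          class = "endmotif_error_configuration")
  }
  n <- n_cancer + n_control
  labels <- rep(c("cancer", "control"), c(n_cancer, n_control))
  if (!is.null(batches) && length(batches) != n) {
    abort("`batches` must have one label per sample.",
          class = "endmotif_error_configuration")
  }
  batch_idx <- if (is.null(batches)) rep(1L, n) else as.integer(factor(batches))
  sig <- match(signal_motifs, dict$motifs)
  bat <- match(batch_motifs, dict$motifs)
  with_seed(seed, {
    profiles <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      alpha <- rep(concentration, length(dict$motifs))
      if (labels[i] == "cancer") alpha[sig] <- alpha[sig] * (1 + effect_size)
      if (batch_effect_size > 0) {
        alpha[bat] <- alpha[bat] * (1 + (batch_idx[i] - 1L) * batch_effect_size)
      }
      g <- rgamma(length(alpha), shape = alpha)
      p <- g / sum(g)
      counts <- as.integer(rmultinom(1L, reads_per_sample, p))
      sid <- sprintf("%s_%03d", labels[i], i)
      profiles[[i]] <- motif_profile(setNames(counts, dict$motifs), dict,
                                     sample_id = sid)
      attr(profiles[[i]], "label") <- labels[i]
      truth[[i]] <- tibble(sample_id = sid, label = labels[i],
                           motif = signal_motifs, prob = p[sig])
    }
    list(profiles = profiles, labels = labels,
         batches = if (is.null(batches)) NULL else batches,
         truth = dplyr::bind_rows(truth))
  })
}

#' Write simulated profiles as FASTQ files
#'
#' Expands each profile's motif counts into reads whose first `k` bases are
#' the assigned motif and whose remaining bases are uniform random A/C/G/T;
#' quality strings are constant. Counting 5'-end motifs on the output exactly
#' reproduces the input counts, which makes the generator the oracle for the
#' extraction stage.
#'
#' @param profiles List of [motif_profile()].
#' @param dir Output directory (one `<sample_id>.fastq` per profile).
#' @param read_length Read length (must be at least `k`).
#' @param seed Seed for the random read tails.
#' @return Character vector of the files written.
#' @export
write_fastq <- function(profiles, dir, read_length = 50, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- attr(profiles[[1L]], "k")
  if (read_length < k) {
    abort("`read_length` must be at least the motif length.",
          class = "endmotif_error_configuration")
  }
  tail_len <- read_length - k
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    vapply(profiles, function(p) {
      sid <- attr(p, "sample_id")
      motifs <- rep(p$motif, p$count)
      n_reads <- length(motifs)
      tails <- if (tail_len > 0) {
        vapply(seq_len(n_reads), function(i) {
          paste(sample(bases, tail_len, replace = TRUE), collapse = "")
        }, "")
      } else rep("", n_reads)
      seqs <- Biostrings::DNAStringSet(paste0(motifs, tails))
      names(seqs) <- sprintf("%s_read%06d", sid, seq_len(n_reads))
      path <- file.path(dir, paste0(sid, ".fastq"))
      Biostrings::writeXStringSet(
        seqs, path, format = "fastq",
        qualities = Biostrings::BStringSet(rep(strrep("I", read_length), n_reads)))
      path
    }, "")
  })
}

#' Simulate a pretraining corpus of ranked sequences
#'
#' Draws a cohort with [simulate_cohort()] and converts each sample's reads
#' into several ranked sequences via disjoint random blocks
#' ([build_augmented_corpus()]), yielding a labeled corpus of about
#' `n_sequences` sequences (balanced across the two groups) for desk-scale
#' pretraining.
#'
#' @param n_sequences Target corpus size.
#' @param t Motif slots per sequence.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cohort()] (group sizes, effect size, ...).
#' @return List of labeled `end_motif_sequence`, length `<= n_sequences`.
#' @export
simulate_corpus <- function(n_sequences = 2000, t = 32, seed = 1L, ...) {
  n_sequences <- check_positive_int(n_sequences, "n_sequences")
  cohort <- simulate_cohort(seed = seed, ...)
  n_samples <- length(cohort$profiles)
  per_sample <- ceiling(n_sequences / n_samples)
  dict <- motif_dictionary(attr(cohort$profiles[[1L]], "k"))
  seeds <- derive_seeds(seed + 1L, n_samples)
  corpus <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    p <- cohort$profiles[[i]]
    block <- max(attr(p, "total_reads_used") %/% per_sample, 4L * t)
    corpus[[i]] <- build_augmented_corpus(
      p, dict, reads_per_block = block, t = t, seed = seeds[i],
      sample_id = attr(p, "sample_id"), label = cohort$labels[i])
  }
  # round-robin across samples before truncating, so labels stay balanced
  block_rank <- unlist(lapply(lengths(corpus), seq_len))
  corpus <- unlist(corpus, recursive = FALSE)[order(block_rank)]
  corpus[seq_len(min(length(corpus), n_sequences))]
}
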