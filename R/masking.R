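#' Corrupt a ranked motif sequence for masked-token pretraining
#'
#' The BERT-style corruption scheme that drives self-supervised pretraining:
#' each motif position (never CLS/SEP/PAD) is independently selected with
#' probability `select_prob` (default 15%); a selected position is replaced by
#' the `MASK` token with probability 80%, by a uniformly drawn random motif
#' with probability 10%, and left unchanged with probability 10%. If no
#' position is selected, one motif position chosen uniformly is forced so
#' every sequence yields a defined loss. Targets record the original token
#' only at selected positions.
#'
#' @param sequence An `end_motif_sequence`, or a character vector of tokens.
#' @param dictionary A [motif_dictionary()].
#' @param seed Integer seed (the corruption is fully reproducible).
#' @param select_prob Per-position selection probability (default 0.15).
#' @param mask_frac,random_frac Conditional shares of MASK / random-motif
#'   replacement among selected positions (defaults 0.8 / 0.1; the remainder
#'   is kept unchanged).
#'
#' @return List with `tokens` (corrupted), `target_tokens` (original tokens
#'   at selected positions, `NA` elsewhere), and `selected` (logical).
#' @export
mask_tokens <- function(sequence, dictionary, seed,
                        select_prob = 0.15, mask_frac = 0.8, random_frac = 0.1) {
  tokens <- if (inherits(sequence, "end_motif_sequence")) sequence$tokens else sequence
  with_seed(seed, mask_tokens_impl(tokens, dictionary, select_prob,
                                   mask_frac, random_frac))
}

# Uses the current RNG stream; the training loop calls this directly so all
# corruption flows from the single run seed.
mask_tokens_impl <- function(tokens, dictionary, select_prob = 0.15,
                             mask_frac = 0.8, random_frac = 0.1) {
  motif_pos <- which(!tokens %in% dictionary$special_tokens)
  if (length(motif_pos) == 0L) {
    abort("Sequence contains no motif tokens to corrupt.",
          class = "endmotif_error_degenerate")
  }
  sel <- motif_pos[runif(length(motif_pos)) < select_prob]
  if (length(sel) == 0L) {
    sel <- motif_pos[sample.int(length(motif_pos), 1L)]
  }
  u <- runif(length(sel))
  action <- ifelse(u < mask_frac, "mask",
                   ifelse(u < mask_frac + random_frac, "random", "keep"))
  corrupted <- tokens
  corrupted[sel[action == "mask"]] <- "MASK"
  n_rand <- sum(action == "random")
  if (n_rand > 0) {
    corrupted[sel[action == "random"]] <-
      dictionary$motifs[sample.int(length(dictionary$motifs), n_rand, replace = TRUE)]
  }
  target <- rep(NA_character_, length(tokens))
  target[sel] <- tokens[sel]
  selected <- logical(length(tokens))
  selected[sel] <- TRUE
  list(tokens = corrupted, target_tokens = target, selected = selected,
       action = setNames(action, sel))
}

#' Exponentiated cross-entropy of masked-token predictions
#'
#' `ECE = exp(mean cross-entropy)` over masked positions: the perplexity-style
#' fit metric for the masked-token objective. A perfect predictor scores 1;
#' a uniform predictor scores the vocabulary size.
#'
#' @param logits Matrix of unnormalized vocabulary scores, one row per masked
#'   position.
#' @param targets Integer vector of true token ids (1-based column indices
#'   into `logits`).
#' @return ECE, a real number ≥ 1 in expectation (exactly ≥ the exponential
#'   of the minimal achievable cross-entropy).
#' @examples
#' compute_ece(matrix(0, 2, 260), c(1L, 5L))  # uniform: 260
#' @export
compute_ece <- function(logits, targets) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (nrow(logits) == 0L || length(targets) == 0L) {
    abort("ECE is undefined with zero masked targets.",
          class = "endmotif_error_degenerate")
  }
  if (length(targets) != nrow(logits)) {
    abort("One target id per logit row is required.",
          class = "endmotif_error_shape")
  }
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  ce <- lse - logits[cbind(seq_len(nrow(logits)), targets)]
  exp(mean(ce))
}
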