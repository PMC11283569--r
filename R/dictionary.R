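#' Build the end-motif vocabulary
#'
#' Enumerates all `4^k` k-nucleotide end-motifs over the alphabet A/C/G/T in
#' lexicographic order (A < C < G < T) and appends the four special tokens
#' `CLS`, `SEP`, `MASK`, `PAD` used by the ranked-sequence model. Token ids are
#' contiguous integers starting at 0, so serialized ids are stable across
#' sessions.
#'
#' @param k Motif length in nucleotides (1 to 8). The field standard for cfDNA
#'   5'-end motifs is `k = 4`, giving 256 motifs and a vocabulary of 260.
#'
#' @return A `motif_dictionary`: list with `k`, `motifs` (character, length
#'   `4^k`), `special_tokens` (`CLS`, `SEP`, `MASK`, `PAD`), and `token_to_id`
#'   (named integer vector over motifs then specials, ids from 0).
#'
#' @examples
#' d <- motif_dictionary(4)
#' length(d$motifs)     # 256
#' d$token_to_id["CLS"] # 256
#' @export
motif_dictionary <- function(k = 4) {
  k <- check_positive_int(k, "k")
  if (k > 8) {
    abort("`k` must be between 1 and 8.", class = "endmotif_error_parameter")
  }
  bases <- c("A", "C", "G", "T")
  # expand.grid with the last base varying slowest gives lexicographic order
  grid <- do.call(expand.grid, c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE))
  motifs <- do.call(paste0, rev(grid))
  motifs <- sort(motifs, method = "radix")
  special <- c("CLS", "SEP", "MASK", "PAD")
  ids <- seq_along(c(motifs, special)) - 1L
  names(ids) <- c(motifs, special)
  structure(
    list(k = k, motifs = motifs, special_tokens = special, token_to_id = ids),
    class = "motif_dictionary"
  )
}

#' @export
print.motif_dictionary <- function(x, ...) {
  cat(sprintf("<motif_dictionary> k = %d: %d motifs + %d special tokens (%s)\n",
              x$k, length(x$motifs), length(x$special_tokens),
              paste(x$special_tokens, collapse = ", ")))
  invisible(x)
}

dict_vocab_size <- function(dictionary) {
  length(dictionary$motifs) + length(dictionary$special_tokens)
}

# 1-based ids for internal matrix indexing
token_index <- function(dictionary, tokens) {
  idx <- dictionary$token_to_id[tokens] + 1L
  if (anyNA(idx)) {
    bad <- tokens[is.na(idx)]
    abort(sprintf("Unknown token(s): %s", paste(unique(bad), collapse = ", ")),
          class = "endmotif_error_token")
  }
  unname(idx)
}
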