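#' Rank a motif profile into a token sequence
#'
#' Sorts end-motifs by frequency in descending order and wraps the top `t` in
#' `CLS`/`SEP` delimiters, producing the ranked token sequence
#' `{CLS, m0, m1, ..., SEP, PAD...}` the transformer consumes. Ties in
#' frequency are broken lexicographically so tokenization is deterministic.
#' If fewer than `t` motifs have nonzero count, all nonzero motifs are used
#' and the tail after `SEP` is `PAD`; the sequence is always padded to the
#' fixed length `t + 2`.
#'
#' @param profile A [motif_profile()] with at least one counted read.
#' @param t Number of motif slots; must satisfy `t < 4^k`. The model default
#'   is 128 ranked motifs per sequence.
#'
#' @return An `end_motif_sequence`: list with `tokens` (character, length
#'   `t + 2`), `attention_mask` (1 for non-PAD positions), `t`, `sample_id`,
#'   `label` (optional), `k`.
#' @examples
#' d <- motif_dictionary(2)
#' p <- motif_profile(c(AA = 5, CC = 3, GG = 1), d)
#' rank_and_tokenize(p, t = 3)$tokens
#' @export
rank_and_tokenize <- function(profile, t = 128) {
  t <- check_positive_int(t, "t")
  k <- attr(profile, "k")
  if (t >= 4^k) {
    abort(sprintf("`t` must be < 4^k = %d.", 4^k),
          class = "endmotif_error_parameter")
  }
  total <- attr(profile, "total_reads_used")
  if (is.null(total) || total == 0) {
    abort("Cannot tokenize an empty profile.",
          class = "endmotif_error_empty_profile")
  }
  nz <- profile[profile$count > 0, ]
  # descending count; profile rows are already lexicographic, and order() is
  # stable, so ties fall back to lexicographic motif order
  ord <- order(-nz$count)
  motifs <- nz$motif[ord][seq_len(min(t, nrow(nz)))]
  tokens <- c("CLS", motifs, "SEP")
  n_pad <- (t + 2L) - length(tokens)
  tokens <- c(tokens, rep("PAD", n_pad))
  structure(
    list(tokens = tokens,
         attention_mask = as.integer(tokens != "PAD"),
         t = t,
         sample_id = attr(profile, "sample_id"),
         label = attr(profile, "label"),
         k = k),
    class = "end_motif_sequence"
  )
}

#' @export
print.end_motif_sequence <- function(x, ...) {
  shown <- paste(head(x$tokens, 8), collapse = " ")
  cat(sprintf("<end_motif_sequence> sample '%s', t = %d: %s%s\n",
              x$sample_id, x$t, shown,
              if (length(x$tokens) > 8) " ..." else ""))
  invisible(x)
}

#' Build an augmented corpus of ranked sequences from one sample's reads
#'
#' To multiply training datapoints per sample, per-read motifs are shuffled
#' (seeded) and partitioned into disjoint blocks of `reads_per_block` reads;
#' each block is counted and ranked into one token sequence. The incomplete
#' trailing block is dropped, so blocks are sampled without replacement and
#' their counts sum to the whole-sample counts minus the dropped remainder.
#'
#' @param reads Character vector of per-read motifs (each a k-mer), or a
#'   [motif_profile()] whose counts are expanded into a read multiset.
#' @param dictionary A [motif_dictionary()].
#' @param reads_per_block Reads per block; should be at least `t`.
#' @param t Motif slots per sequence.
#' @param seed Integer seed for the shuffle.
#' @param sample_id,label Propagated to each sequence.
#'
#' @return List of `end_motif_sequence` (possibly empty, with a warning, if
#'   there are fewer reads than one block).
#' @export
build_augmented_corpus <- function(reads, dictionary, reads_per_block, t = 128,
                                   seed = 1L, sample_id = NULL, label = NULL) {
  reads_per_block <- check_positive_int(reads_per_block, "reads_per_block")
  if (inherits(reads, "motif_profile")) {
    if (is.null(sample_id)) sample_id <- attr(reads, "sample_id")
    reads <- rep(reads$motif, reads$count)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  n_blocks <- length(reads) %/% reads_per_block
  if (n_blocks == 0L) {
    warn("Fewer reads than one block; returning an empty corpus.")
    return(list())
  }
  shuffled <- with_seed(seed, sample(reads))
  lapply(seq_len(n_blocks), function(b) {
    block <- shuffled[((b - 1L) * reads_per_block + 1L):(b * reads_per_block)]
    prof <- motif_profile(table_to_counts(block, dictionary), dictionary,
                          sample_id = sprintf("%s#%d", sample_id, b))
    s <- rank_and_tokenize(prof, t = t)
    s$label <- label
    s
  })
}

table_to_counts <- function(motifs, dictionary) {
  tab <- table(factor(motifs, levels = dictionary$motifs))
  setNames(as.integer(tab), names(tab))
}

#' Serialize / load a sequence corpus
#'
#' One sequence per line, whitespace-separated tokens (gzip transparent when
#' `path` ends in `.gz`), with an optional sidecar label table
#' (`sample_id`, `label`, tab-delimited).
#'
#' @param corpus List of `end_motif_sequence`.
#' @param path Corpus file path.
#' @param labels_path Optional path for the sidecar label table.
#' @return `write_corpus` returns `path` invisibly.
#' @export
write_corpus <- function(corpus, path, labels_path = NULL) {
  lines <- vapply(corpus, function(s) paste(s$tokens, collapse = " "), "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  if (!is.null(labels_path)) {
    lab <- tibble(
      sample_id = vapply(corpus, function(s) s$sample_id, ""),
      label = vapply(corpus, function(s) {
        if (is.null(s$label)) NA_character_ else as.character(s$label)
      }, "")
    )
    write.table(as.data.frame(lab), labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, labels_path = NULL) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read.delim(labels_path, sep = "\t", colClasses = "character")
  }
  lapply(seq_along(lines), function(i) {
    tokens <- strsplit(lines[[i]], "\\s+")[[1]]
    t <- length(tokens) - 2L
    k <- nchar(tokens[2L])
    sid <- if (!is.null(labels)) labels$sample_id[i] else sprintf("seq%d", i)
    lab <- if (!is.null(labels) && !is.na(labels$label[i])) labels$label[i] else NULL
    structure(
      list(tokens = tokens,
           attention_mask = as.integer(tokens != "PAD"),
           t = t, sample_id = sid, label = lab, k = k),
      class = "end_motif_sequence"
    )
  })
}
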