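#' Construct a per-sample end-motif count profile
#'
#' A `motif_profile` is a tibble with one row per dictionary motif (columns
#' `motif`, `count`), in the dictionary's lexicographic order, carrying the
#' sample id and read bookkeeping as attributes. It is the tabular unit that
#' flows between extraction, ranking, diversity and simulation.
#'
#' @param counts Named integer vector or tibble/data.frame with columns
#'   `motif` and `count`; motifs must belong to the dictionary. Motifs absent
#'   from `counts` get count 0.
#' @param dictionary A [motif_dictionary()].
#' @param sample_id Sample identifier string.
#' @param skipped_reads Number of reads excluded (too short or non-ACGT start).
#'
#' @return A tibble of class `motif_profile` with attributes `sample_id`, `k`,
#'   `total_reads_used`, `skipped_reads`.
#' @export
motif_profile <- function(counts, dictionary, sample_id = "sample",
                          skipped_reads = 0L) {
  if (is.data.frame(counts)) {
    counts <- setNames(as.integer(counts$count), counts$motif)
  }
  if (is.null(names(counts)) && length(counts) == length(dictionary$motifs)) {
    names(counts) <- dictionary$motifs
  }
  bad <- setdiff(names(counts), dictionary$motifs)
  if (length(bad) > 0) {
    abort(sprintf("Counts contain motifs outside the dictionary: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "endmotif_error_motif")
  }
  if (any(counts < 0)) {
    abort("Counts must be non-negative.", class = "endmotif_error_parameter")
  }
  full <- setNames(integer(length(dictionary$motifs)), dictionary$motifs)
  full[names(counts)] <- as.integer(counts)
  out <- tibble(motif = dictionary$motifs, count = unname(full))
  structure(out,
            class = c("motif_profile", class(out)),
            sample_id = as.character(sample_id),
            k = dictionary$k,
            total_reads_used = sum(full),
            skipped_reads = as.integer(skipped_reads))
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> sample '%s' (k = %d): %d reads used, %d skipped, %d motifs with nonzero count\n",
              attr(x, "sample_id"), attr(x, "k"),
              attr(x, "total_reads_used"), attr(x, "skipped_reads"),
              sum(x$count > 0)))
  NextMethod()
}

#' Convert a count profile to a frequency vector
#'
#' Returns per-motif relative frequencies in dictionary (lexicographic) order;
#' these are the \eqn{P_i} that feed the motif diversity score. Frequencies sum
#' to 1 within numerical tolerance; motifs with zero count have frequency 0.
#'
#' @param profile A [motif_profile()].
#' @return Named numeric vector of length `4^k` summing to 1.
#' @export
profile_frequencies <- function(profile) {
  total <- attr(profile, "total_reads_used")
  if (is.null(total) || total == 0) {
    abort("Profile has no usable reads; frequencies are undefined.",
          class = "endmotif_error_empty_profile")
  }
  setNames(profile$count / total, profile$motif)
}

#' Write / read a motif count table
#'
#' Tab-delimited, two columns `motif` and `count`, one header line, motifs in
#' lexicographic order. Round-trips counts exactly.
#'
#' @param profile A [motif_profile()].
#' @param path Output file path.
#' @return `write_motif_counts` returns `path` invisibly; `read_motif_counts`
#'   returns a [motif_profile()].
#' @export
write_motif_counts <- function(profile, path) {
  write.table(as.data.frame(profile[, c("motif", "count")]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_counts
#' @param dictionary Dictionary used to validate motifs; defaults to one
#'   inferred from the motif length in the file.
#' @param sample_id Sample id to attach (defaults to the file name).
#' @export
read_motif_counts <- function(path, dictionary = NULL, sample_id = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer"))
  if (!all(c("motif", "count") %in% names(tab))) {
    abort("Count table must have columns `motif` and `count`.",
          class = "endmotif_error_format")
  }
  if (is.null(dictionary)) dictionary <- motif_dictionary(nchar(tab$motif[1]))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  }
  motif_profile(setNames(tab$count, tab$motif), dictionary,
                sample_id = sample_id)
}
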