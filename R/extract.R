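#' Count 5'-end k-mer motifs from sequencing reads
#'
#' Tallies the k-nucleotide motif at the 5' terminus of each read into a
#' per-sample count profile. Input may be a FASTQ/FASTA file (gzip
#' transparent), a SAM/BAM file, a `Biostrings::DNAStringSet`, or a plain
#' character vector of read sequences.
#'
#' Two counting modes are provided because strand handling differs between raw
#' and aligned data:
#' \describe{
#'   \item{`"raw-read"` (default)}{the first `k` bases of the read as
#'     sequenced are the motif. For BAM/SAM input the stored sequence is used
#'     as-is.}
#'   \item{`"alignment-oriented"`}{requires SAM/BAM input; reads mapped to the
#'     reverse strand are reverse-complemented first, so the motif always
#'     reflects the fragment's 5' terminus in fragment orientation.}
#' }
#'
#' Reads shorter than `k`, or whose first `k` bases contain any non-ACGT
#' character (e.g. `N`), are skipped and tallied in the profile's
#' `skipped_reads` attribute: the dictionary has exactly `4^k` motifs and no
#' ambiguity token. For paired-end alignments only the first mate is counted
#' by default (it carries the fragment's sequenced 5' end); set
#' `both_mates = TRUE` to count both.
#'
#' @param reads File path, `DNAStringSet`, or character vector of reads.
#' @param dictionary A [motif_dictionary()].
#' @param mode `"raw-read"` or `"alignment-oriented"`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param both_mates Count second mates of paired-end alignments too.
#'
#' @return A [motif_profile()] with `total_reads_used` + `skipped_reads`
#'   equal to the number of usable input records.
#' @examples
#' d <- motif_dictionary(4)
#' p <- count_end_motifs(c("CCCATTGA", "CCCAGGGG", "AAAATTTT"), d)
#' dplyr::filter(p, count > 0)
#' @export
count_end_motifs <- function(reads, dictionary, mode = c("raw-read", "alignment-oriented"),
                             sample_id = NULL, both_mates = FALSE) {
  mode <- match.arg(mode)
  k <- dictionary$k
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- guess_read_format(reads)
    if (fmt %in% c("sam", "bam")) {
      return(count_end_motifs_bam(reads, dictionary, mode, sample_id, both_mates))
    }
    if (mode == "alignment-oriented") {
      abort("alignment-oriented mode requires SAM/BAM input.",
            class = "endmotif_error_parameter")
    }
    if (is.null(sample_id)) sample_id <- strip_read_ext(reads)
    seqs <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
    return(count_prefix_motifs(seqs, dictionary, sample_id))
  }
  if (mode == "alignment-oriented") {
    abort("alignment-oriented mode requires SAM/BAM input.",
          class = "endmotif_error_parameter")
  }
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (!is.character(reads)) {
    abort("`reads` must be a file path, DNAStringSet or character vector.",
          class = "endmotif_error_parameter")
  }
  if (is.null(sample_id)) sample_id <- "sample"
  count_prefix_motifs(reads, dictionary, sample_id)
}

count_prefix_motifs <- function(seqs, dictionary, sample_id) {
  k <- dictionary$k
  prefixes <- substr(seqs, 1L, k)
  usable <- nchar(seqs) >= k & grepl("^[ACGT]+$", prefixes)
  tab <- table(factor(prefixes[usable], levels = dictionary$motifs))
  motif_profile(setNames(as.integer(tab), names(tab)), dictionary,
                sample_id = sample_id,
                skipped_reads = sum(!usable))
}

count_end_motifs_bam <- function(path, dictionary, mode, sample_id, both_mates) {
  fmt <- guess_read_format(path)
  if (fmt == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
    path <- bam
  }
  if (is.null(sample_id)) sample_id <- strip_read_ext(path)
  param <- Rsamtools::ScanBamParam(what = c("seq", "strand", "flag"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  seqs <- rec$seq
  if (length(seqs) == 0) {
    return(motif_profile(integer(0), dictionary, sample_id = sample_id))
  }
  flag <- rec$flag
  is_paired <- bitwAnd(flag, 1L) > 0L
  is_second <- bitwAnd(flag, 128L) > 0L
  keep <- !is_paired | both_mates | !is_second
  seqs <- seqs[keep]
  strand <- as.character(rec$strand)[keep]
  if (mode == "alignment-oriented") {
    rev <- !is.na(strand) & strand == "-"
    if (any(rev)) seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
  }
  count_prefix_motifs(as.character(seqs), dictionary, sample_id)
}

guess_read_format <- function(path) {
  p <- tolower(sub("\\.gz$", "", path))
  if (grepl("\\.bam$", p)) return("bam")
  if (grepl("\\.sam$", p)) return("sam")
  if (grepl("\\.(fa|fasta|fna)$", p)) return("fasta")
  if (grepl("\\.(fq|fastq)$", p)) return("fastq")
  abort(sprintf("Cannot infer read format from '%s'.", path),
        class = "endmotif_error_format")
}

strip_read_ext <- function(path) {
  sub("\\.(fq|fastq|fa|fasta|fna|sam|bam)(\\.gz)?$", "", basename(path),
      ignore.case = TRUE)
}
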