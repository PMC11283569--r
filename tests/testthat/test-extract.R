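test_that("5'-end prefixes are counted and degenerate reads skipped", {
  p <- count_end_motifs("CCCATTGA", dict4)
  expect_equal(p$count[p$motif == "CCCA"], 1L)
  expect_equal(attr(p, "total_reads_used"), 1L)

  p <- count_end_motifs("CCNATTGA", dict4)
  expect_equal(attr(p, "skipped_reads"), 1L)
  expect_equal(attr(p, "total_reads_used"), 0L)
  expect_true(all(p$count == 0))

  p <- count_end_motifs(c("CCCAxxxx", "CCCAyyyy", "AAAAzzzz"), dict4)
  expect_equal(p$count[p$motif == "CCCA"], 2L)
  expect_equal(p$count[p$motif == "AAAA"], 1L)
  expect_equal(attr(p, "total_reads_used"), 3L)

  # too-short reads are skipped, not errors
  p <- count_end_motifs(c("CC", "AAAA"), dict4)
  expect_equal(attr(p, "skipped_reads"), 1L)
})

test_that("frequencies sum to one and respect dictionary order", {
  p <- motif_profile(c(CCCA = 2L, AAAA = 2L), dict4)
  f <- profile_frequencies(p)
  expect_equal(unname(f[c("AAAA", "CCCA")]), c(0.5, 0.5))
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(names(f), dict4$motifs)

  one <- profile_frequencies(motif_profile(c(AAAA = 1L), dict4))
  expect_equal(sum(one == 1), 1)
  expect_error(profile_frequencies(motif_profile(integer(0), dict4)),
               class = "endmotif_error_empty_profile")
})

test_that("count tables round-trip through the tab-delimited format", {
  p <- count_end_motifs(c("ACGTAAAA", "ACGTCCCC", "TTTTGGGG"), dict4,
                        sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_counts(p, path)
  expect_equal(readLines(path)[1], "motif\tcount")
  p2 <- read_motif_counts(path, dict4, sample_id = "s1")
  expect_equal(p2$count, p$count)
  expect_equal(attr(p2, "total_reads_used"), attr(p, "total_reads_used"))
})

test_that("generated FASTQ reproduces the generator's counts exactly", {
  cohort <- simulate_cohort(n_cancer = 2, n_control = 2,
                            reads_per_sample = 500, seed = 5)
  dir <- withr::local_tempdir()
  files <- write_fastq(cohort$profiles, dir, read_length = 36, seed = 6)
  for (i in seq_along(files)) {
    p <- count_end_motifs(files[i], dict4)
    expect_equal(p$count, cohort$profiles[[i]]$count)
    expect_equal(attr(p, "skipped_reads"), 0L)
  }
})

test_that("FASTA input is accepted", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "CCCATT", ">r2", "GGGTAA"), path)
  p <- count_end_motifs(path, dict4)
  expect_equal(sum(p$count), 2L)
  expect_equal(p$count[p$motif == "GGGT"], 1L)
})

test_that("alignment-oriented counting reverse-complements minus-strand reads", {
  sam_header <- c("@HD\tVN:1.6\tSO:unmapped", "@SQ\tSN:chr1\tLN:1000")
  # forward read starts CCCA; reverse-strand read stored as aligned: its
  # fragment 5' motif is revcomp of the last 4 stored bases (TTTT -> AAAA)
  recs <- c(
    "r1\t0\tchr1\t1\t60\t8M\t*\t0\t0\tCCCAGGTT\tIIIIIIII",
    "r2\t16\tchr1\t10\t60\t8M\t*\t0\t0\tGGCCTTTT\tIIIIIIII"
  )
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sam_header, recs), sam)

  raw <- count_end_motifs(sam, dict4, mode = "raw-read")
  expect_equal(raw$count[raw$motif == "CCCA"], 1L)
  expect_equal(raw$count[raw$motif == "GGCC"], 1L)

  ori <- count_end_motifs(sam, dict4, mode = "alignment-oriented")
  expect_equal(ori$count[ori$motif == "CCCA"], 1L)
  expect_equal(ori$count[ori$motif == "AAAA"], 1L)
})

test_that("alignment-oriented equals raw-read on forward-strand-only input", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
               sprintf("r%d\t0\tchr1\t%d\t60\t6M\t*\t0\t0\t%s\tIIIIII",
                       1:3, c(1, 10, 20), c("ACGTAC", "TTGGCC", "CCCAAA"))),
             sam)
  a <- count_end_motifs(sam, dict4, mode = "raw-read")
  b <- count_end_motifs(sam, dict4, mode = "alignment-oriented")
  expect_equal(a$count, b$count)
})

test_that("second mates are excluded by default and counted on request", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
               "r1\t99\tchr1\t1\t60\t4M\t=\t50\t53\tACGT\tIIII",
               "r1\t147\tchr1\t50\t60\t4M\t=\t1\t-53\tGGGG\tIIII"),
             sam)
  first_only <- count_end_motifs(sam, dict4, mode = "raw-read")
  expect_equal(attr(first_only, "total_reads_used"), 1L)
  both <- count_end_motifs(sam, dict4, mode = "raw-read", both_mates = TRUE)
  expect_equal(attr(both, "total_reads_used"), 2L)
})
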