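test_that("CLS attention rows sum to one and match the attention tensor", {
  fx <- trained_fixture()
  s <- fx$sequences[[1]]
  scores <- cls_attention_scores(fx$model, list(s))
  fw <- transformer_forward(fx$model, s)
  motif_pos <- which(!s$tokens %in% dict4$special_tokens)
  for (j in seq_len(fx$model$config$num_heads)) {
    hj <- scores[scores$head == j, ]
    # scores are the CLS row of A restricted to motif positions
    expect_equal(hj$score, unname(fw$attentions[[1]][[j]][1, motif_pos]))
    # full CLS row including specials sums to 1
    expect_equal(sum(fw$attentions[[1]][[j]][1, ]), 1, tolerance = 1e-6)
    expect_lt(sum(hj$score), 1)
  }
  expect_setequal(hj$motif, s$tokens[motif_pos])
})

test_that("identical groups yield no significant motifs and BH is monotone", {
  fx <- trained_fixture()
  seqs <- fx$sequences[1:10]
  scores <- cls_attention_scores(fx$model, seqs)
  # assign labels independently of content: no real group signal
  labs <- setNames(rep(c("a", "b"), 5),
                   vapply(seqs, `[[`, "", "sample_id"))
  cmp <- compare_attention_groups(scores, labels = labs)
  expect_true(all(cmp$p.adjust >= cmp$p.value - 1e-12))
  expect_true(all(cmp$p.adjust >= 0 & cmp$p.adjust <= 1))
  # manual BH equivalence within one head
  h1 <- cmp[cmp$head == 1, ]
  expect_equal(h1$p.adjust, p.adjust(h1$p.value, "BH"))
})

test_that("a strongly shifted motif is flagged after BH adjustment", {
  withr::with_seed(61, {
    motifs <- dict4$motifs[1:20]
    mk <- function(label, i) {
      sc <- tibble::tibble(
        sample_id = sprintf("%s%02d", label, i), label = label, head = 1L,
        motif = motifs, score = rnorm(20, mean = 0.05, sd = 0.005))
      # shift one motif by ~5 pooled SDs in the cancer group
      if (label == "cancer") sc$score[sc$motif == "AAAC"] <-
          rnorm(1, mean = 0.05 + 5 * 0.005, sd = 0.005)
      sc
    }
    scores <- dplyr::bind_rows(
      lapply(1:30, function(i) mk("cancer", i)),
      lapply(1:30, function(i) mk("control", i)))
  })
  cmp <- compare_attention_groups(scores, test = "wilcoxon")
  flagged <- cmp$motif[cmp$p.adjust < 0.05]
  expect_true("AAAC" %in% flagged)
  cmp_t <- compare_attention_groups(scores, test = "t-test")
  expect_true("AAAC" %in% cmp_t$motif[cmp_t$p.adjust < 0.05])
})

test_that("constant scores give p = 1 and one-group motifs are excluded", {
  scores <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:6), each = 2),
    label = rep(c("cancer", "control"), each = 6),
    head = 1L,
    motif = rep(c("AAAA", "CCCC"), 6),
    score = 0.1)
  # a motif seen only in the cancer group must be dropped
  extra <- tibble::tibble(sample_id = "s1", label = "cancer", head = 1L,
                          motif = "GGGG", score = 0.5)
  cmp <- compare_attention_groups(dplyr::bind_rows(scores, extra))
  expect_false("GGGG" %in% cmp$motif)
  expect_equal(cmp$p.value, rep(1, nrow(cmp)))
})

test_that("attention networks retain the strongest interactions", {
  fx <- trained_fixture()
  grp <- fx$sequences[1:5]
  full <- build_attention_network(fx$model, grp, retention = 1)
  expect_true(all(full$weight > 0))
  expect_false(any(full$source == full$target))
  expect_equal(full$weight, sort(full$weight, decreasing = TRUE))
  n_cand <- attr(full, "n_candidates")
  top <- build_attention_network(fx$model, grp, retention = 0.01)
  expect_lte(nrow(top), ceiling(0.01 * n_cand))
  expect_equal(top$weight, head(full$weight, nrow(top)))
  expect_error(build_attention_network(fx$model, list(), retention = 0.1),
               class = "endmotif_error_empty")
  expect_error(build_attention_network(fx$model, grp, retention = 0),
               class = "endmotif_error_parameter")
})

test_that("the default retention keeps ~0.1% of candidate pairs", {
  # sequences covering all 256 motifs: candidate ordered pairs ~ 256*255
  prof <- motif_profile(setNames(rep(1L, 256) + seq_len(256) %% 5,
                                 dict4$motifs), dict4, sample_id = "s1")
  seqs <- list(rank_and_tokenize(prof, t = 255))
  m <- tiny_model(seed = 9)
  net <- build_attention_network(m, seqs, retention = 0.001)
  n_cand <- attr(net, "n_candidates")
  expect_equal(n_cand, 255 * 254)  # t = 255 distinct motifs per sequence
  expect_equal(nrow(net), ceiling(0.001 * n_cand))
})

test_that("network weights are additive across groups and order-invariant", {
  fx <- trained_fixture()
  a <- fx$sequences[1:3]; b <- fx$sequences[4:6]
  na <- build_attention_network(fx$model, a, retention = 1)
  nb <- build_attention_network(fx$model, b, retention = 1)
  nab <- build_attention_network(fx$model, c(a, b), retention = 1)
  key <- function(n) setNames(n$weight, paste(n$source, n$target))
  ka <- key(na); kb <- key(nb); kab <- key(nab)
  joint <- union(names(ka), names(kb))
  summed <- setNames(rep(0, length(joint)), joint)
  summed[names(ka)] <- summed[names(ka)] + ka
  summed[names(kb)] <- summed[names(kb)] + kb
  expect_equal(kab[sort(names(kab))], summed[sort(names(summed))],
               tolerance = 1e-10)
  shuffled <- build_attention_network(fx$model, c(a, b)[c(4, 2, 6, 1, 3, 5)],
                                      retention = 1)
  expect_equal(key(shuffled), kab)
})

test_that("networks export to TSV and GraphML", {
  fx <- trained_fixture()
  net <- build_attention_network(fx$model, fx$sequences[1:3], retention = 0.05)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, tsv = tsv, graphml = gml)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net))
  expect_true(igraph::is_directed(g))
})
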