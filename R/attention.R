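#' CLS-attention importance scores per motif
#'
#' For each sequence and attention head, reads the CLS row of the attention
#' matrix (how strongly the sequence-summary token attends to each position)
#' and keys it by motif identity — positions differ across sequences because
#' rankings differ. Motifs absent from a sequence are simply missing from
#' that sequence's rows (not recorded as zero). The full CLS row, including
#' special tokens, sums to 1 per head; the returned scores are its
#' restriction to motif positions.
#'
#' @param model A `motif_transformer`.
#' @param sequences List of `end_motif_sequence`.
#' @param layer Encoder layer to read attention from (default: last).
#' @return Tibble with columns `sample_id`, `label`, `head`, `motif`,
#'   `score`.
#' @export
cls_attention_scores <- function(model, sequences, layer = NULL) {
  if (is.null(layer)) layer <- model$config$num_layers
  purrr::map_dfr(sequences, function(s) {
    fw <- transformer_forward(model, s)
    heads <- fw$attentions[[layer]]
    motif_pos <- which(!s$tokens %in% model$dictionary$special_tokens)
    purrr::map_dfr(seq_along(heads), function(j) {
      tibble(sample_id = s$sample_id,
             label = if (is.null(s$label)) NA_character_ else as.character(s$label),
             head = j,
             motif = s$tokens[motif_pos],
             score = heads[[j]][1L, motif_pos])
    })
  })
}

#' Compare CLS-attention scores between groups
#'
#' Per motif and per head, a two-sided test (Wilcoxon rank-sum by default, or
#' Welch t-test) of the per-sample attention scores between the two label
#' groups, with Benjamini-Hochberg adjustment across motifs within each head.
#' When one sample contributes several sequences its scores are averaged
#' first. Motifs observed in only one group are dropped from the comparison;
#' cells where every value is identical in both groups get p = 1 by
#' convention.
#'
#' @param scores Tibble from [cls_attention_scores()] (needs `label` filled,
#'   or pass `labels`).
#' @param labels Optional named vector `sample_id -> label` overriding the
#'   `label` column.
#' @param test `"wilcoxon"` (default, as in the group-difference analysis) or
#'   `"t-test"`.
#' @param bh_scope `"head"` (adjust within each head, default) or `"global"`.
#' @return Tibble of class `attention_comparison`: `motif`, `head`,
#'   `mean_a`, `mean_b` (group means, groups in sorted label order),
#'   `statistic`, `p.value`, `p.adjust`.
#' @export
compare_attention_groups <- function(scores, labels = NULL,
                                     test = c("wilcoxon", "t-test"),
                                     bh_scope = c("head", "global")) {
  test <- match.arg(test)
  bh_scope <- match.arg(bh_scope)
  if (!is.null(labels)) {
    scores$label <- unname(labels[scores$sample_id])
  }
  if (anyNA(scores$label)) {
    abort("Every sample needs a group label.", class = "endmotif_error_parameter")
  }
  groups <- sort(unique(scores$label))
  if (length(groups) != 2L) {
    abort("Exactly two groups are required.",
          class = "endmotif_error_degenerate_labels")
  }
  per_sample <- scores |>
    dplyr::group_by(.data$sample_id, .data$label, .data$head, .data$motif) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  res <- per_sample |>
    dplyr::group_by(.data$head, .data$motif) |>
    dplyr::group_modify(function(df, key) {
      a <- df$score[df$label == groups[1L]]
      b <- df$score[df$label == groups[2L]]
      if (length(a) == 0L || length(b) == 0L) {
        return(tibble())  # motif absent from one group: excluded
      }
      if (length(unique(c(a, b))) == 1L) {
        return(tibble(mean_a = mean(a), mean_b = mean(b),
                      statistic = NA_real_, p.value = 1))
      }
      ht <- if (test == "wilcoxon") {
        suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
      } else {
        t.test(a, b, alternative = "two.sided")
      }
      tibble(mean_a = mean(a), mean_b = mean(b),
             statistic = unname(ht$statistic), p.value = ht$p.value)
    }) |>
    dplyr::ungroup()
  res <- if (bh_scope == "head") {
    res |>
      dplyr::group_by(.data$head) |>
      dplyr::mutate(p.adjust = p.adjust(.data$p.value, method = "BH")) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(res, p.adjust = p.adjust(.data$p.value, method = "BH"))
  }
  attr(res, "groups") <- groups
  attr(res, "test") <- test
  class(res) <- c("attention_comparison", class(res))
  res
}

#' Build an end-motif attention network for one group
#'
#' Accumulates the pairwise attention weights `alpha[i, j]` over all
#' sequences of a group (summed over the heads of the chosen layer), keyed by
#' source/target motif identity with special tokens excluded and no
#' self-loops, then retains the strongest fraction of interactions: the top
#' `ceiling(retention * n_candidate_pairs)` edges by cumulative weight
#' (deterministic tie-break by motif order). The default retention 0.001
#' mirrors keeping the top 0.1% of interactions.
#'
#' @param model A `motif_transformer`.
#' @param sequences Sequences of one group.
#' @param retention Fraction of candidate (nonzero) ordered pairs to keep,
#'   in (0, 1].
#' @param layer Layer whose attention is accumulated (default: last).
#' @return A `motif_network`: tibble of directed edges (`source`, `target`,
#'   `weight`) with attributes `retention` and `n_candidates`.
#' @export
build_attention_network <- function(model, sequences, retention = 0.001,
                                    layer = NULL) {
  if (length(sequences) == 0L) {
    abort("Cannot build a network from an empty group.",
          class = "endmotif_error_empty")
  }
  if (retention <= 0 || retention > 1) {
    abort("`retention` must be in (0, 1].", class = "endmotif_error_parameter")
  }
  if (is.null(layer)) layer <- model$config$num_layers
  acc <- new.env(parent = emptyenv())
  for (s in sequences) {
    fw <- transformer_forward(model, s)
    heads <- fw$attentions[[layer]]
    motif_pos <- which(!s$tokens %in% model$dictionary$special_tokens)
    motifs <- s$tokens[motif_pos]
    A <- Reduce(`+`, heads)[motif_pos, motif_pos, drop = FALSE]
    diag(A) <- 0
    nz <- which(A > 0, arr.ind = TRUE)
    keys <- paste(motifs[nz[, 1L]], motifs[nz[, 2L]], sep = "\t")
    w <- A[nz]
    agg <- rowsum(w, keys)
    for (i in seq_len(nrow(agg))) {
      kk <- rownames(agg)[i]
      acc[[kk]] <- (if (is.null(acc[[kk]])) 0 else acc[[kk]]) + agg[i, 1L]
    }
  }
  keys <- ls(acc)
  w <- vapply(keys, function(kk) acc[[kk]], 0)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- tibble(source = vapply(parts, `[[`, "", 1L),
                  target = vapply(parts, `[[`, "", 2L),
                  weight = unname(w)) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$source, .data$target)
  n_cand <- nrow(edges)
  n_keep <- min(n_cand, ceiling(retention * n_cand))
  out <- edges[seq_len(n_keep), ]
  structure(out, class = c("motif_network", class(out)),
            retention = retention, n_candidates = n_cand)
}

#' Export an attention network for external graph viewers
#'
#' Writes the directed weighted edge list as TSV and/or GraphML (loadable by
#' Cytoscape-class tools).
#'
#' @param network A `motif_network` from [build_attention_network()].
#' @param tsv,graphml Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, tsv = NULL, graphml = NULL) {
  written <- character(0)
  if (!is.null(tsv)) {
    write.table(as.data.frame(network[, c("source", "target", "weight")]),
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(network[, c("source", "target", "weight")]),
      directed = TRUE)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
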