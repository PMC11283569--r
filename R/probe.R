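#' Extract a frozen representation for a ranked motif sequence
#'
#' Runs the encoder in evaluation mode and returns the final-layer hidden
#' state at the CLS position — the sequence-level summary the CLS token
#' aggregates — or the mean over non-PAD positions when `pooling = "mean"`.
#'
#' @param model A `motif_transformer`.
#' @param sequence An `end_motif_sequence`.
#' @param pooling `"cls"` (default) or `"mean"`.
#' @return Numeric vector of length `hidden_size`.
#' @export
extract_representation <- function(model, sequence, pooling = c("cls", "mean")) {
  pooling <- match.arg(pooling)
  fw <- transformer_forward(model, sequence)
  if (pooling == "cls") {
    fw$Z[1L, ]
  } else {
    tokens <- if (inherits(sequence, "end_motif_sequence")) sequence$tokens else sequence
    colMeans(fw$Z[tokens != "PAD", , drop = FALSE])
  }
}

#' @rdname extract_representation
#' @param sequences List of `end_motif_sequence`.
#' @return `extract_representations` returns an `n x hidden_size` matrix with
#'   one row per sequence, rownames from sample ids.
#' @export
extract_representations <- function(model, sequences, pooling = c("cls", "mean")) {
  pooling <- match.arg(pooling)
  out <- t(vapply(sequences, function(s) extract_representation(model, s, pooling),
                  numeric(model$config$hidden_size)))
  rownames(out) <- vapply(sequences, function(s) s$sample_id, "")
  out
}

stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Linear probing of frozen representations under cross-validation
#'
#' Fits an L2-regularized linear (logistic) classifier on frozen features
#' under stratified k-fold cross-validation: features are standardized with
#' train-fold statistics, a ridge-penalized logistic model is fit on the
#' train folds, and probabilities are predicted on the held-out fold. Pooled
#' out-of-fold predictions feed every reported metric: AUROC with a DeLong
#' 95% CI, and accuracy/sensitivity/specificity at `threshold` with exact
#' Clopper-Pearson 95% CIs. The ridge strength is fixed (not tuned) so the
#' probe stays a linear projection of the representation rather than a
#' model-selection exercise.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param labels Binary vector; the positive (cancer) class is `positive`.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the stratified fold shuffle.
#' @param positive Value of `labels` treated as the positive class. Defaults
#'   to `"cancer"` when present, otherwise the larger level.
#' @param lambda Fixed ridge penalty (default 0.01).
#' @param threshold Probability cutoff for the confusion-matrix metrics.
#'
#' @return A `probe_result`: list with `predictions` (tibble: `sample_id`,
#'   `label`, `fold`, `prob`), `metrics` (tibble: metric, estimate, conf.low,
#'   conf.high), `threshold`, `positive`, `folds`, `seed`.
#' @export
linear_probe_cv <- function(x, labels, folds = 5, seed = 1L, positive = NULL,
                            lambda = 0.01, threshold = 0.5) {
  x <- as.matrix(x)
  folds <- check_positive_int(folds, "folds")
  if (nrow(x) != length(labels)) {
    abort("`labels` must have one entry per row of `x`.",
          class = "endmotif_error_shape")
  }
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    abort("Exactly two classes are required.",
          class = "endmotif_error_degenerate_labels")
  }
  if (is.null(positive)) positive <- if ("cancer" %in% lv) "cancer" else lv[2L]
  if (nrow(x) < folds) {
    abort("Need at least as many samples as folds.",
          class = "endmotif_error_parameter")
  }
  y <- as.integer(labels == positive)
  fold <- stratified_folds(labels, folds, seed)
  prob <- numeric(nrow(x))
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    xs <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
    # separable folds trigger glmnet's perfect-fit warning; that is the
    # expected regime for a probe on strong signal
    fit <- suppressWarnings(
      glmnet::glmnet(xs[tr, , drop = FALSE], factor(y[tr], levels = 0:1),
                     family = "binomial", alpha = 0,
                     lambda = sort(unique(c(10, 1, 0.1, lambda)),
                                   decreasing = TRUE),
                     standardize = FALSE))
    prob[!tr] <- as.numeric(predict(fit, xs[!tr, , drop = FALSE],
                                    s = lambda, type = "response"))
  }
  sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(x)))
  preds <- tibble(sample_id = sample_ids, label = labels,
                  fold = fold, prob = prob)
  metrics <- probe_metrics(prob, y, threshold)
  structure(list(predictions = preds, metrics = metrics,
                 threshold = threshold, positive = positive,
                 folds = folds, seed = seed),
            class = "probe_result")
}

probe_metrics <- function(prob, y, threshold) {
  roc <- auroc_with_ci(prob, y)
  cm <- binary_metrics_cp(as.integer(prob >= threshold), y)
  dplyr::bind_rows(
    tibble(metric = "auroc", estimate = roc$auroc,
           conf.low = roc$ci[1L], conf.high = roc$ci[2L]),
    cm
  )
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe_result> %d samples, %d folds (positive class '%s')\n",
              nrow(x$predictions), x$folds, x$positive))
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Linear probe on raw end-motif count profiles (baseline)
#'
#' The reference method: the same cross-validated ridge-logistic probe applied
#' directly to the per-sample end-motif matrix instead of learned
#' representations. By default the counts are normalized to frequencies so
#' sequencing depth does not act as a feature; `normalize = FALSE` probes raw
#' counts. Using the same `seed` as the representation probe yields the
#' identical fold partition, which makes the two AUROCs comparable with the
#' paired DeLong test.
#'
#' @param counts Samples-by-motifs numeric matrix, or a list of
#'   [motif_profile()] objects.
#' @param labels,folds,seed,... Passed to [linear_probe_cv()].
#' @param normalize Divide each row by its total (default TRUE).
#' @return A `probe_result`.
#' @export
count_baseline_probe <- function(counts, labels, folds = 5, seed = 1L,
                                 normalize = TRUE, ...) {
  if (is.list(counts) && inherits(counts[[1L]], "motif_profile")) {
    ids <- vapply(counts, function(p) attr(p, "sample_id"), "")
    counts <- do.call(rbind, lapply(counts, function(p) p$count))
    rownames(counts) <- ids
  }
  counts <- as.matrix(counts)
  if (normalize) {
    tot <- rowSums(counts)
    tot[tot == 0] <- 1
    counts <- counts / tot
  }
  linear_probe_cv(counts, labels, folds = folds, seed = seed, ...)
}
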