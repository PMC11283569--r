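#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline geom_col labs theme_minimal coord_equal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy / summarize a cross-validated probe
#'
#' `tidy()` returns the metric table (one row per metric with its 95% CI);
#' `glance()` returns a one-row summary with the AUROC, accuracy at the
#' threshold, fold count and sample count.
#'
#' @param x A `probe_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy probe_result
#' @export
tidy.probe_result <- function(x, ...) x$metrics

#' @rdname tidy.probe_result
#' @method glance probe_result
#' @export
glance.probe_result <- function(x, ...) {
  m <- x$metrics
  tibble(auroc = m$estimate[m$metric == "auroc"],
         accuracy = m$estimate[m$metric == "accuracy"],
         sensitivity = m$estimate[m$metric == "sensitivity"],
         specificity = m$estimate[m$metric == "specificity"],
         n = nrow(x$predictions), folds = x$folds,
         threshold = x$threshold, positive = x$positive)
}

#' ROC curve of a probe's pooled out-of-fold predictions
#'
#' @param object A `probe_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot probe_result
#' @export
autoplot.probe_result <- function(object, ...) {
  y <- as.integer(object$predictions$label == object$positive)
  ord <- order(object$predictions$prob, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1L) / max(sum(y == 1L), 1L))
  fpr <- c(0, cumsum(y[ord] == 0L) / max(sum(y == 0L), 1L))
  auc <- object$metrics$estimate[object$metrics$metric == "auroc"]
  ggplot(tibble(fpr = fpr, tpr = tpr), aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("Linear probe ROC (AUROC = %.3f)", auc)) +
    theme_minimal()
}

#' Tidy / summarize a pretraining run
#'
#' `tidy()` returns the per-epoch metrics (train loss, holdout ECE, learning
#' rate); `glance()` a one-row summary with initial and final holdout ECE.
#'
#' @param x A `pretrain_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pretrain_run
#' @export
tidy.pretrain_run <- function(x, ...) x$metrics

#' @rdname tidy.pretrain_run
#' @method glance pretrain_run
#' @export
glance.pretrain_run <- function(x, ...) {
  m <- x$metrics
  tibble(epochs = max(m$epoch),
         initial_ece = m$holdout_ece[m$epoch == 0L],
         final_ece = m$holdout_ece[which.max(m$epoch)],
         final_train_loss = m$train_loss[which.max(m$epoch)],
         holdout_n = length(x$holdout_ids), seed = x$seed)
}

#' Holdout ECE learning curve
#'
#' @param object A `pretrain_run`.
#' @param ... Unused.
#' @return A ggplot of holdout ECE against training epoch.
#' @method autoplot pretrain_run
#' @export
autoplot.pretrain_run <- function(object, ...) {
  ggplot(object$metrics, aes(x = .data$epoch, y = .data$holdout_ece)) +
    geom_line() + geom_point() +
    labs(x = "Epoch", y = "Holdout ECE",
         title = "Masked-token pretraining fit") +
    theme_minimal()
}

#' Tidy / summarize a kBET result
#'
#' `tidy()` returns the per-sample chi-square statistics and p-values;
#' `glance()` the acceptance rate with the test's settings.
#'
#' @param x A `kbet_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kbet_result
#' @export
tidy.kbet_result <- function(x, ...) x$samples

#' @rdname tidy.kbet_result
#' @method glance kbet_result
#' @export
glance.kbet_result <- function(x, ...) {
  tibble(acceptance_rate = x$acceptance_rate, n = nrow(x$samples),
         batches = length(x$batch_frequencies), K = x$K, alpha = x$alpha)
}

#' Top differential motifs by CLS attention
#'
#' Bar chart of the attention-score difference (group means) for the most
#' significant motifs of each head.
#'
#' @param object An `attention_comparison` from
#'   [compare_attention_groups()].
#' @param n_motifs Motifs shown per head (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attention_comparison
#' @export
autoplot.attention_comparison <- function(object, n_motifs = 10, ...) {
  top <- object |>
    dplyr::mutate(diff = .data$mean_a - .data$mean_b) |>
    dplyr::group_by(.data$head) |>
    dplyr::slice_min(.data$p.adjust, n = n_motifs, with_ties = FALSE) |>
    dplyr::ungroup()
  groups <- attr(object, "groups")
  ggplot(top, aes(x = stats::reorder(.data$motif, .data$diff), y = .data$diff,
                  fill = .data$p.adjust < 0.05)) +
    geom_col() +
    facet_wrap(~head, scales = "free_y") +
    labs(x = NULL,
         y = sprintf("Mean CLS attention: %s - %s", groups[1L], groups[2L]),
         fill = "adj. p < 0.05") +
    theme_minimal() +
    ggplot2::coord_flip()
}
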