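#' AUROC with a DeLong 95% confidence interval
#'
#' The AUROC is the rank statistic (ties count one half). Its variance is
#' estimated with DeLong's structural components: per-case placement values
#' against controls and vice versa; the CI is the normal interval on the AUC
#' scale, clipped to [0, 1].
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1/TRUE/"cancer" = positive); any two-level
#'   vector works, with the positive class taken as the larger level unless
#'   `positive` is given.
#' @param positive Value treated as the positive class.
#' @param conf.level Confidence level (default 0.95).
#' @return List with `auroc`, `ci` (length 2), `se`.
#' @examples
#' auroc_with_ci(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auroc  # 1
#' @export
auroc_with_ci <- function(scores, labels, positive = NULL, conf.level = 0.95) {
  y <- binarize_labels(labels, positive)
  cases <- scores[y == 1L]
  controls <- scores[y == 0L]
  comp <- delong_components(cases, controls)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- pmin(pmax(comp$auc + c(-1, 1) * z * comp$se, 0), 1)
  list(auroc = comp$auc, ci = ci, se = comp$se)
}

binarize_labels <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    abort("Exactly two classes are required.",
          class = "endmotif_error_degenerate_labels")
  }
  if (is.null(positive)) {
    positive <- if ("cancer" %in% lv) "cancer" else if ("1" %in% lv) "1" else lv[2L]
  }
  as.integer(labels == positive)
}

# Placement values: V10[i] = P(case_i > control) + 0.5 P(==), over controls;
# V01[j] symmetric. AUC = mean(V10); var = S10/m + S01/n.
delong_components <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  if (m == 0L || n == 0L) {
    abort("Both classes must be present.",
          class = "endmotif_error_degenerate_labels")
  }
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  list(auc = auc, se = sqrt(s10 / m + s01 / n), v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares two scoring rules evaluated on the same samples (e.g. the
#' representation probe versus the raw-count baseline) with DeLong's paired
#' z-test on the AUROC difference.
#'
#' @param scores_a,scores_b Scores from the two classifiers, same samples in
#'   the same order.
#' @param labels Binary labels shared by both.
#' @param positive Value treated as the positive class.
#' @return List with `auc_a`, `auc_b`, `statistic` (z), `p.value`
#'   (two-sided).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("Scores and labels must have equal lengths.",
          class = "endmotif_error_shape")
  }
  y <- binarize_labels(labels, positive)
  ca <- delong_components(scores_a[y == 1L], scores_a[y == 0L])
  cb <- delong_components(scores_b[y == 1L], scores_b[y == 0L])
  m <- sum(y == 1L); n <- sum(y == 0L)
  s10 <- if (m > 1) var(ca$v10 - cb$v10) else 0
  s01 <- if (n > 1) var(ca$v01 - cb$v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  diff <- ca$auc - cb$auc
  if (se == 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / se
  }
  list(auc_a = ca$auc, auc_b = cb$auc, statistic = z,
       p.value = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' Confusion-matrix metrics with exact Clopper-Pearson intervals
#'
#' Accuracy, sensitivity and specificity from predicted and true binary
#' labels, each with the exact two-sided 95% Clopper-Pearson binomial
#' interval (the beta-quantile interval computed by `stats::binom.test`).
#'
#' @param predicted Predicted binary labels (same coding as `truth`).
#' @param truth True binary labels (1 = positive).
#' @param conf.level Confidence level (default 0.95).
#' @return Tibble with columns `metric`, `estimate`, `conf.low`, `conf.high`,
#'   `successes`, `trials`.
#' @examples
#' # 17 of 21 cases detected: sensitivity CI (0.581, 0.946)
#' binary_metrics_cp(rep(c(1, 0), c(17, 4)), rep(1, 21))
#' @export
binary_metrics_cp <- function(predicted, truth, conf.level = 0.95) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be equal-length non-empty vectors.",
          class = "endmotif_error_degenerate")
  }
  cp_row <- function(metric, x, n) {
    if (n == 0L) {
      return(tibble(metric = metric, estimate = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_,
                    successes = 0L, trials = 0L))
    }
    ci <- binom.test(x, n, conf.level = conf.level)$conf.int
    tibble(metric = metric, estimate = x / n,
           conf.low = ci[1L], conf.high = ci[2L],
           successes = as.integer(x), trials = as.integer(n))
  }
  dplyr::bind_rows(
    cp_row("accuracy", sum(predicted == truth), length(truth)),
    cp_row("sensitivity", sum(predicted == 1L & truth == 1L), sum(truth == 1L)),
    cp_row("specificity", sum(predicted == 0L & truth == 0L), sum(truth == 0L))
  )
}
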