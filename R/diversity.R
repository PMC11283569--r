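#' Motif diversity score (normalized Shannon entropy)
#'
#' `MDS = sum_i -P_i * log(P_i) / log(N)` over the `N = 4^k` end-motif
#' frequencies `P_i`, with `0 * log(0)` defined as 0. The score lies in
#' [0, 1]: 0 for a point mass on one motif, 1 for the uniform distribution.
#' The logarithm base cancels in the ratio, so natural log is used.
#'
#' @param x A [motif_profile()] or a non-negative frequency vector summing to
#'   1 (within `tol`).
#' @param tol Tolerance on the simplex constraint (default 1e-6).
#' @return The diversity score in [0, 1].
#' @examples
#' motif_diversity(rep(1 / 256, 256))          # 1
#' motif_diversity(c(1, rep(0, 255)))          # 0
#' motif_diversity(c(0.5, 0.5, rep(0, 254)))   # log(2)/log(256) = 0.125
#' @export
motif_diversity <- function(x, tol = 1e-6) {
  p <- if (inherits(x, "motif_profile")) profile_frequencies(x) else as.numeric(x)
  if (any(p < 0)) {
    abort("Frequencies must be non-negative.",
          class = "endmotif_error_distribution")
  }
  if (abs(sum(p) - 1) > tol) {
    abort("Frequencies must sum to 1.", class = "endmotif_error_distribution")
  }
  nz <- p[p > 0]
  sum(-nz * log(nz)) / log(length(p))
}

#' kBET batch-effect acceptance rate
#'
#' The k-nearest-neighbour batch-effect test: for every sample, the batch
#' composition of its K nearest neighbours (Euclidean, self excluded,
#' distance ties broken by sample index) is compared with the global batch
#' frequencies `f_j = n_j / n` by a chi-square statistic
#' `k_i = sum_j (n_ji - f_j K)^2 / (f_j K)` on `m - 1` degrees of freedom
#' with p-value `1 - F(k_i)`. The acceptance rate is the percentage of
#' samples with `p >= alpha`; values near 100% indicate well-mixed batches,
#' values near 0 a strong batch effect.
#'
#' @param points Numeric matrix (samples in rows) of any representation —
#'   frequencies, rankings, or learned features.
#' @param batches Batch label per row; at least 2 batches.
#' @param K Neighbourhood size (default 5).
#' @param alpha Significance level (default 0.05).
#' @return A `kbet_result`: list with `acceptance_rate` (percent),
#'   `samples` (tibble: `sample`, `batch`, `statistic`, `p.value`,
#'   `accepted`), `batch_frequencies`, `K`, `alpha`.
#' @export
kbet_acceptance <- function(points, batches, K = 5, alpha = 0.05) {
  points <- as.matrix(points)
  K <- check_positive_int(K, "K")
  n <- nrow(points)
  if (length(batches) != n) {
    abort("One batch label per row is required.",
          class = "endmotif_error_shape")
  }
  batches <- factor(batches)
  m <- nlevels(batches)
  if (m < 2L) {
    abort("At least two batches are required.",
          class = "endmotif_error_degenerate_batches")
  }
  if (K >= n) {
    abort("`K` must be smaller than the number of samples.",
          class = "endmotif_error_parameter")
  }
  f <- as.numeric(table(batches)) / n
  expected <- f * K
  D <- as.matrix(dist(points))
  diag(D) <- Inf
  stat <- numeric(n)
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[seq_len(K)]  # stable order: index breaks ties
    obs <- tabulate(batches[nn], nbins = m)
    stat[i] <- sum((obs - expected)^2 / expected)
  }
  pval <- 1 - pchisq(stat, df = m - 1L)
  accepted <- pval >= alpha
  ids <- rownames(points)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(n))
  structure(
    list(acceptance_rate = 100 * mean(accepted),
         samples = tibble(sample = ids, batch = as.character(batches),
                          statistic = stat, p.value = pval,
                          accepted = accepted),
         batch_frequencies = setNames(f, levels(batches)),
         K = K, alpha = alpha),
    class = "kbet_result"
  )
}

#' @export
print.kbet_result <- function(x, ...) {
  cat(sprintf("<kbet_result> acceptance rate %.1f%% (n = %d, %d batches, K = %d, alpha = %g)\n",
              x$acceptance_rate, nrow(x$samples),
              length(x$batch_frequencies), x$K, x$alpha))
  invisible(x)
}
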