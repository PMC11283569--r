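# exhaustive concordant-pair oracle: P(case > control) + 0.5 P(tie)
auc_by_counting <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

test_that("AUROC matches fixed hand-counted instances", {
  expect_equal(auroc_with_ci(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auroc, 1.0)
  # {0.9, 0.4} vs {0.3, 0.5}: 3 concordant of 4 pairs
  expect_equal(auroc_with_ci(c(0.9, 0.4, 0.3, 0.5), c(1, 1, 0, 0))$auroc, 0.75)
  expect_equal(auroc_with_ci(rep(0.7, 10), rep(c(1, 0), 5))$auroc, 0.5)
})

test_that("DeLong point estimate equals exhaustive pair counting", {
  withr::with_seed(51, {
    for (i in 1:100) {
      n <- sample(6:50, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
      scores <- round(runif(n), sample(1:3, 1))  # ties likely
      expect_equal(auroc_with_ci(scores, y)$auroc, auc_by_counting(scores, y))
    }
  })
})

test_that("DeLong CI and variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(52, {
    y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
    scores <- rnorm(80, mean = y)
  })
  ours <- auroc_with_ci(scores, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, scores, quiet = TRUE, levels = c(0, 1), direction = "<"),
                                       method = "delong"))
  expect_equal(ours$auroc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$ci[1], as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(ours$ci[2], as.numeric(ref[3]), tolerance = 1e-8)
})

test_that("paired DeLong test behaves at its boundary cases", {
  withr::with_seed(53, {
    y <- rep(c(1, 0), each = 100)
    perfect <- y + rnorm(200, sd = 0.01)
    random <- rnorm(200)
  })
  same <- delong_paired_test(perfect, perfect, y)
  expect_equal(same$p.value, 1.0)
  strong <- delong_paired_test(perfect, random, y)
  expect_lt(strong$p.value, 0.001)
  # antisymmetry of the z statistic
  ab <- delong_paired_test(perfect, random, y)
  ba <- delong_paired_test(random, perfect, y)
  expect_equal(ab$statistic, -ba$statistic)
  expect_error(delong_paired_test(1:3, 1:4, c(1, 0, 1)),
               class = "endmotif_error_shape")
})

test_that("paired test matches pROC's DeLong test on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(54, {
    y <- rep(c(1, 0), each = 60)
    a <- y + rnorm(120, sd = 1.2)
    b <- y + rnorm(120, sd = 2.5)
  })
  ours <- delong_paired_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, levels = c(0, 1), direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, levels = c(0, 1), direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p.value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("Clopper-Pearson intervals reproduce exact binomial bounds", {
  # 17/21 correct cancer calls
  sens <- binary_metrics_cp(rep(c(1, 0), c(17, 4)), rep(1, 21))
  row <- sens[sens$metric == "sensitivity", ]
  expect_equal(row$estimate, 17 / 21, tolerance = 1e-12)
  expect_equal(round(row$conf.low, 3), 0.581)
  expect_equal(round(row$conf.high, 3), 0.946)
  # 37/41 overall
  acc <- binary_metrics_cp(c(rep(1, 17), rep(0, 4 + 20)),
                           rep(c(1, 0), c(21, 20)))
  arow <- acc[acc$metric == "accuracy", ]
  expect_equal(arow$successes, 37L)
  expect_equal(round(arow$conf.low, 3), 0.769)
  expect_equal(round(arow$conf.high, 3), 0.973)
  # x = n closed form: lower bound alpha/2 ^ (1/n), upper exactly 1
  all20 <- binary_metrics_cp(rep(1, 20), rep(1, 20))
  srow <- all20[all20$metric == "sensitivity", ]
  expect_equal(srow$conf.low, 0.025^(1 / 20), tolerance = 1e-9)
  expect_equal(srow$conf.low, stats::qbeta(0.025, 20, 1), tolerance = 1e-12)
  expect_equal(srow$conf.high, 1)
})

test_that("Clopper-Pearson width shrinks with n and contains the estimate", {
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    x <- round(0.8 * n)
    r <- binary_metrics_cp(rep(c(1, 0), c(x, n - x)), rep(1, n))
    r <- r[r$metric == "sensitivity", ]
    expect_true(r$conf.low <= r$estimate && r$estimate <= r$conf.high)
    r$conf.high - r$conf.low
  }, 0)
  expect_true(all(diff(widths) < 0))
})
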