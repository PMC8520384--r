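test_that("rank-sum test: worked examples, symmetry, and reference agreement", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_exact, 0.1)          # 2 of the 20 assignments are as extreme
  expect_equal(wilcoxon_rank_sum(c(5, 1, 9), c(9, 5, 1))$Z, 0)
  set.seed(51)
  x <- rnorm(15); y <- rnorm(12) + 0.4
  expect_equal(wilcoxon_rank_sum(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
  # tie-corrected variance also matches the reference implementation
  xt <- c(1, 2, 2, 3, 7); yt <- c(2, 3, 3, 8)
  expect_equal(wilcoxon_rank_sum(xt, yt)$p,
               suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                                   correct = FALSE)$p.value),
               tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("rank-sum normal approximation tracks the exact enumeration", {
  set.seed(52)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(4) + runif(1, -1, 1)
    w <- wilcoxon_rank_sum(x, y)
    expect_equal(w$p_exact, enum_ranksum_p(x, y))
  }
  # expected gap over the exact null distribution, evaluated exhaustively,
  # shrinks with N and is well under 0.05 by N = 15
  gap <- function(n1, n2) {
    N <- n1 + n2
    sums <- combn(N, n1, FUN = sum)
    mu <- n1 * (N + 1) / 2; sig <- sqrt(n1 * n2 * (N + 1) / 12)
    ws <- table(sums) / length(sums)
    w <- as.numeric(names(ws))
    pe <- vapply(w, function(v) mean(abs(sums - mu) >= abs(v - mu) - 1e-9), 0)
    pn <- pmin(1, 2 * pnorm(-abs((w - mu) / sig)))
    sum(ws * abs(pe - pn))
  }
  expect_lt(gap(8, 7), 0.05)
  expect_lt(gap(8, 7), gap(5, 4))
})

test_that("fisher exact: worked examples and enumeration oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 6, 6), 2)), 1)
  set.seed(53)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact_2x2(tab), enum_fisher_p(tab), tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("count test switches between chi-square and Fisher on expected counts", {
  big <- matrix(c(30, 26, 8, 5), 2)     # boy/girl style table, all expected >= 5
  expect_equal(group_count_test(t(big))$method, "chisq")
  expect_equal(group_count_test(t(big))$p,
               stats::chisq.test(t(big), correct = FALSE)$p.value)
  small <- matrix(c(3, 0, 53, 13), 2)   # sparse complication table
  got <- group_count_test(small)
  expect_equal(got$method, "fisher")
  expect_equal(got$p, fisher_exact_2x2(small))
})

test_that("pearson correlation: affine limits and the hand-computed example", {
  x <- c(0.5, 1.5, 4, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(1:4, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:4, 1:3), "equal length")
})

test_that("ROC: separable toys, concordance oracle, and transform invariance", {
  r <- roc_analysis(c(10, 20, 30, 40), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$best_cutoff, 30)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  set.seed(54)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(c(1, 8), 1))   # some runs with ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, concordance_auc(scores, labels), tolerance = 1e-12)
    # strictly increasing transform leaves the curve untouched
    r2 <- roc_analysis(exp(scores), labels)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
    expect_equal(r2$tpr, r$tpr)
    expect_equal(r2$fpr, r$fpr)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- c(rnorm(30, 1), rnorm(40))
  labels <- rep(c(1, 0), c(30, 40))
  r <- roc_analysis(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_best <- pROC::coords(ref, "best", best.method = "youden",
                           transpose = FALSE)
  expect_equal(r$sensitivity, ref_best$sensitivity, tolerance = 1e-9)
  expect_equal(r$specificity, ref_best$specificity, tolerance = 1e-9)
})
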