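# Clinical statistics harness: two-group nonparametric comparison, 2x2
# categorical tests, bivariate correlation, and ROC analysis with
# Youden-index cutoff selection.

#' Wilcoxon rank-sum test (normal approximation, optional exact enumeration)
#'
#' Mid-ranks with tie correction; the standardised statistic is
#' `Z = (W - mu_W) / sigma_W` without continuity correction, where `W` is
#' the rank sum of `x`, and the two-sided p-value comes from the normal
#' approximation.  When the combined sample size is at most 12 and there are
#' no ties, an exact two-sided p-value is also computed by full enumeration
#' of all rank assignments.
#'
#' @param x,y numeric samples (each nonempty).
#' @return list with `Z`, `p` (normal approximation), `W` (rank sum of `x`),
#'   and `p_exact` (`NA` unless the exact enumeration applies).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_exact  # 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be nonempty", call. = FALSE)
  if (!all(is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y), ties.method = "average")
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  Z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  p <- 2 * pnorm(-abs(Z))
  p_exact <- NA_real_
  if (N <= 12L && !any(duplicated(c(x, y)))) {
    sums <- utils::combn(N, n1, FUN = sum)
    p_exact <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  }
  list(Z = Z, p = min(p, 1), W = W, p_exact = p_exact)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum, over all tables with the observed margins,
#' of hypergeometric probabilities no larger than the observed table's
#' probability (with a small relative tolerance for round-off).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  lo <- max(0L, kk - n); hi <- min(kk, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, kk)
  p_obs <- dhyper(tab[1, 1], m, n, kk)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("`tab` must be a 2x2 matrix", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("`tab` must contain nonnegative integer counts", call. = FALSE)
  }
  storage.mode(tab) <- "double"
  tab
}

#' Two-group count comparison (chi-square or Fisher)
#'
#' Pearson chi-square without continuity correction when every expected cell
#' count is at least 5, Fisher's exact test otherwise -- the usual
#' small-sample switch for 2x2 clinical tables.
#'
#' @param tab 2x2 matrix of counts.
#' @return list with `method` (`"chisq"` or `"fisher"`), `p`, and
#'   `statistic` (chi-square statistic, `NA` for Fisher).
#' @export
group_count_test <- function(tab) {
  tab <- check_2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- chisq.test(tab, correct = FALSE)
    list(method = "chisq", p = ct$p.value, statistic = unname(ct$statistic))
  } else {
    list(method = "fisher", p = fisher_exact_2x2(tab), statistic = NA_real_)
  }
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined: a sample has zero variance", call. = FALSE)
  }
  cor(x, y)
}

#' ROC analysis with Youden-index cutoff
#'
#' Empirical ROC over all distinct score thresholds (a subject is called
#' positive when `score >= threshold`), AUC by the trapezoid rule, and the
#' best cutoff maximising the Youden index `J = sensitivity + specificity
#' - 1`, ties broken toward higher specificity.
#'
#' @param scores numeric vector of biomarker values.
#' @param labels logical or 0/1 vector; `TRUE`/1 = positive class (PDA).
#' @return object of class `roc_result`: list with `thresholds` (descending,
#'   beginning with `Inf`), `tpr`, `fpr`, `auc`, `best_cutoff`,
#'   `sensitivity`, `specificity`, and `youden`.
#' @export
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$best_cutoff  # 3
roc_analysis <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("`labels` must be logical or 0/1", call. = FALSE)
  if (length(scores) != length(labels)) stop("`scores` and `labels` lengths differ", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg, 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  finite <- is.finite(thr)
  best_j <- max(j[finite])
  cand <- which(finite & j >= best_j - 1e-12)
  best <- cand[which.min(fpr[cand])]   # tie toward higher specificity
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 best_cutoff = thr[best], sensitivity = tpr[best],
                 specificity = 1 - fpr[best], youden = j[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<ROC: AUC %.3f; cutoff %.4g (sens %.1f%%, spec %.1f%%)>\n",
              x$auc, x$best_cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Serialize an ROC result to JSON
#'
#' @param x a `roc_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roc_json <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing JSON requires the 'jsonlite' package", call. = FALSE)
  }
  jsonlite::write_json(unclass(x), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
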