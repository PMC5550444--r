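# Evaluation statistics for variant scores: ROC/AUC, threshold
# sensitivity/specificity, Mann-Whitney comparisons, score-binned allele
# frequency correlation, non-parametric QQ comparison, and gene-list
# enrichment.

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score as a threshold (ties grouped into a single
#' step) and integrates the curve by the trapezoid rule; equal-scored
#' pairs therefore contribute 1/2, so the AUC equals the Mann-Whitney U
#' statistic normalized by `n1 * n0`.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector (1 = positive class), parallel to `scores`.
#' @return A list of class `roc_result`: `thresholds`, `tpr`, `fpr`
#'   (monotone along the sweep) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need both classes to compute a ROC")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), 0L)
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), 0L)
  tpr <- c(0, tp / np, 1)
  fpr <- c(0, fp / nn, 1)
  thresholds <- c(Inf, thr, -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' Sensitivity and specificity at a score threshold
#'
#' Scores `>= threshold` are called positive.
#'
#' @inheritParams roc_auc
#' @param threshold Numeric scalar.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec_at <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1L)
  fn <- sum(!call_pos & labels == 1L)
  tn <- sum(!call_pos & labels == 0L)
  fp <- sum(call_pos & labels == 0L)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Mann-Whitney U test between two score sets
#'
#' Exact enumeration when both groups have n <= 8 and there are no ties;
#' otherwise the normal approximation with tie correction (and continuity
#' correction), as in [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors.
#' @return List with `U` (the U statistic of `a` vs `b`) and `p`
#'   (two-sided).
#' @export
mann_whitney <- function(a, b) {
  exact <- length(a) <= 8L && length(b) <= 8L &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Correlation between binned scores and mean allele frequency
#'
#' Bins the scores into `n_bins` equal-count (5% quantile) intervals,
#' computes each bin's mean score and mean MAF, and reports the Pearson
#' correlation (with parametric p) over the bin points.  Duplicate
#' quantile breaks (heavily tied score distributions) merge the affected
#' bins, with a message.
#'
#' @param scores Numeric vector.
#' @param maf Minor allele frequencies, parallel to `scores`.
#' @param n_bins Number of score bins (default 20, i.e. 5% intervals).
#' @return List with `r`, `p` and `bins` (data.frame of per-bin n,
#'   mean_score, mean_maf).
#' @export
binned_maf_correlation <- function(scores, maf, n_bins = 20L) {
  stopifnot(length(scores) == length(maf))
  if (length(unique(scores)) < n_bins)
    stop("need at least n_bins distinct scores")
  breaks <- stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1))
  ub <- unique(breaks)
  if (length(ub) < length(breaks))
    message("tied score quantiles: ", length(breaks) - length(ub),
            " bin(s) merged with a neighbor")
  bin <- cut(scores, breaks = ub, include.lowest = TRUE)
  tab <- data.frame(
    n = as.integer(table(bin)),
    mean_score = as.numeric(tapply(scores, bin, mean)),
    mean_maf = as.numeric(tapply(maf, bin, mean)))
  ct <- stats::cor.test(tab$mean_score, tab$mean_maf, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, bins = tab)
}

#' Non-parametric quantile-quantile comparison
#'
#' Sorts the smaller set and linearly interpolates the order statistics of
#' the larger set at matching plotting positions, so the two vectors have
#' equal length.  Comparing a set against itself returns the identity line
#' exactly.
#'
#' @param small,large Numeric vectors (`small` is the smaller set; they
#'   are swapped internally if not).
#' @return Data.frame with columns `quantile_small` and `quantile_large`.
#' @export
qq_compare <- function(small, large) {
  if (length(small) > length(large)) {
    tmp <- small; small <- large; large <- tmp
  }
  s <- sort(small)
  l <- sort(large)
  n <- length(s)
  if (n < 1L) stop("empty score set")
  xout <- seq(1, length(l), length.out = n)
  ql <- if (length(l) == 1L) rep(l, n)
        else stats::approx(seq_along(l), l, xout = xout)$y
  data.frame(quantile_small = s, quantile_large = ql)
}

#' One-sided gene-list enrichment (Fisher's exact test)
#'
#' Tests over-representation of hits in a gene list of size `n_list`
#' against a background rate of `K_background_hits` out of
#' `N_background` genes, via the one-sided Fisher's exact test on the
#' 2x2 table `(k, n-k | K, N-K)`.  The background column is the full
#' reference set (the list is negligibly small against it), equivalent to
#' the hypergeometric upper tail on that table's margins.
#'
#' @param k_hits Hits in the list.
#' @param n_list List size.
#' @param K_background_hits Hits in the background set.
#' @param N_background Background set size.
#' @return One-sided p-value, P(X >= k).
#' @export
fisher_enrichment <- function(k_hits, n_list, K_background_hits,
                              N_background) {
  stopifnot(k_hits <= n_list, K_background_hits <= N_background,
            n_list <= N_background)
  tab <- matrix(c(k_hits, n_list - k_hits,
                  K_background_hits, N_background - K_background_hits),
                nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}
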