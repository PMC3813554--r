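#' Rank-based ROC AUC for one feature
#'
#' The area under the receiver-operating-characteristic curve computed by
#' the rank-sum identity: the fraction of (positive, negative) pairs where
#' the positive scores higher, with half credit for ties. Equals the
#' Mann-Whitney U statistic divided by `n1 * n2`.
#'
#' @param scores_pos feature values (or scores) of the positive class.
#' @param scores_neg feature values of the negative class.
#' @return AUC in \[0, 1\].
#' @export
feature_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (!n1 || !n2) abort_fmt("feature_auc: both classes must be non-empty")
  if (anyNA(scores_pos) || anyNA(scores_neg))
    abort_fmt("feature_auc: NA scores not allowed")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

mann_whitney_p <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
}

#' Screen features by Mann-Whitney U test and single-feature AUC
#'
#' Each feature is tested for class separation with a two-sided
#' Mann-Whitney U test (Bonferroni-corrected across the features actually
#' screened) and its single-feature AUC against the driver/passenger
#' labels. A feature passes when the corrected p-value is below `alpha` and
#' `|AUC - 0.5|` exceeds `auc_margin`. Features on the exclusion list
#' (e.g. descriptors prone to dataset-specific bias) are not screened and do
#' not contribute to the Bonferroni multiplier.
#'
#' @param table fully imputed [feature_table()].
#' @param labels driver/passenger labels (named by mutation id or aligned).
#' @param alpha family-wise significance level (default 0.05).
#' @param auc_margin required `|AUC - 0.5|` margin (default 0.05).
#' @param exclude feature names to leave out of screening.
#' @return `data.frame` with one row per screened feature: `feature`,
#'   `auc`, `u_pvalue`, `p_bonferroni`, `direction` (sign of `auc - 0.5`),
#'   `passed`.
#' @export
screen_features <- function(table, labels, alpha = 0.05, auc_margin = 0.05,
                            exclude = character()) {
  labels <- check_labels(table, labels)
  require_both_classes(labels)
  if (anyNA(table$values))
    abort_fmt("feature table contains missing values; impute first")
  feats <- setdiff(colnames(table$values), exclude)
  if (!length(feats)) abort_fmt("no features left to screen")
  m <- length(feats)
  pos <- labels == "driver"
  res <- lapply(feats, function(f) {
    x <- table$values[, f]
    auc <- feature_auc(x[pos], x[!pos])
    p <- mann_whitney_p(x[pos], x[!pos])
    data.frame(feature = f, auc = auc, u_pvalue = p,
               p_bonferroni = min(1, p * m),
               direction = sign(auc - 0.5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$passed <- out$p_bonferroni < alpha & abs(out$auc - 0.5) > auc_margin
  out
}
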