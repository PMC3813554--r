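#' ROC AUC and driver recall of a call table
#'
#' AUC is computed from the scores by the rank identity (the same
#' implementation as [feature_auc()]); recall is the number of true drivers
#' called `"driver"` over the total number of true drivers. With
#' single-class truth the AUC is undefined (`NA` with a warning) but the
#' recall is still returned.
#'
#' @param calls call `data.frame` as produced by [predict_calls()].
#' @param truth named driver/passenger vector, or `data.frame` with columns
#'   `mutation_id` and `label`.
#' @return list with `auc`, `recall` (fraction), `n_called` and `n_drivers`.
#' @export
roc_auc_and_recall <- function(calls, truth) {
  if (is.data.frame(truth)) {
    tr <- truth$label
    names(tr) <- truth$mutation_id
    truth <- tr
  }
  if (!all(calls$mutation_id %in% names(truth)))
    abort_fmt("truth labels missing for some calls")
  y <- truth[calls$mutation_id]
  bad <- setdiff(unique(y), c("driver", "passenger"))
  if (length(bad)) abort_fmt("truth labels must be driver/passenger")
  is_d <- y == "driver"
  auc <- if (all(is_d) || !any(is_d)) {
    warn_fmt("truth contains a single class; AUC undefined")
    NA_real_
  } else {
    feature_auc(calls$score[is_d], calls$score[!is_d])
  }
  n_drivers <- sum(is_d)
  n_called <- sum(is_d & calls$category == "driver")
  list(auc = auc,
       recall = if (n_drivers) n_called / n_drivers else NA_real_,
       n_called = n_called, n_drivers = n_drivers)
}

#' Pearson correlation between scores and mutation prevalence
#'
#' Mutation prevalence (the observed count of a mutation in a cancer type)
#' is a robust indicator of driver function; a more accurate score should
#' correlate with it more strongly.
#'
#' @param prevalence observed counts (>= 1), one per mutation.
#' @param scores matching numeric scores.
#' @return Pearson r in \[-1, 1\].
#' @export
prevalence_correlation <- function(prevalence, scores) {
  if (length(prevalence) != length(scores))
    abort_fmt("prevalence and scores must have equal length")
  if (length(prevalence) < 3)
    abort_fmt("at least 3 points required for a correlation")
  if (any(prevalence < 1)) abort_fmt("prevalence must be >= 1")
  if (stats::sd(prevalence) == 0 || stats::sd(scores) == 0)
    abort_fmt("correlation undefined: constant axis")
  stats::cor(prevalence, scores, method = "pearson")
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` predicted drivers among the `n`
#' rare mutations of a gene panel, when `K` of all `N` rare mutations are
#' predicted drivers: `p = sum_{j >= k} C(n, j) C(N - n, K - j) / C(N, K)`.
#' One-sided (enrichment direction).
#'
#' @param N total rare mutations considered.
#' @param K predicted drivers among them.
#' @param n rare mutations in the gene panel.
#' @param k predicted drivers in the panel.
#' @return upper-tail p-value.
#' @export
enrichment_pvalue <- function(N, K, n, k) {
  ok <- is_count(N) && is_count(K, 0) && is_count(n, 0) && is_count(k, 0)
  if (!ok || K > N || n > N || k > min(K, n))
    abort_fmt("invalid enrichment counts: need k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Mann-Whitney comparison of two score groups
#'
#' Used to test whether mutations from a cancer type score higher under the
#' matched model than under a mismatched one. Same U-test implementation as
#' the screening module.
#'
#' @param scores_a,scores_b non-empty numeric vectors.
#' @return two-sided p-value.
#' @export
compare_score_groups <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b))
    abort_fmt("both score groups must be non-empty")
  mann_whitney_p(scores_a, scores_b)
}

#' Identify rare (tail) mutations in a catalog
#'
#' Rare candidates are variants reported exactly once in the catalog with
#' no other mutation record within a small vicinity (default 3 bp on either
#' side), excluding any ids already used as training/test examples.
#'
#' @param catalog mutation catalog.
#' @param window_bp half-window in base pairs (default 3).
#' @param exclude mutation ids to drop (e.g. curated training examples).
#' @return character vector of mutation ids.
#' @export
find_rare_mutations <- function(catalog, window_bp = 3, exclude = character()) {
  mis <- which(catalog$mutation_class == "missense")
  if (!length(mis)) return(character())
  key <- variant_key(catalog$chrom[mis], catalog$pos[mis],
                     catalog$ref_allele[mis], catalog$alt_allele[mis])
  occ <- table(key)
  singleton <- as.vector(occ[key]) == 1L
  win <- count_within_window(catalog$chrom[mis], catalog$pos[mis],
                             catalog$chrom, catalog$pos, half = window_bp)
  ids <- catalog$mutation_id[mis][singleton & win == 1L]
  setdiff(ids, exclude)
}

#' Enrichment of predicted drivers in a gene panel
#'
#' Convenience wrapper assembling the hypergeometric counts from a call
#' table: `N` = all calls, `K` = driver calls, `n` = calls in panel genes,
#' `k` = driver calls in panel genes.
#'
#' @param calls call `data.frame` (see [predict_calls()]).
#' @param genes named character vector mapping `mutation_id` to gene symbol.
#' @param panel a [gene_list()] or character vector of panel gene symbols.
#' @return list with the four counts, the panel and background driver
#'   fractions, and `p_value`.
#' @export
panel_enrichment <- function(calls, genes, panel) {
  if (inherits(panel, "gene_list")) panel <- panel$genes
  panel <- toupper(panel)
  g <- toupper(genes[calls$mutation_id])
  if (anyNA(g)) abort_fmt("gene mapping missing for some calls")
  in_panel <- g %in% panel
  is_driver <- calls$category == "driver"
  N <- nrow(calls); K <- sum(is_driver)
  n <- sum(in_panel); k <- sum(in_panel & is_driver)
  list(N = N, K = K, n = n, k = k,
       panel_fraction = if (n) k / n else NA_real_,
       background_fraction = if (N) K / N else NA_real_,
       p_value = enrichment_pvalue(N, K, n, k))
}
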