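#' Cross-validation configuration
#'
#' Repeated stratified k-fold cross-validation settings used to evaluate
#' feature subsets. The defaults (10 folds, 5 repeats) reproduce the study
#' design; smaller settings are convenient for simulations.
#'
#' @param folds number of folds (>= 2).
#' @param repeats number of repetitions (>= 1).
#' @param seed integer seed; the entire fold layout (and hence every subset
#'   evaluation) is reproducible bit-for-bit under a fixed seed.
#' @return a `cv_config` list.
#' @export
cv_config <- function(folds = 10, repeats = 5, seed = 1L) {
  if (!is_count(folds, 2)) abort_fmt("folds must be an integer >= 2")
  if (!is_count(repeats)) abort_fmt("repeats must be a positive integer")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "cv_config")
}

# stratified fold assignments, one integer vector per repeat
make_folds <- function(labels, cv) {
  lapply(seq_len(cv$repeats), function(r) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(cv$folds), length(idx))
    }
    fold
  })
}

#' Mean cross-validated AUC of a feature subset
#'
#' Evaluates a feature subset by repeated stratified k-fold
#' cross-validation: within each fold the features are z-standardised using
#' the training split, a class-weighted SVM ([model_spec()]) is fitted, and
#' the held-out decision values are summarised by the rank-based AUC. The
#' result is the mean over `folds x repeats` fold-level AUCs and is
#' deterministic for a fixed `cv$seed`.
#'
#' @param table fully imputed [feature_table()].
#' @param labels driver/passenger labels.
#' @param features non-empty character vector of feature names.
#' @param cv a [cv_config()].
#' @param spec a [model_spec()].
#' @return mean AUC.
#' @export
cv_auc <- function(table, labels, features, cv = cv_config(),
                   spec = model_spec()) {
  labels <- check_labels(table, labels)
  require_both_classes(labels)
  if (!length(features)) abort_fmt("feature subset must be non-empty")
  missing <- setdiff(features, colnames(table$values))
  if (length(missing)) abort_fmt("unknown feature '%s'", missing[1])
  counts <- table(labels)
  if (any(counts < cv$folds))
    abort_fmt("class '%s' has %d mutations, fewer than %d folds; use fewer folds",
              names(counts)[which.min(counts)], min(counts), cv$folds)
  x <- table$values[, features, drop = FALSE]
  if (anyNA(x)) abort_fmt("features contain missing values; impute first")

  folds <- withr::with_seed(cv$seed, make_folds(labels, cv))
  aucs <- numeric(0)
  for (fold in folds) {
    for (k in seq_len(cv$folds)) {
      tr <- fold != k; te <- !tr
      st <- standardize_fit(x[tr, , drop = FALSE])
      fit <- fit_weighted_svm(standardize_apply(x[tr, , drop = FALSE], st),
                              labels[tr], spec)
      s <- svm_scores(fit, standardize_apply(x[te, , drop = FALSE], st))
      yte <- labels[te]
      aucs <- c(aucs, feature_auc(s[yte == "driver"], s[yte == "passenger"]))
    }
  }
  mean(aucs)
}

subset_label <- function(features) paste(features, collapse = "+")

#' Exhaustive search over feature subsets of size at most three
#'
#' Evaluates every subset of 1, 2 or 3 screened features by [cv_auc()] and
#' returns the best ("core") set. Ties favour the smaller subset, then the
#' lexicographically earlier one.
#'
#' @inheritParams cv_auc
#' @param features screened feature names.
#' @param max_size largest subset size enumerated (default 3).
#' @return list with `core_set`, `cv_auc`, and `evaluated` (a `data.frame`
#'   of every subset and its AUC, in evaluation order).
#' @export
enumerate_core <- function(table, labels, features, cv = cv_config(),
                           spec = model_spec(), max_size = 3) {
  if (!length(features)) abort_fmt("no screened features to enumerate")
  features <- sort(features)
  best <- NULL; best_auc <- -Inf
  rows <- list()
  for (size in seq_len(min(max_size, length(features)))) {
    combos <- utils::combn(length(features), size)
    for (j in seq_len(ncol(combos))) {
      sub <- features[combos[, j]]
      a <- cv_auc(table, labels, sub, cv, spec)
      rows[[length(rows) + 1L]] <- data.frame(subset = subset_label(sub),
                                              size = size, cv_auc = a,
                                              stringsAsFactors = FALSE)
      if (a > best_auc) { best <- sub; best_auc <- a }
    }
  }
  list(core_set = best, cv_auc = best_auc,
       evaluated = do.call(rbind, rows))
}

#' Hill-climbing expansion of the core feature set
#'
#' Starting from the core set, iteratively adds the single remaining
#' feature that maximises the cross-validated AUC of the augmented set
#' (ties break to the lexicographically earlier name), until every
#' remaining feature has been added. The full path is recorded; the optimal
#' set is the shortest path prefix attaining the maximum AUC.
#'
#' @inheritParams cv_auc
#' @param core_set core features from [enumerate_core()].
#' @param remaining screened features not in the core (may be empty).
#' @return a `selection_trace`: list with `core_set`, `path` (`data.frame`
#'   of `feature`, `cv_auc`, `n_features` -- one row per prefix),
#'   `optimal_set` and `optimal_cv_auc`.
#' @export
hill_climb <- function(table, labels, core_set, remaining,
                       cv = cv_config(), spec = model_spec()) {
  if (length(intersect(core_set, remaining)))
    abort_fmt("core set and remaining features must be disjoint")
  core_set <- sort(core_set)
  path_feat <- character(); path_auc <- numeric()
  for (i in seq_along(core_set)) {     # core prefixes open the trace
    path_feat <- c(path_feat, core_set[i])
    path_auc <- c(path_auc, cv_auc(table, labels, core_set[seq_len(i)],
                                   cv, spec))
  }
  current <- core_set
  remaining <- sort(remaining)
  while (length(remaining)) {
    cand_auc <- vapply(remaining, function(f)
      cv_auc(table, labels, c(current, f), cv, spec), numeric(1))
    pick <- remaining[which.max(cand_auc)]  # first max = lexicographic tie-break
    current <- c(current, pick)
    path_feat <- c(path_feat, pick)
    path_auc <- c(path_auc, max(cand_auc))
    remaining <- setdiff(remaining, pick)
  }
  opt <- which.max(path_auc)               # first max = shortest prefix
  structure(list(
    core_set = core_set,
    path = data.frame(feature = path_feat, cv_auc = path_auc,
                      n_features = seq_along(path_feat),
                      stringsAsFactors = FALSE),
    optimal_set = path_feat[seq_len(opt)],
    optimal_cv_auc = path_auc[opt]
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: core {%s}; optimal %d features, CV AUC %.4f\n",
              subset_label(x$core_set), length(x$optimal_set),
              x$optimal_cv_auc))
  invisible(x)
}

#' Full feature-selection pipeline: screen, enumerate, hill-climb
#'
#' Screens all features ([screen_features()]), enumerates subsets of up to
#' three passing features ([enumerate_core()]) and expands the best subset
#' by hill-climbing over the remaining passing features ([hill_climb()]).
#'
#' @inheritParams screen_features
#' @inheritParams cv_auc
#' @param max_core_size largest subset size in the enumeration step.
#' @return list with `screen` (the screening table) and `trace` (the
#'   [hill_climb()] selection trace).
#' @export
select_features <- function(table, labels, cv = cv_config(),
                            spec = model_spec(), alpha = 0.05,
                            auc_margin = 0.05, exclude = character(),
                            max_core_size = 3) {
  scr <- screen_features(table, labels, alpha, auc_margin, exclude)
  passed <- scr$feature[scr$passed]
  if (!length(passed))
    abort_fmt("no features passed screening (alpha=%g, margin=%g)",
              alpha, auc_margin)
  core <- enumerate_core(table, labels, passed, cv, spec, max_core_size)
  trace <- hill_climb(table, labels, core$core_set,
                      setdiff(passed, core$core_set), cv, spec)
  list(screen = scr, trace = trace)
}
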