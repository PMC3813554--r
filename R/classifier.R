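#' Classifier specification
#'
#' A class-weighted support vector machine handles the strong
#' driver/passenger imbalance of the expanded training sets. The per-class
#' weight is the inverse class frequency normalised to mean one,
#' `w_c = N / (2 * N_c)`, so the rarer class (usually drivers) gets the
#' proportionally larger misclassification penalty.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C regularisation cost (default 1).
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @param seed integer seed stored with the model for provenance (the SVM
#'   fit itself is deterministic).
#' @return a `model_spec` list.
#' @export
model_spec <- function(kernel = c("rbf", "linear"), C = 1, gamma = NULL,
                       seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.numeric(C) || C <= 0) abort_fmt("C must be positive")
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 seed = as.integer(seed)), class = "model_spec")
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (2 * N_c)` for each class; balanced classes give equal
#' unit weights, and the weight ratio between classes equals the inverse
#' ratio of their counts.
#'
#' @param labels driver/passenger label vector, or a named count vector.
#' @return named numeric weight vector.
#' @export
class_weights <- function(labels) {
  counts <- if (is.numeric(labels)) labels else table(labels)
  if (length(counts) != 2) abort_fmt("exactly two classes required")
  w <- sum(counts) / (2 * counts)
  v <- as.numeric(w)
  names(v) <- names(w)
  v
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = ctr, scale = sdv)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

# Fit a class-weighted SVM and record the orientation of its decision
# values. e1071 reports decision values in a column named "A/B" where
# positive values favour class A; we store a sign so that higher scores are
# always driver-like.
fit_weighted_svm <- function(x, y, spec) {
  y <- factor(as.character(y), levels = c("driver", "passenger"))
  w <- class_weights(y)
  fit <- e1071::svm(
    x = x, y = y,
    kernel = if (spec$kernel == "rbf") "radial" else "linear",
    cost = spec$C,
    gamma = spec$gamma %||% (1 / ncol(x)),
    scale = FALSE, class.weights = w, probability = FALSE
  )
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  list(fit = fit, orient = if (first == "driver") 1 else -1)
}

svm_scores <- function(fitobj, x) {
  dv <- attr(stats::predict(fitobj$fit, x, decision.values = TRUE),
             "decision.values")
  out <- fitobj$orient * as.numeric(dv[, 1])
  names(out) <- rownames(x)
  out
}

#' Train the class-weighted SVM driver model
#'
#' Standardises the selected features (mean/SD learned on the training
#' table and stored with the model), fits the weighted SVM, scores the
#' training mutations and records the empirical score distributions per
#' class together with the two calling thresholds: the 90th percentile of
#' training passenger scores (above which a mutation is called a driver)
#' and the 10th percentile of training driver scores (below which it is
#' called a passenger). Percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param table fully imputed [feature_table()].
#' @param labels driver/passenger labels.
#' @param selected_features feature names to use.
#' @param spec a [model_spec()].
#' @return a `driver_model` object.
#' @export
train_model <- function(table, labels, selected_features,
                        spec = model_spec()) {
  labels <- check_labels(table, labels)
  require_both_classes(labels)
  missing <- setdiff(selected_features, colnames(table$values))
  if (length(missing)) abort_fmt("selected feature '%s' not in table", missing[1])
  x <- table$values[, selected_features, drop = FALSE]
  if (anyNA(x)) abort_fmt("features contain missing values; impute first")
  st <- standardize_fit(x)
  fitobj <- fit_weighted_svm(standardize_apply(x, st), labels, spec)
  scores <- svm_scores(fitobj, standardize_apply(x, st))
  drv <- sort(unname(scores[labels == "driver"]))
  pas <- sort(unname(scores[labels == "passenger"]))
  structure(list(
    spec = spec,
    selected_features = selected_features,
    fit = fitobj$fit,
    orient = fitobj$orient,
    standardization = st,
    class_weights = class_weights(labels),
    q90_passenger = unname(stats::quantile(pas, 0.90, type = 7)),
    q10_driver = unname(stats::quantile(drv, 0.10, type = 7)),
    train_scores = list(driver = drv, passenger = pas)
  ), class = "driver_model")
}

#' @export
print.driver_model <- function(x, ...) {
  cat(sprintf(paste0("driver_model: %s SVM, %d features, %d drivers / %d",
                     " passengers\n  thresholds: driver > %.4f, passenger < %.4f\n"),
              x$spec$kernel, length(x$selected_features),
              length(x$train_scores$driver), length(x$train_scores$passenger),
              x$q90_passenger, x$q10_driver))
  invisible(x)
}

#' Score mutations with a trained model
#'
#' Applies the stored standardisation and returns signed SVM decision
#' values (higher = more driver-like). Columns not among the selected
#' features are ignored.
#'
#' @param model a `driver_model`.
#' @param table a [feature_table()] containing all selected features.
#' @return named numeric score vector.
#' @export
score_mutations <- function(model, table) {
  missing <- setdiff(model$selected_features, colnames(table$values))
  if (length(missing))
    abort_fmt("feature '%s' required by the model is absent", missing[1])
  x <- table$values[, model$selected_features, drop = FALSE]
  if (anyNA(x)) abort_fmt("features contain missing values; impute first")
  svm_scores(list(fit = model$fit, orient = model$orient),
             standardize_apply(x, model$standardization))
}

#' Three-way category from a score
#'
#' A mutation is a `"driver"` if its score is strictly greater than the
#' 90th percentile of the training passengers' scores, a `"passenger"` if
#' strictly less than the 10th percentile of the training drivers' scores,
#' and a `"no-call"` otherwise. The driver test takes precedence; if both
#' tests fire simultaneously (possible when the two thresholds cross) a
#' warning is emitted because the class score ranges are then disjoint in
#' an unexpected direction.
#'
#' @param model a `driver_model`.
#' @param scores numeric score vector.
#' @return character vector of categories.
#' @export
categorize <- function(model, scores) {
  is_drv <- scores > model$q90_passenger
  is_pas <- scores < model$q10_driver
  if (any(is_drv & is_pas))
    warn_fmt("%d score(s) satisfy both the driver and passenger rules; driver takes precedence",
             sum(is_drv & is_pas))
  out <- ifelse(is_drv, "driver", ifelse(is_pas, "passenger", "no-call"))
  names(out) <- names(scores)
  out
}

#' Empirical tail fraction of a training score list
#'
#' The fraction of training scores strictly more extreme than the query:
#' strictly greater for the upper tail (drivers), strictly lower for the
#' lower tail (passengers). Ties count as not more extreme.
#'
#' @param train_scores numeric vector of same-class training scores.
#' @param score query score (vectorised).
#' @param tail `"upper"` or `"lower"`.
#' @return numeric vector in \[0, 1\].
#' @export
empirical_confidence <- function(train_scores, score,
                                 tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  vapply(score, function(s) {
    if (tail == "upper") mean(train_scores > s) else mean(train_scores < s)
  }, numeric(1))
}

#' Confidence of driver/passenger calls
#'
#' The empirical class-wise tail probability: for a driver call, the
#' fraction of training drivers with strictly greater score; for a
#' passenger call, the fraction of training passengers with strictly lower
#' score. No-calls get `NA`.
#'
#' @param model a `driver_model`.
#' @param scores numeric score vector.
#' @param categories categories from [categorize()].
#' @return numeric vector (NA for no-calls).
#' @export
confidence_score <- function(model, scores, categories) {
  out <- rep(NA_real_, length(scores))
  d <- categories == "driver"
  p <- categories == "passenger"
  out[d] <- empirical_confidence(model$train_scores$driver, scores[d], "upper")
  out[p] <- empirical_confidence(model$train_scores$passenger, scores[p], "lower")
  names(out) <- names(scores)
  out
}

#' Score, categorise and attach confidences in one step
#'
#' @param model a `driver_model`.
#' @param table a [feature_table()].
#' @return `data.frame` with columns `mutation_id`, `score`, `category`,
#'   `confidence`.
#' @export
predict_calls <- function(model, table) {
  s <- score_mutations(model, table)
  cat_ <- categorize(model, s)
  conf <- confidence_score(model, s, cat_)
  data.frame(mutation_id = rownames(table$values),
             score = unname(s), category = unname(cat_),
             confidence = unname(conf), stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' The serialised model contains the selected features, standardisation,
#' calling thresholds, sorted per-class training scores and the seed, so
#' scoring, categories and confidences are reproducible without retraining.
#'
#' @param model a `driver_model`.
#' @param path file path (RDS).
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "driver_model")) abort_fmt("'%s' is not a driver model", path)
  m
}
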