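#' Mutation-by-feature table
#'
#' A feature table holds the numeric matrix of precomputed per-mutation
#' descriptors (rows = mutation ids, columns = features). Missing cells are
#' `NA`; each feature is declared `continuous` or `binary`. Binary features
#' must take values in \{0, 1\} where observed.
#'
#' @param values numeric matrix with mutation ids as rownames and feature
#'   names as colnames.
#' @param kinds named character vector (`"continuous"` / `"binary"`), one
#'   entry per feature; inferred when omitted (a feature whose observed
#'   values are all 0/1 is binary).
#' @return a `feature_table` object.
#' @export
feature_table <- function(values, kinds = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_fmt("feature table matrix must have mutation-id rownames and feature colnames")
  storage.mode(values) <- "double"
  if (is.null(kinds)) {
    kinds <- vapply(colnames(values), function(f) {
      v <- values[, f]; v <- v[!is.na(v)]
      if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  } else {
    kinds <- kinds[colnames(values)]
    if (anyNA(kinds))
      abort_fmt("feature kinds missing for some features")
    bad <- setdiff(unique(kinds), c("continuous", "binary"))
    if (length(bad)) abort_fmt("unknown feature kind '%s'", bad[1])
  }
  for (f in names(kinds)[kinds == "binary"]) {
    v <- values[, f]; v <- v[!is.na(v)]
    if (length(v) && !all(v %in% c(0, 1)))
      abort_fmt("binary feature '%s' has observed values outside {0,1}", f)
  }
  structure(list(values = values, kinds = kinds), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d mutations x %d features (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read / write a feature table
#'
#' TSV format: first column `mutation_id`, remaining columns features; empty
#' string or `NA` denotes a missing cell. Feature kinds may be declared in a
#' sidecar YAML file (feature name -> `continuous`/`binary`); otherwise they
#' are inferred from the observed values.
#'
#' @param path TSV file.
#' @param kinds_path optional sidecar YAML path.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, kinds_path = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!ncol(raw) >= 2) abort_fmt("feature table '%s' needs >= 2 columns", path)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  kinds <- NULL
  if (!is.null(kinds_path)) {
    kl <- yaml::read_yaml(kinds_path)
    kinds <- unlist(kl)
  }
  feature_table(m, kinds)
}

#' @rdname read_feature_table
#' @param table a `feature_table`.
#' @export
write_feature_table <- function(table, path, kinds_path = NULL) {
  df <- data.frame(mutation_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(kinds_path))
    yaml::write_yaml(as.list(table$kinds), kinds_path)
  invisible(path)
}

#' Fraction of missing cells
#'
#' @param table a [feature_table()].
#' @return list with `overall` (missing cells / cells) and `per_feature`
#'   (named vector).
#' @export
missing_fraction <- function(table) {
  miss <- is.na(table$values)
  list(overall = mean(miss), per_feature = colMeans(miss))
}

central_value <- function(v, kind) {
  if (kind == "binary") {
    p <- mean(v)
    # mode; an exact 0/1 tie resolves to 0 (no annotation)
    if (p > 0.5) 1 else 0
  } else {
    stats::median(v)
  }
}

#' Impute missing feature values by k-nearest neighbours within gene
#'
#' For each missing cell, the donors are the mutations of the same gene with
#' that feature observed; the `k` nearest by genomic distance (base pairs,
#' ties broken by lower position then lexicographic mutation id) contribute
#' their values, aggregated by the median for continuous features and the
#' mode for binary features (a 0/1 tie resolves to 0). When no same-gene
#' donor exists -- including mutations absent from the catalog, for which a
#' warning is emitted -- the table-wide central value of the feature is used.
#' Observed cells are never changed, so imputation is idempotent.
#'
#' @param table a [feature_table()].
#' @param catalog mutation catalog resolving each mutation id to (gene, pos).
#' @param k number of neighbours (default 5).
#' @return a fully-observed `feature_table`.
#' @export
impute_features <- function(table, catalog, k = 5) {
  if (!is_count(k)) abort_fmt("k must be a positive integer")
  vals <- table$values
  ids <- rownames(vals)
  m <- match(ids, catalog$mutation_id)
  gene <- catalog$gene[m]
  pos <- catalog$pos[m]
  if (anyNA(m))
    warn_fmt("%d mutation id(s) absent from catalog; table-wide fallback used (e.g. '%s')",
             sum(is.na(m)), ids[is.na(m)][1])
  for (j in seq_len(ncol(vals))) {
    miss <- which(is.na(vals[, j]))
    if (!length(miss)) next
    obs <- which(!is.na(vals[, j]))
    if (!length(obs))
      abort_fmt("feature '%s' is missing for all mutations; cannot impute",
                colnames(vals)[j])
    kind <- table$kinds[j]
    global <- central_value(vals[obs, j], kind)
    for (i in miss) {
      if (is.na(gene[i])) { vals[i, j] <- global; next }
      donors <- obs[!is.na(gene[obs]) & gene[obs] == gene[i]]
      if (!length(donors)) { vals[i, j] <- global; next }
      ord <- order(abs(pos[donors] - pos[i]), pos[donors], ids[donors])
      nn <- donors[ord][seq_len(min(k, length(donors)))]
      vals[i, j] <- central_value(vals[nn, j], kind)
    }
  }
  feature_table(vals, table$kinds)
}
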