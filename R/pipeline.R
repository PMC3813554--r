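#' Run configuration for the end-to-end pipeline
#'
#' A run configuration is a plain list (or a YAML file with the same keys)
#' holding file paths and per-stage parameters. Recognised keys:
#' \describe{
#'   \item{out_dir}{output directory (required).}
#'   \item{catalog, features, feature_kinds}{input paths (required).}
#'   \item{labels}{optional TSV (`mutation_id`, `label`); when absent,
#'     labels are derived by curating the catalog (expanded sets).}
#'   \item{cancer_type, blacklist, cancer_genes, curation}{curation inputs
#'     used when `labels` is absent.}
#'   \item{impute_k}{neighbours for imputation (default 5).}
#'   \item{alpha, auc_margin, exclude_features}{screening parameters.}
#'   \item{folds, repeats}{cross-validation settings (defaults 10, 5).}
#'   \item{kernel, C}{classifier settings.}
#'   \item{seed}{single integer propagated to every stochastic stage.}
#' }
#'
#' @param config list or path to a YAML file.
#' @return validated config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("out_dir", "catalog", "features"))
    if (is.null(config[[key]])) abort_fmt("run config: missing '%s'", key)
  for (key in c("catalog", "features", "feature_kinds", "labels",
                "blacklist", "cancer_genes")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      abort_fmt("run config: input file not found: %s", p)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full annotation pipeline
#'
#' Executes, in order: read inputs, derive labels (from a truth file or by
#' catalog curation), impute the feature table, select features under
#' cross-validated AUC, train the class-weighted SVM, score and categorise
#' every mutation in the table, and write `calls.tsv`, `screen.tsv`,
#' `selection_trace.tsv`, `model.rds`, `summary.json` and `manifest.yaml`
#' into the output directory. Every stochastic stage is seeded from
#' `config$seed`, so two runs with the same configuration produce
#' byte-identical call tables.
#'
#' @param config a [run_config()] list or YAML path.
#' @return (invisibly) list with the trained model, calls, selection trace
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_log("read", "catalog %s", config$catalog)
  catalog <- read_catalog(config$catalog)
  table <- read_feature_table(config$features, config$feature_kinds)
  stage_log("read", "%d mutations x %d features", nrow(table$values),
            ncol(table$values))

  if (!is.null(config$labels)) {
    tr <- utils::read.delim(config$labels, stringsAsFactors = FALSE)
    labels <- tr$label
    names(labels) <- tr$mutation_id
    stage_log("labels", "%d labelled mutations from %s",
              length(labels), config$labels)
  } else {
    if (is.null(config$cancer_type))
      abort_fmt("run config: need 'labels' or 'cancer_type' for curation")
    bl <- if (!is.null(config$blacklist)) read_blacklist(config$blacklist)
          else site_blacklist()
    cg <- if (!is.null(config$cancer_genes))
            read_gene_list(config$cancer_genes, "cancer_genes")
          else gene_list()
    cur_cfg <- do.call(curation_config, config$curation %||% list())
    sets <- curate_training_sets(catalog, config$cancer_type, bl, cg, cur_cfg)
    labels <- c(stats::setNames(rep("driver", length(sets$expanded$drivers)),
                                sets$expanded$drivers),
                stats::setNames(rep("passenger",
                                    length(sets$expanded$passengers)),
                                sets$expanded$passengers))
    labels <- labels[names(labels) %in% rownames(table$values)]
    stage_log("curate", "expanded set: %d drivers, %d passengers",
              sum(labels == "driver"), sum(labels == "passenger"))
  }

  stage_log("impute", "missing fraction %.3f", missing_fraction(table)$overall)
  table <- impute_features(table, catalog, k = config$impute_k %||% 5)

  train_ids <- intersect(rownames(table$values), names(labels))
  if (!length(train_ids)) abort_fmt("no labelled mutations present in the table")
  train_tab <- feature_table(table$values[train_ids, , drop = FALSE],
                             table$kinds)
  train_lab <- labels[train_ids]

  cv <- cv_config(folds = config$folds %||% 10,
                  repeats = config$repeats %||% 5, seed = config$seed)
  spec <- model_spec(kernel = config$kernel %||% "rbf",
                     C = config$C %||% 1, seed = config$seed)
  stage_log("select", "screening %d features (folds=%d, repeats=%d)",
            ncol(table$values), cv$folds, cv$repeats)
  sel <- select_features(train_tab, train_lab, cv, spec,
                         alpha = config$alpha %||% 0.05,
                         auc_margin = config$auc_margin %||% 0.05,
                         exclude = config$exclude_features %||% character())
  stage_log("select", "optimal set: %d features, CV AUC %.4f",
            length(sel$trace$optimal_set), sel$trace$optimal_cv_auc)

  model <- train_model(train_tab, train_lab, sel$trace$optimal_set, spec)
  calls <- predict_calls(model, table)

  paths <- list(calls = file.path(config$out_dir, "calls.tsv"),
                screen = file.path(config$out_dir, "screen.tsv"),
                trace = file.path(config$out_dir, "selection_trace.tsv"),
                model = file.path(config$out_dir, "model.rds"),
                summary = file.path(config$out_dir, "summary.json"),
                manifest = file.path(config$out_dir, "manifest.yaml"))
  write_calls(calls, paths$calls)
  utils::write.table(sel$screen, paths$screen, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sel$trace$path, paths$trace, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_model(model, paths$model)

  summary <- list(n_mutations = nrow(calls),
                  n_driver_calls = sum(calls$category == "driver"),
                  n_no_calls = sum(calls$category == "no-call"),
                  n_passenger_calls = sum(calls$category == "passenger"),
                  optimal_features = sel$trace$optimal_set,
                  optimal_cv_auc = sel$trace$optimal_cv_auc)
  if (!is.null(config$labels)) {
    ev <- roc_auc_and_recall(calls[calls$mutation_id %in% train_ids, ],
                             labels)
    summary$training_auc <- ev$auc
    summary$training_recall <- ev$recall
  }
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "somaticdriver",
    version = as.character(utils::packageVersion("somaticdriver")),
    seed = config$seed,
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("catalog", "features", "feature_kinds", "labels",
                      "blacklist", "cancer_genes")]),
      function(p) unname(tools::md5sum(p))),
    config = config[setdiff(names(config), "out_dir")]
  )
  yaml::write_yaml(manifest, paths$manifest)
  stage_log("done", "%d calls written to %s", nrow(calls), paths$calls)

  invisible(list(model = model, calls = calls, selection = sel,
                 paths = paths, summary = summary))
}
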