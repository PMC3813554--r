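#' Specification of a synthetic study fixture
#'
#' Describes a labelled feature table (two-class Gaussian/Bernoulli model)
#' and a companion mutation catalog with injected recurrence structure, so
#' every pipeline stage can be exercised with known ground truth.
#'
#' Continuous informative features are drawn `Normal(effect_size, 1)` for
#' drivers vs `Normal(0, 1)` for passengers; noise features are standard
#' normal in both classes. Binary informative features are
#' `Bernoulli(0.5 + bernoulli_shift)` for drivers vs `Bernoulli(0.5)`.
#' Missing cells are masked completely at random at `missing_rate`
#' (`missing_mode = "mcar"`), or concentrated in a random block of ~30% of
#' the features (`"block"`), emulating portal-wise dropout.
#'
#' @param n_drivers,n_passengers class sizes of the feature table.
#' @param n_features total features.
#' @param n_informative number of class-separated features (the first
#'   `n_informative` columns).
#' @param effect_size mean shift (in SD units) of informative continuous
#'   features for drivers.
#' @param binary_fraction fraction of features that are binary (the last
#'   columns).
#' @param bernoulli_shift driver-rate shift of informative binary features.
#' @param missing_rate fraction of cells masked missing.
#' @param missing_mode `"mcar"` or `"block"`.
#' @param hotspots list of hotspot descriptors for the catalog, each a list
#'   with `gene`, `n_records` (default 5), `window_bp` (default 25) and
#'   optional `classes` (record classes, recycled).
#' @param recurrent list of recurrent-variant descriptors, each a list with
#'   `gene`, `n_samples` (default 3) and optional `cancer_types` (recycled
#'   over the carrying samples).
#' @param n_singletons isolated background singletons (expanded-passenger
#'   truth when their genes are not in the census).
#' @param singleton_spacing base pairs between consecutive singletons
#'   (default 100, comfortably beyond the 31 bp isolation window).
#' @param cancer_type target cancer type written on generated records.
#' @param seed integer seed; generation is deterministic.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_drivers = 100, n_passengers = 400,
                         n_features = 30, n_informative = 3,
                         effect_size = 1, binary_fraction = 0,
                         bernoulli_shift = 0.2, missing_rate = 0,
                         missing_mode = c("mcar", "block"),
                         hotspots = list(), recurrent = list(),
                         n_singletons = 0, singleton_spacing = 100,
                         cancer_type = "SIM", seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (n_informative > n_features)
    abort_fmt("n_informative (%d) exceeds n_features (%d)",
              n_informative, n_features)
  if (missing_rate < 0 || missing_rate >= 1)
    abort_fmt("missing_rate must be in [0, 1)")
  if (effect_size < 0) abort_fmt("effect_size must be >= 0")
  if (binary_fraction < 0 || binary_fraction > 1)
    abort_fmt("binary_fraction must be in [0, 1]")
  structure(list(n_drivers = n_drivers, n_passengers = n_passengers,
                 n_features = n_features, n_informative = n_informative,
                 effect_size = effect_size,
                 binary_fraction = binary_fraction,
                 bernoulli_shift = bernoulli_shift,
                 missing_rate = missing_rate, missing_mode = missing_mode,
                 hotspots = hotspots, recurrent = recurrent,
                 n_singletons = n_singletons,
                 singleton_spacing = singleton_spacing,
                 cancer_type = cancer_type, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a labelled feature table
#'
#' @param spec a [fixture_spec()].
#' @return list with `table` (a [feature_table()]) and `labels` (named
#'   driver/passenger vector).
#' @export
make_feature_table <- function(spec) {
  withr::with_seed(spec$seed, {
    nd <- spec$n_drivers; np <- spec$n_passengers
    nf <- spec$n_features; ni <- spec$n_informative
    nb <- floor(spec$binary_fraction * nf)
    ids <- c(sprintf("d%04d", seq_len(nd)), sprintf("p%04d", seq_len(np)))
    labels <- c(rep("driver", nd), rep("passenger", np))
    names(labels) <- ids
    kinds <- rep("continuous", nf)
    if (nb) kinds[(nf - nb + 1):nf] <- "binary"
    fnames <- ifelse(seq_len(nf) <= ni,
                     sprintf("inf%02d", seq_len(nf)),
                     sprintf("noise%02d", seq_len(nf)))
    names(kinds) <- fnames
    m <- matrix(NA_real_, nd + np, nf, dimnames = list(ids, fnames))
    for (j in seq_len(nf)) {
      informative <- j <= ni
      if (kinds[j] == "binary") {
        pd <- if (informative) min(1, 0.5 + spec$bernoulli_shift) else 0.5
        m[, j] <- c(stats::rbinom(nd, 1, pd), stats::rbinom(np, 1, 0.5))
      } else {
        mu <- if (informative) spec$effect_size else 0
        m[, j] <- c(stats::rnorm(nd, mu), stats::rnorm(np, 0))
      }
    }
    if (spec$missing_rate > 0) {
      if (spec$missing_mode == "mcar") {
        mask <- matrix(stats::runif(length(m)) < spec$missing_rate,
                       nrow(m), ncol(m))
      } else {
        block <- sample.int(nf, max(1, ceiling(0.3 * nf)))
        mask <- matrix(FALSE, nrow(m), ncol(m))
        mask[, block] <- stats::runif(nrow(m) * length(block)) <
          min(0.95, spec$missing_rate * nf / length(block))
      }
      # keep at least one observed value per feature so imputation is defined
      for (j in which(colSums(!mask) == 0)) mask[1, j] <- FALSE
      m[mask] <- NA_real_
    }
    list(table = feature_table(m, kinds), labels = labels)
  })
}

#' Generate a mutation catalog with known curation structure
#'
#' Lays out each element (singletons, hotspots, recurrent variants) in its
#' own well-separated genomic neighbourhood (10 kb apart on `chr1`) so the
#' proximity rules cannot interact across elements. Hotspot records are
#' spread evenly over the window, so exactly the centred record accumulates
#' the full window count; recurrent variants repeat the same
#' (chrom, pos, ref, alt) across distinct primary-tumour samples.
#'
#' @param spec a [fixture_spec()].
#' @return list with `catalog` (mutation catalog `data.frame`) and `truth`
#'   (`data.frame` of `mutation_id`, `role`, `gene`), where `role` is one of
#'   `expanded_passenger`, `rule1_driver`, `rule2_driver`, `rule3_driver`,
#'   `hotspot_support`.
#' @export
make_catalog <- function(spec) {
  withr::with_seed(spec$seed, {
    rows <- list(); truth <- list()
    idc <- 0L
    nid <- function() { idc <<- idc + 1L; sprintf("c%05d", idc) }
    block <- 0L
    base_pos <- function() { block <<- block + 1L; block * 10000L }
    rec <- function(id, gene, pos, sample, class = "missense",
                    stype = "primary_tumor", ctype = spec$cancer_type,
                    ref = "A", alt = "T") {
      data.frame(mutation_id = id, gene = gene, chrom = "chr1",
                 pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
                 protein_change = "", sample_id = sample,
                 sample_type = stype, mutation_class = class,
                 cancer_type = ctype, source = "sim",
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(spec$n_singletons)) {
      base <- base_pos()
      id <- nid()
      gene <- sprintf("BGG%03d", i)
      rows[[length(rows) + 1L]] <-
        rec(id, gene, base, sprintf("S_bg_%03d", i))
      truth[[length(truth) + 1L]] <-
        data.frame(mutation_id = id, role = "expanded_passenger",
                   gene = gene, stringsAsFactors = FALSE)
    }
    for (h in spec$hotspots) {
      base <- base_pos()
      nrec <- h$n_records %||% 5L
      win <- h$window_bp %||% 25L
      classes <- rep_len(h$classes %||% "missense", nrec)
      half <- (win - 1L) / 2L
      offs <- if (nrec == 1L) 0L else
        as.integer(round(seq(-half, half, length.out = nrec)))
      centre <- which.min(abs(offs))
      role <- if (win == 1L) "rule2_driver" else "rule3_driver"
      for (r in seq_len(nrec)) {
        id <- nid()
        rows[[length(rows) + 1L]] <-
          rec(id, h$gene, base + offs[r], sprintf("S_%s_%02d", h$gene, r),
              class = classes[r],
              alt = if (classes[r] == "missense") "T" else "-")
        if (r == centre && classes[r] == "missense")
          truth[[length(truth) + 1L]] <-
            data.frame(mutation_id = id, role = role, gene = h$gene,
                       stringsAsFactors = FALSE)
        else
          truth[[length(truth) + 1L]] <-
            data.frame(mutation_id = id, role = "hotspot_support",
                       gene = h$gene, stringsAsFactors = FALSE)
      }
    }
    for (v in spec$recurrent) {
      base <- base_pos()
      ns <- v$n_samples %||% 3L
      ctypes <- rep_len(v$cancer_types %||% spec$cancer_type, ns)
      for (r in seq_len(ns)) {
        id <- nid()
        rows[[length(rows) + 1L]] <-
          rec(id, v$gene, base, sprintf("S_%s_rv%02d", v$gene, r),
              ctype = ctypes[r])
        truth[[length(truth) + 1L]] <-
          data.frame(mutation_id = id,
                     role = if (ns >= 3) "rule1_driver" else "hotspot_support",
                     gene = v$gene, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) abort_fmt("fixture spec generates an empty catalog")
    catalog <- do.call(rbind, rows)
    class(catalog) <- c("mutation_catalog", "data.frame")
    list(catalog = catalog, truth = do.call(rbind, truth))
  })
}

#' Generate a matched feature table + catalog study
#'
#' Produces the feature table of [make_feature_table()] together with a
#' minimal companion catalog assigning each table mutation a gene and a
#' position (round-robin over `genes_per_25` mutations per gene, 150 bp
#' apart), so that within-gene k-nearest-neighbour imputation is exercised.
#'
#' @param spec a [fixture_spec()].
#' @param mutations_per_gene how many table mutations share a gene.
#' @return list with `table`, `labels`, `catalog`.
#' @export
make_study <- function(spec, mutations_per_gene = 25) {
  ft <- make_feature_table(spec)
  ids <- rownames(ft$table$values)
  n <- length(ids)
  gidx <- ceiling(seq_len(n) / mutations_per_gene)
  catalog <- data.frame(
    mutation_id = ids,
    gene = sprintf("SG%03d", gidx),
    chrom = "chr1",
    pos = as.integer(gidx * 100000L +
                       (seq_len(n) - 1L) %% mutations_per_gene * 150L),
    ref_allele = "A", alt_allele = "T", protein_change = "",
    sample_id = sprintf("S%04d", seq_len(n)),
    sample_type = "primary_tumor", mutation_class = "missense",
    cancer_type = spec$cancer_type, source = "sim",
    stringsAsFactors = FALSE
  )
  class(catalog) <- c("mutation_catalog", "data.frame")
  list(table = ft$table, labels = ft$labels, catalog = catalog)
}

#' Write a simulated study to disk
#'
#' Emits `catalog.tsv`, `features.tsv`, `feature_kinds.yaml` and
#' `truth.tsv` (mutation_id, label) under `dir`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named vector of the four paths.
#' @export
write_study <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- make_study(spec)
  paths <- c(catalog = file.path(dir, "catalog.tsv"),
             features = file.path(dir, "features.tsv"),
             kinds = file.path(dir, "feature_kinds.yaml"),
             truth = file.path(dir, "truth.tsv"))
  write_catalog(st$catalog, paths["catalog"])
  write_feature_table(st$table, paths["features"], paths["kinds"])
  utils::write.table(
    data.frame(mutation_id = names(st$labels), label = unname(st$labels)),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
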