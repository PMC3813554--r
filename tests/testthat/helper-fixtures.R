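# Small constructors and independent brute-force oracles used across tests.

cat_row <- function(id, gene, pos, sample, class = "missense",
                    chrom = "chr1", stype = "primary_tumor", ctype = "GBM",
                    ref = "A", alt = "T", protein = "") {
  data.frame(mutation_id = id, gene = gene, chrom = chrom,
             pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
             protein_change = protein, sample_id = sample,
             sample_type = stype, mutation_class = class,
             cancer_type = ctype, source = "test",
             stringsAsFactors = FALSE)
}

bind_catalog <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

tiny_table <- function(values, kinds = NULL) {
  feature_table(values, kinds)
}

# AUC by explicit enumeration of all (positive, negative) pairs
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# upper-tail hypergeometric by direct combinatorial summation
oracle_hyper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(n, js) * choose(N - n, K - js)) / choose(N, K)
}

# brute-force O(n^2) pairwise-distance re-implementation of the expanded
# window rules, used as the oracle for the curation module
oracle_expanded_drivers <- function(catalog, cancer_type,
                                    config = curation_config()) {
  genes_in_type <- unique(catalog$gene[catalog$cancer_type == cancer_type])
  half <- (config$hotspot_window_bp - 1) / 2
  out <- character()
  for (i in seq_len(nrow(catalog))) {
    r <- catalog[i, ]
    if (r$mutation_class != "missense" || !(r$gene %in% genes_in_type)) next
    same_var <- catalog$chrom == r$chrom & catalog$pos == r$pos &
      catalog$ref_allele == r$ref_allele & catalog$alt_allele == r$alt_allele
    rule1 <- length(unique(
      catalog$sample_id[same_var & catalog$sample_type == "primary_tumor"])) >=
      config$expanded_driver_min_samples
    same_site <- catalog$chrom == r$chrom & catalog$pos == r$pos
    rule2 <- sum(same_site) >= config$site_intersect_min
    in_win <- catalog$chrom == r$chrom & abs(catalog$pos - r$pos) <= half
    rule3 <- sum(in_win) >= config$hotspot_min_mutations
    if (rule1 || rule2 || rule3) out <- c(out, r$mutation_id)
  }
  out
}

oracle_expanded_passengers <- function(catalog, cancer_type,
                                       cancer_genes = gene_list(),
                                       config = curation_config()) {
  half <- (config$passenger_isolation_window_bp - 1) / 2
  out <- character()
  for (i in seq_len(nrow(catalog))) {
    r <- catalog[i, ]
    if (r$mutation_class != "missense" || r$cancer_type != cancer_type ||
        r$sample_type != "primary_tumor") next
    if (r$gene %in% cancer_genes$genes) next
    same_var <- which(catalog$chrom == r$chrom & catalog$pos == r$pos &
                        catalog$ref_allele == r$ref_allele &
                        catalog$alt_allele == r$alt_allele &
                        catalog$cancer_type == cancer_type &
                        catalog$sample_type == "primary_tumor")
    if (length(same_var) != 1) next
    others <- setdiff(which(catalog$chrom == r$chrom &
                              abs(catalog$pos - r$pos) <= half), i)
    if (length(others)) next
    out <- c(out, r$mutation_id)
  }
  out
}

# random catalog with clustered positions so the window rules actually fire
random_catalog <- function(n, seed) {
  withr::with_seed(seed, {
    classes <- sample(c("missense", "indel", "nonsense", "dinucleotide"),
                      n, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
    bind_catalog(cat_row(
      id = sprintf("r%04d", seq_len(n)),
      gene = sprintf("G%02d", sample.int(12, n, replace = TRUE)),
      pos = sample.int(2000, n, replace = TRUE),
      sample = sprintf("S%02d", sample.int(25, n, replace = TRUE)),
      class = classes,
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      stype = sample(c("primary_tumor", "cell_line"), n, replace = TRUE,
                     prob = c(0.8, 0.2)),
      ctype = sample(c("GBM", "OVC"), n, replace = TRUE, prob = c(0.6, 0.4))
    ))
  })
}
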