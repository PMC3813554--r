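#' Curation thresholds and windows
#'
#' Parameters of the recurrence and proximity rules that define the
#' stringent (S) and expanded (E) driver/passenger sets. Windows are odd and
#' centred on the candidate mutation: a 25 bp hotspot window means
#' `pos +/- 12`; a 31 bp isolation window means `pos +/- 15`.
#'
#' @param stringent_min_samples minimum distinct samples carrying the exact
#'   variant for a stringent driver (default 2).
#' @param expanded_driver_min_samples minimum distinct primary-tumour
#'   samples, any cancer type, for expanded rule 1 (default 3).
#' @param site_intersect_min minimum mutation records (any class) sharing
#'   the exact genomic site for expanded rule 2 (default 4).
#' @param hotspot_window_bp centred window width for expanded rule 3
#'   (default 25; must be odd).
#' @param hotspot_min_mutations minimum records inside the hotspot window
#'   (default 5).
#' @param passenger_isolation_window_bp centred window that must contain no
#'   other record for an expanded passenger (default 31; must be odd).
#' @param hypermutated_min_missense per-sample missense count above which a
#'   sample is hypermutated (strictly greater; dataset specific, e.g. 55 for
#'   glioblastoma, 130 for ovarian carcinoma).
#' @param site_intersect_unit `"records"` (default) or `"samples"`: whether
#'   rules 2-3 count mutation records or distinct samples.
#' @return a `curation_config` list.
#' @export
curation_config <- function(stringent_min_samples = 2,
                            expanded_driver_min_samples = 3,
                            site_intersect_min = 4,
                            hotspot_window_bp = 25,
                            hotspot_min_mutations = 5,
                            passenger_isolation_window_bp = 31,
                            hypermutated_min_missense = 55,
                            site_intersect_unit = c("records", "samples")) {
  cfg <- list(stringent_min_samples = stringent_min_samples,
              expanded_driver_min_samples = expanded_driver_min_samples,
              site_intersect_min = site_intersect_min,
              hotspot_window_bp = hotspot_window_bp,
              hotspot_min_mutations = hotspot_min_mutations,
              passenger_isolation_window_bp = passenger_isolation_window_bp,
              hypermutated_min_missense = hypermutated_min_missense,
              site_intersect_unit = match.arg(site_intersect_unit))
  for (f in setdiff(names(cfg), "site_intersect_unit"))
    if (!is_count(cfg[[f]])) abort_fmt("curation config '%s' must be a positive integer", f)
  if (cfg$hotspot_window_bp %% 2 == 0 ||
      cfg$passenger_isolation_window_bp %% 2 == 0)
    abort_fmt("window sizes must be odd (centred windows)")
  structure(cfg, class = "curation_config")
}

# number of reference records within query pos +/- half on the same
# chromosome (a reference record at the query position itself counts)
count_within_window <- function(chrom_q, pos_q, chrom_ref = chrom_q,
                                pos_ref = pos_q, half = 0L) {
  out <- integer(length(pos_q))
  for (cc in unique(chrom_q)) {
    i <- which(chrom_q == cc)
    p <- sort(pos_ref[chrom_ref == cc])
    out[i] <- findInterval(pos_q[i] + half, p) -
      findInterval(pos_q[i] - half - 1L, p)
  }
  out
}

distinct_samples_by <- function(key, sample_id) {
  tab <- tapply(sample_id, key, function(s) length(unique(s)))
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

#' Stringent driver mutations
#'
#' A missense variant (identical chrom, pos, ref, alt) is a stringent driver
#' when observed in at least `stringent_min_samples` distinct samples, no
#' carrying sample also harbours a putative functional confounder (indel,
#' nonsense, nonstop, splice-site or translation-start mutation) in the same
#' gene, and its site is not blacklisted.
#'
#' @param catalog mutation catalog restricted to one cancer type.
#' @param blacklist a [site_blacklist()].
#' @param config a [curation_config()].
#' @return character vector of qualifying missense mutation ids (all records
#'   of each qualifying variant).
#' @export
stringent_drivers <- function(catalog, blacklist = site_blacklist(),
                              config = curation_config()) {
  mis <- catalog[catalog$mutation_class == "missense", , drop = FALSE]
  if (!nrow(mis)) return(character())
  key <- variant_key(mis$chrom, mis$pos, mis$ref_allele, mis$alt_allele)
  nsamp <- distinct_samples_by(key, mis$sample_id)
  cand <- names(nsamp)[nsamp >= config$stringent_min_samples]
  if (!length(cand)) return(character())

  conf <- catalog[catalog$mutation_class %in% CONFOUNDER_CLASSES, , drop = FALSE]
  conf_pairs <- unique(paste(conf$gene, conf$sample_id, sep = "\r"))
  keep <- vapply(cand, function(kk) {
    rows <- mis[key == kk, , drop = FALSE]
    if (blacklisted(blacklist, rows$chrom[1], rows$pos[1])) return(FALSE)
    !any(paste(rows$gene, rows$sample_id, sep = "\r") %in% conf_pairs)
  }, logical(1))
  mis$mutation_id[key %in% cand[keep]]
}

#' Stringent passenger mutations
#'
#' Missense mutations from hypermutated samples (per-sample missense count
#' strictly greater than `hypermutated_min_missense`), excluding mutations
#' in cancer genes and blacklisted sites.
#'
#' @inheritParams stringent_drivers
#' @param cancer_genes a [gene_list()] of known cancer genes.
#' @return character vector of mutation ids.
#' @export
stringent_passengers <- function(catalog, blacklist = site_blacklist(),
                                 cancer_genes = gene_list(),
                                 config = curation_config()) {
  mis <- catalog[catalog$mutation_class == "missense", , drop = FALSE]
  if (!nrow(mis)) return(character())
  cnt <- table(mis$sample_id)
  hyper <- names(cnt)[cnt > config$hypermutated_min_missense]
  rows <- mis[mis$sample_id %in% hyper &
                !(mis$gene %in% cancer_genes$genes) &
                !blacklisted(blacklist, mis$chrom, mis$pos), , drop = FALSE]
  rows$mutation_id
}

#' Expanded driver mutations
#'
#' For a target cancer type, a missense record whose gene carries at least
#' one record (any class) in that type qualifies as an expanded driver when
#' any of three cross-cancer recurrence rules holds:
#' \enumerate{
#'   \item its exact variant is observed in at least
#'     `expanded_driver_min_samples` distinct primary-tumour samples of any
#'     cancer type;
#'   \item at least `site_intersect_min` catalog records of any class share
#'     its genomic site (the candidate's own records included);
#'   \item at least `hotspot_min_mutations` catalog records fall within the
#'     centred `hotspot_window_bp` window around its position.
#' }
#' Records whose variant appears among `exclude` (typically the stringent
#' drivers) are removed so the sets stay independent.
#'
#' @param catalog mutation catalog; may span multiple cancer types.
#' @param cancer_type target cancer type (matched against the catalog's
#'   `cancer_type` column).
#' @param config a [curation_config()].
#' @param exclude mutation ids whose variants to subtract from the result.
#' @return character vector of mutation ids.
#' @export
expanded_drivers <- function(catalog, cancer_type,
                             config = curation_config(),
                             exclude = character()) {
  target <- catalog[catalog$cancer_type == cancer_type, , drop = FALSE]
  genes_in_type <- unique(target$gene)
  cand_idx <- which(catalog$mutation_class == "missense" &
                      catalog$gene %in% genes_in_type)
  if (!length(cand_idx)) return(character())
  cand <- catalog[cand_idx, , drop = FALSE]
  ckey <- variant_key(cand$chrom, cand$pos, cand$ref_allele, cand$alt_allele)

  # rule 1: recurrence across primary tumour samples, any cancer type
  prim <- catalog[catalog$sample_type == "primary_tumor", , drop = FALSE]
  pkey <- variant_key(prim$chrom, prim$pos, prim$ref_allele, prim$alt_allele)
  nsamp <- distinct_samples_by(pkey, prim$sample_id)
  rule1 <- !is.na(nsamp[ckey]) & nsamp[ckey] >= config$expanded_driver_min_samples
  rule1[is.na(rule1)] <- FALSE

  # rules 2-3: proximity over all records of any class (optionally counting
  # distinct samples per site instead of records)
  if (config$site_intersect_unit == "records") {
    ref <- catalog
  } else {
    ref <- catalog[!duplicated(paste(catalog$chrom, catalog$pos,
                                     catalog$sample_id)), , drop = FALSE]
  }
  site_n <- table(site_key(ref$chrom, ref$pos))
  rule2 <- as.vector(site_n[site_key(cand$chrom, cand$pos)]) >=
    config$site_intersect_min
  rule2[is.na(rule2)] <- FALSE
  win_n <- count_within_window(cand$chrom, cand$pos, ref$chrom, ref$pos,
                               (config$hotspot_window_bp - 1L) / 2L)
  rule3 <- win_n >= config$hotspot_min_mutations

  hit <- rule1 | rule2 | rule3
  if (length(exclude)) {
    ex <- catalog[catalog$mutation_id %in% exclude, , drop = FALSE]
    exkey <- variant_key(ex$chrom, ex$pos, ex$ref_allele, ex$alt_allele)
    hit <- hit & !(ckey %in% exkey)
  }
  cand$mutation_id[hit]
}

#' Expanded passenger mutations
#'
#' Missense mutations observed exactly once in primary-tumour samples of the
#' target cancer type, in a gene outside the cancer-gene list, with no other
#' catalog record (any class, any cancer type) within the centred
#' `passenger_isolation_window_bp` window. Variants appearing among
#' `exclude` (typically the stringent passengers) are subtracted.
#'
#' @inheritParams expanded_drivers
#' @param cancer_genes a [gene_list()].
#' @return character vector of mutation ids.
#' @export
expanded_passengers <- function(catalog, cancer_type,
                                cancer_genes = gene_list(),
                                config = curation_config(),
                                exclude = character()) {
  tprim <- catalog$cancer_type == cancer_type &
    catalog$sample_type == "primary_tumor"
  tmis <- which(tprim & catalog$mutation_class == "missense")
  if (!length(tmis)) return(character())
  cand <- catalog[tmis, , drop = FALSE]
  ckey <- variant_key(cand$chrom, cand$pos, cand$ref_allele, cand$alt_allele)
  occ <- table(ckey)
  singleton <- as.vector(occ[ckey]) == 1L

  half <- (config$passenger_isolation_window_bp - 1L) / 2L
  win_all <- count_within_window(catalog$chrom, catalog$pos, half = half)
  isolated <- win_all[tmis] == 1L   # only the record itself in its window

  keep <- singleton & isolated & !(cand$gene %in% cancer_genes$genes)
  if (length(exclude)) {
    ex <- catalog[catalog$mutation_id %in% exclude, , drop = FALSE]
    exkey <- variant_key(ex$chrom, ex$pos, ex$ref_allele, ex$alt_allele)
    keep <- keep & !(ckey %in% exkey)
  }
  cand$mutation_id[keep]
}

#' Curate stringent and expanded training sets
#'
#' Runs the four curation rules for one target cancer type and enforces
#' mutual independence: expanded drivers/passengers have the stringent
#' variants subtracted, and no mutation id appears in more than one of the
#' four sets.
#'
#' @inheritParams expanded_drivers
#' @param blacklist a [site_blacklist()].
#' @param cancer_genes a [gene_list()].
#' @return list with elements `stringent` and `expanded`, each a list with
#'   `drivers` and `passengers` (mutation-id vectors), plus `cancer_type`.
#' @export
curate_training_sets <- function(catalog, cancer_type,
                                 blacklist = site_blacklist(),
                                 cancer_genes = gene_list(),
                                 config = curation_config()) {
  target <- catalog[catalog$cancer_type == cancer_type, , drop = FALSE]
  s_drv <- stringent_drivers(target, blacklist, config)
  s_pas <- setdiff(stringent_passengers(target, blacklist, cancer_genes, config),
                   s_drv)
  e_drv <- expanded_drivers(catalog, cancer_type, config, exclude = s_drv)
  e_pas <- expanded_passengers(catalog, cancer_type, cancer_genes, config,
                               exclude = s_pas)
  e_drv <- setdiff(e_drv, c(s_drv, s_pas))
  e_pas <- setdiff(e_pas, c(s_drv, s_pas, e_drv))
  list(stringent = list(drivers = s_drv, passengers = s_pas,
                        provenance = "stringent"),
       expanded = list(drivers = e_drv, passengers = e_pas,
                       provenance = "expanded"),
       cancer_type = cancer_type)
}
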