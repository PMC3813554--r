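#' @title Somatic mutation catalog I/O
#' @description Readers and writers for mutation catalogs (MAF-like TSV),
#'   site blacklists (BED or two-column TSV), gene lists and driver-call
#'   tables. Coordinates are 1-based inclusive internally; BED input is
#'   converted at the boundary.
#' @name catalog-io
NULL

MUTATION_CLASSES <- c("missense", "nonsense", "nonstop", "splice_site",
                      "translation_start", "indel", "dinucleotide",
                      "trinucleotide", "other")

SAMPLE_TYPES <- c("primary_tumor", "cell_line", "other")

# Mutation classes that disqualify a recurrent missense candidate when found
# in the same gene of a carrying sample (putative functional confounders).
CONFOUNDER_CLASSES <- c("indel", "nonsense", "nonstop", "splice_site",
                        "translation_start")

# spellings commonly seen in MAF / catalog exports, lower-cased
.class_aliases <- c(
  missense = "missense", missense_mutation = "missense", snp = "missense",
  nonsense = "nonsense", nonsense_mutation = "nonsense",
  nonstop = "nonstop", nonstop_mutation = "nonstop",
  splice_site = "splice_site", splice = "splice_site",
  translation_start = "translation_start",
  translation_start_site = "translation_start",
  indel = "indel", frame_shift_del = "indel", frame_shift_ins = "indel",
  in_frame_del = "indel", in_frame_ins = "indel", insertion = "indel",
  deletion = "indel",
  dinucleotide = "dinucleotide", dnp = "dinucleotide",
  trinucleotide = "trinucleotide", tnp = "trinucleotide",
  other = "other"
)

.sample_type_aliases <- c(
  primary_tumor = "primary_tumor", primary = "primary_tumor",
  tumor = "primary_tumor", tumour = "primary_tumor",
  cell_line = "cell_line", cellline = "cell_line", ccle = "cell_line",
  other = "other"
)

#' Column-mapping dialect for mutation catalogs
#'
#' Maps the package's internal field names to the column headers of a
#' particular catalog file. The default dialect expects internal names
#' verbatim; [maf_dialect()] covers common MAF headers. A dialect can also be
#' loaded from a YAML file with [read_dialect()], so differently-headed
#' catalogs load without code changes.
#'
#' @param mutation_id,gene,chrom,pos,ref_allele,alt_allele,protein_change,sample_id,sample_type,mutation_class,cancer_type,source
#'   column name in the file for each field, or `NA` to mark a field as
#'   absent (optional fields only).
#' @return named list of column names.
#' @export
catalog_dialect <- function(mutation_id = "mutation_id", gene = "gene",
                            chrom = "chrom", pos = "pos",
                            ref_allele = "ref_allele",
                            alt_allele = "alt_allele",
                            protein_change = "protein_change",
                            sample_id = "sample_id",
                            sample_type = "sample_type",
                            mutation_class = "mutation_class",
                            cancer_type = "cancer_type", source = "source") {
  list(mutation_id = mutation_id, gene = gene, chrom = chrom, pos = pos,
       ref_allele = ref_allele, alt_allele = alt_allele,
       protein_change = protein_change, sample_id = sample_id,
       sample_type = sample_type, mutation_class = mutation_class,
       cancer_type = cancer_type, source = source)
}

#' @rdname catalog_dialect
#' @export
maf_dialect <- function() {
  catalog_dialect(mutation_id = NA, gene = "Hugo_Symbol",
                  chrom = "Chromosome", pos = "Start_Position",
                  ref_allele = "Reference_Allele",
                  alt_allele = "Tumor_Seq_Allele2",
                  protein_change = "HGVSp_Short",
                  sample_id = "Tumor_Sample_Barcode",
                  sample_type = NA,
                  mutation_class = "Variant_Classification",
                  cancer_type = NA, source = NA)
}

#' @rdname catalog_dialect
#' @param path YAML file whose keys are internal field names and values are
#'   column headers.
#' @export
read_dialect <- function(path) {
  d <- yaml::read_yaml(path)
  do.call(catalog_dialect, d)
}

#' Read a somatic mutation catalog
#'
#' Reads a tab-separated catalog with a header row into a mutation-catalog
#' `data.frame` (one row per observed mutation record). Row count is
#' preserved; mutation classes that cannot be mapped to the internal
#' vocabulary become `"other"`. When the dialect provides no mutation-id
#' column, stable ids `m00001, m00002, ...` are synthesised in file order.
#'
#' @param path TSV file with header.
#' @param dialect column mapping, see [catalog_dialect()].
#' @return `data.frame` with columns `mutation_id`, `gene`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `protein_change`, `sample_id`,
#'   `sample_type`, `mutation_class`, `cancer_type`, `source`. Gene symbols
#'   are upper-cased; `pos` is a 1-based integer.
#' @export
read_catalog <- function(path, dialect = catalog_dialect()) {
  if (!file.exists(path)) abort_fmt("catalog file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  required <- c("gene", "chrom", "pos", "ref_allele", "alt_allele",
                "sample_id", "mutation_class")
  for (f in required) {
    col <- dialect[[f]]
    if (is.null(col) || is.na(col) || !col %in% names(raw))
      abort_fmt("catalog '%s': missing required column '%s' (field '%s')",
                path, if (is.null(col) || is.na(col)) "<unmapped>" else col, f)
  }
  n <- nrow(raw)
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && !is.na(col) && col %in% names(raw)) raw[[col]]
    else rep(default, n)
  }
  pos_chr <- get_col("pos")
  pos_num <- suppressWarnings(as.numeric(pos_chr))
  bad <- which(is.na(pos_num) | pos_num %% 1 != 0 | pos_num < 1)
  if (length(bad))
    abort_fmt("catalog '%s': non-integer or invalid position '%s' at line %d",
              path, pos_chr[bad[1]], bad[1] + 1L)

  ids <- get_col("mutation_id")
  if (all(is.na(ids))) ids <- sprintf("m%05d", seq_len(n))
  if (anyDuplicated(ids))
    abort_fmt("catalog '%s': duplicated mutation_id '%s'",
              path, ids[duplicated(ids)][1])

  cls <- tolower(get_col("mutation_class"))
  cls <- unname(.class_aliases[cls])
  cls[is.na(cls)] <- "other"

  styp <- tolower(get_col("sample_type", "primary_tumor"))
  styp[is.na(styp) | styp == ""] <- "primary_tumor"
  styp <- unname(.sample_type_aliases[styp])
  styp[is.na(styp)] <- "other"

  out <- data.frame(
    mutation_id = ids,
    gene = toupper(get_col("gene")),
    chrom = get_col("chrom"),
    pos = as.integer(pos_num),
    ref_allele = get_col("ref_allele"),
    alt_allele = get_col("alt_allele"),
    protein_change = get_col("protein_change"),
    sample_id = get_col("sample_id"),
    sample_type = styp,
    mutation_class = cls,
    cancer_type = get_col("cancer_type", ""),
    source = get_col("source", ""),
    stringsAsFactors = FALSE
  )
  out$cancer_type[is.na(out$cancer_type)] <- ""
  out$source[is.na(out$source)] <- ""
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

#' Write a mutation catalog as TSV (internal column names)
#'
#' `read_catalog(write_catalog(x))` with the default dialect is the identity
#' on the modelled fields.
#' @param catalog mutation catalog `data.frame`.
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a site blacklist
#'
#' Sites (e.g. known germline polymorphisms) that disqualify curation
#' candidates. BED input is 0-based half-open and each interval is expanded
#' to its 1-based sites; TSV input is two columns `chrom`, `pos`, 1-based.
#' Duplicate lines collapse to a single membership.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return a `site_blacklist` object.
#' @export
read_blacklist <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(site_blacklist(character()))
  parts <- strsplit(lines, "[\t ]+")
  keys <- unlist(lapply(parts, function(p) {
    if (format == "bed") {
      if (length(p) < 3) abort_fmt("blacklist BED line with < 3 fields")
      start <- as.numeric(p[2]); end <- as.numeric(p[3])
      if (is.na(start) || is.na(end) || start < 0 || end < start)
        abort_fmt("blacklist BED: invalid interval '%s %s %s'", p[1], p[2], p[3])
      if (end == start) return(character())     # zero-length interval
      site_key(p[1], seq.int(start + 1, end))   # 0-based half-open -> 1-based
    } else {
      if (length(p) < 2) abort_fmt("blacklist TSV line with < 2 fields")
      pos <- as.numeric(p[2])
      if (is.na(pos) || pos < 1)
        abort_fmt("blacklist TSV: invalid position '%s'", p[2])
      site_key(p[1], as.integer(pos))
    }
  }))
  site_blacklist(keys)
}

#' @rdname read_blacklist
#' @param sites character vector of `"chrom:pos"` keys.
#' @export
site_blacklist <- function(sites = character()) {
  structure(list(sites = unique(sites)), class = "site_blacklist")
}

#' @rdname read_blacklist
#' @param x a `site_blacklist`.
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return logical vector of memberships.
#' @export
blacklisted <- function(x, chrom, pos) {
  stopifnot(inherits(x, "site_blacklist"))
  site_key(chrom, pos) %in% x$sites
}

#' Read a gene list (one symbol per line)
#'
#' Symbols are upper-cased and de-duplicated; no alias resolution is
#' attempted.
#' @param path plain-text file, one gene symbol per line.
#' @param label short label for provenance (e.g. `"cancer_census"`).
#' @return a `gene_list` object with elements `genes` and `label`.
#' @export
read_gene_list <- function(path, label = "gene_list") {
  g <- readLines(path)
  g <- toupper(trimws(g))
  gene_list(g[nzchar(g)], label)
}

#' @rdname read_gene_list
#' @param genes character vector of symbols.
#' @export
gene_list <- function(genes = character(), label = "gene_list") {
  structure(list(genes = unique(toupper(genes)), label = label),
            class = "gene_list")
}

#' Write and read driver-call tables
#'
#' The call table has columns `mutation_id`, `score`, `category`
#' (`"driver"`, `"no-call"`, `"passenger"`) and `confidence` (empty for
#' no-calls). Writing then reading reproduces scores and confidences to six
#' decimals.
#'
#' @param calls `data.frame` with the four call columns.
#' @param path output TSV path.
#' @export
write_calls <- function(calls, path) {
  stopifnot(all(c("mutation_id", "score", "category", "confidence") %in%
                  names(calls)))
  bad <- setdiff(unique(calls$category), c("driver", "no-call", "passenger"))
  if (length(bad) && nrow(calls))
    abort_fmt("invalid call category '%s'", bad[1])
  out <- data.frame(
    mutation_id = calls$mutation_id,
    score = sprintf("%.6f", calls$score),
    category = calls$category,
    confidence = ifelse(is.na(calls$confidence), "NA",
                        sprintf("%.6f", calls$confidence)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(mutation_id = "character",
                                   score = "numeric",
                                   category = "character",
                                   confidence = "numeric"))
}
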