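`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

#' Normalise a label vector against a feature table
#'
#' Labels may be a named vector (matched to the table's mutation ids) or an
#' unnamed vector aligned with the table rows. Values must be "driver" or
#' "passenger".
#' @keywords internal
check_labels <- function(table, labels) {
  ids <- rownames(table$values)
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels)))
      abort_fmt("labels missing for %d mutation id(s), e.g. '%s'",
                sum(!ids %in% names(labels)), ids[!ids %in% names(labels)][1])
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    abort_fmt("labels length (%d) does not match table rows (%d)",
              length(labels), length(ids))
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("driver", "passenger"))
  if (length(bad))
    abort_fmt("labels must be 'driver' or 'passenger'; found '%s'", bad[1])
  names(labels) <- ids
  labels
}

require_both_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    abort_fmt("both classes (driver and passenger) must be present; found only '%s'",
              unique(labels))
  invisible(labels)
}
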