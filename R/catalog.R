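#' Contig catalog
#'
#' A contig catalog is the node universe of the contact network: one row per
#' assembly contig with its length (bp) and mean read coverage. It is a plain
#' `data.frame` with class `contig_catalog` so it prints compactly and can be
#' validated at module boundaries.
#'
#' @param id character vector of unique, non-empty contig identifiers.
#' @param length integer vector of contig lengths in bp (all >= 1).
#' @param coverage numeric vector of mean read depths (all >= 0). Defaults to
#'   0, to be filled in later by [compute_coverage()] or a depth table.
#' @return A `contig_catalog` data frame with columns `id`, `length`,
#'   `coverage`.
#' @examples
#' contig_catalog(c("c1", "c2"), c(1200L, 800L), c(12.5, 3.1))
#' @export
contig_catalog <- function(id, length, coverage = 0) {
  id <- as.character(id)
  length <- as.integer(length)
  coverage <- rep_len(as.numeric(coverage), length(id))
  if (any(is.na(id)) || any(!nzchar(id))) stop("contig ids must be non-empty")
  if (anyDuplicated(id)) stop("contig ids must be unique")
  if (length(length) != length(id)) stop("id and length differ in length")
  if (any(is.na(length)) || any(length < 1L)) stop("contig lengths must be >= 1")
  if (any(is.na(coverage)) || any(coverage < 0)) stop("coverages must be >= 0")
  structure(
    data.frame(id = id, length = length, coverage = coverage,
               stringsAsFactors = FALSE),
    class = c("contig_catalog", "data.frame")
  )
}

#' @export
print.contig_catalog <- function(x, ...) {
  cat(sprintf("<contig_catalog> %d contigs, %s bp total\n",
              nrow(x), format(sum(as.numeric(x$length)), big.mark = ",")))
  NextMethod()
}

as_contig_catalog <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "length") %in% names(x)))
  if (is.null(x$coverage)) x$coverage <- 0
  contig_catalog(x$id, x$length, x$coverage)
}

#' Discard short contigs
#'
#' Restricts a catalog to contigs of at least `min_length` bp. Contigs below
#' the threshold carry too little proximity-ligation signal to be placed
#' reliably and are removed before network construction; the conventional
#' cutoff is 500 bp. A contig of exactly `min_length` bp is retained (the
#' filter discards strictly shorter contigs).
#'
#' @param catalog a [contig_catalog()].
#' @param min_length minimum retained length in bp (default 500).
#' @return The filtered catalog; the input is not modified. An empty result
#'   triggers a warning, not an error.
#' @export
filter_contigs <- function(catalog, min_length = 500L) {
  stopifnot(min_length >= 0)
  keep <- catalog$length >= min_length
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no contigs pass the length filter")
  class(out) <- c("contig_catalog", "data.frame")
  out
}

#' Compute contig coverage from alignments
#'
#' Mean read depth per contig, computed as total aligned bases divided by
#' contig length. Records are filtered with the same ambiguity and mapping
#' quality rules used for network construction, so coverage and contact
#' counts are drawn from one consistent read population. Intra-contig (cis)
#' pairs contribute: every passing single-end alignment deposits its aligned
#' bases regardless of where its mate maps.
#'
#' @param alignments data frame of single-end alignment records with columns
#'   `contig_id`, `mapq`, `ambiguous`, and `read_len` (aligned bases).
#' @param catalog a [contig_catalog()]; contigs with no passing alignment get
#'   coverage 0.
#' @param mapq_threshold minimum retained mapping quality (default 20;
#'   records with mapq strictly below are discarded).
#' @return The catalog with its `coverage` column replaced.
#' @export
compute_coverage <- function(alignments, catalog, mapq_threshold = 20L) {
  stopifnot(all(c("contig_id", "mapq", "read_len") %in% names(alignments)))
  amb <- if (is.null(alignments$ambiguous)) FALSE else alignments$ambiguous
  keep <- !amb & alignments$mapq >= mapq_threshold &
    alignments$contig_id %in% catalog$id
  a <- alignments[keep, , drop = FALSE]
  bases <- vapply(
    split(as.numeric(a$read_len), factor(a$contig_id, levels = catalog$id)),
    sum, numeric(1)
  )
  catalog$coverage <- unname(bases) / catalog$length
  catalog
}
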