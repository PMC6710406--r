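#' Pair single-end alignments into inter-contig contacts
#'
#' Proximity-ligation mates are aligned independently in single-end mode;
#' this step re-joins them by read id and keeps a read pair only when both
#' mates align unambiguously, with mapping quality at or above the threshold,
#' to two *different* contigs. Everything else is dropped and counted by
#' category:
#'
#' * `ambiguous` — either mate flagged ambiguous (secondary/supplementary or
#'   multi-mapping), or a read id carrying more than two records, or two
#'   records of the same mate.
#' * `low_mapq` — either mate below `mapq_threshold` (mapq equal to the
#'   threshold is retained).
#' * `unmatched` — a singleton mate with no partner record.
#' * `same_contig` — both mates on one contig (cis pair; informative for
#'   coverage but excluded from the network).
#'
#' A dropped pair is counted once, in the first matching category of the
#' order above.
#'
#' @param alignments data frame of records with columns `read_id`, `mate`
#'   (1 or 2), `contig_id`, `mapq`, and optionally `ambiguous` (logical) and
#'   `position`.
#' @param mapq_threshold minimum retained mapping quality (default 20).
#' @param dedup if `TRUE`, collapse exact duplicate read ids after pairing to
#'   one pair each (input is normally already PCR-deduplicated upstream).
#' @return A list with `pairs`, a data frame of canonically ordered columns
#'   `contig_a` < `contig_b` (one row per retained read pair), and `drops`,
#'   a named integer vector of per-category dropped read counts.
#' @export
pair_reads <- function(alignments, mapq_threshold = 20L, dedup = FALSE) {
  stopifnot(all(c("read_id", "mate", "contig_id", "mapq") %in% names(alignments)))
  n <- nrow(alignments)
  amb <- if (is.null(alignments$ambiguous)) rep(FALSE, n) else as.logical(alignments$ambiguous)
  drops <- c(ambiguous = 0L, low_mapq = 0L, unmatched = 0L, same_contig = 0L)
  if (n == 0L) {
    return(list(pairs = data.frame(contig_a = character(), contig_b = character(),
                                   stringsAsFactors = FALSE),
                drops = drops))
  }

  rid <- as.character(alignments$read_id)
  ord <- order(rid, alignments$mate)
  rid <- rid[ord]
  mate <- as.integer(alignments$mate[ord])
  contig <- as.character(alignments$contig_id[ord])
  mapq <- as.numeric(alignments$mapq[ord])
  amb <- amb[ord]

  # run-length structure over sorted read ids
  r <- rle(rid)
  n_rec <- r$lengths
  first <- cumsum(c(1L, n_rec[-length(n_rec)]))

  multi <- n_rec > 2L
  single <- n_rec == 1L
  dual <- n_rec == 2L
  i1 <- first[dual]
  i2 <- i1 + 1L
  same_mate <- mate[i1] == mate[i2]

  drops["unmatched"] <- sum(single)
  dual_amb <- same_mate | amb[i1] | amb[i2]
  drops["ambiguous"] <- sum(multi) + sum(dual_amb)
  ok <- !dual_amb
  lowq <- ok & (mapq[i1] < mapq_threshold | mapq[i2] < mapq_threshold)
  drops["low_mapq"] <- sum(lowq)
  ok <- ok & !lowq
  cis <- ok & contig[i1] == contig[i2]
  drops["same_contig"] <- sum(cis)
  ok <- ok & !cis

  ca <- pmin(contig[i1][ok], contig[i2][ok])
  cb <- pmax(contig[i1][ok], contig[i2][ok])
  if (dedup && length(ca)) {
    keep <- !duplicated(r$values[dual][ok])
    ca <- ca[keep]; cb <- cb[keep]
  }
  list(
    pairs = data.frame(contig_a = ca, contig_b = cb, stringsAsFactors = FALSE),
    drops = drops
  )
}

#' Read a pre-digested pairs table
#'
#' Reads the tab-separated "pairs" format with columns `readID`, `contigA`,
#' `posA`, `mapqA`, `contigB`, `posB`, `mapqB` and converts it to the
#' per-mate alignment record layout consumed by [pair_reads()].
#'
#' @param path path to the TSV file (with header).
#' @return A data frame of single-end alignment records.
#' @export
read_pairs_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("readID", "contigA", "posA", "mapqA", "contigB", "posB", "mapqB")
  if (!all(need %in% names(x)))
    stop("pairs file must have columns: ", paste(need, collapse = ", "))
  data.frame(
    read_id = rep(x$readID, 2L),
    mate = rep(c(1L, 2L), each = nrow(x)),
    contig_id = c(x$contigA, x$contigB),
    position = c(x$posA, x$posB),
    mapq = c(x$mapqA, x$mapqB),
    ambiguous = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Read per-mate alignment records from a SAM/BAM file
#'
#' Thin adapter over `Rsamtools::scanBam()`. Mate number is taken from the
#' first/second-of-pair flags; records flagged secondary or supplementary are
#' marked `ambiguous`, as are unmapped records. Positions are converted to
#' 0-based.
#'
#' @param path path to a SAM or BAM file (SAM files are accepted via
#'   `asBam`-free streaming when samtools-indexed input is not available;
#'   plain SAM text is converted in a temporary directory).
#' @param read_len read length to assign when sequences are absent.
#' @return A data frame of single-end alignment records for [pair_reads()].
#' @export
read_alignments_sam <- function(path, read_len = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM input")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- x$flag
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  len <- if (!is.null(read_len)) rep_len(read_len, length(flag)) else
    Biostrings::width(x$seq)
  data.frame(
    read_id = x$qname,
    mate = mate,
    contig_id = as.character(x$rname),
    position = ifelse(is.na(x$pos), 0L, x$pos - 1L),
    mapq = ifelse(is.na(x$mapq), 0L, x$mapq),
    ambiguous = secondary | unmapped,
    read_len = len,
    stringsAsFactors = FALSE
  )
}
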