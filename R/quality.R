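#' Single-copy marker table
#'
#' Holds the marker evidence used to score bins: the universe of expected
#' single-copy markers and, per (contig, marker), the observed copy count.
#' This is a deliberately simple marker model -- a flat universal set with
#' no lineage-specific sets or collocation correction -- chosen so the
#' downstream scoring logic is identical whether the evidence comes from the
#' bundled simulator or from an external annotator's table
#' (see [read_checkm_table()] for ingesting pre-computed scores instead).
#'
#' @param markers character vector: the full expected marker set.
#' @param hits data frame with columns `contig_id`, `marker_id`, `copies`
#'   (integer >= 1).
#' @return A `marker_table` object.
#' @export
marker_table <- function(markers, hits) {
  markers <- unique(as.character(markers))
  stopifnot(length(markers) >= 1L,
            all(c("contig_id", "marker_id", "copies") %in% names(hits)))
  if (any(hits$copies < 1L)) stop("marker copy counts must be >= 1")
  if (!all(hits$marker_id %in% markers))
    stop("hits reference markers outside the marker set")
  structure(list(markers = markers, hits = hits), class = "marker_table")
}

#' Score a bin for completeness and contamination
#'
#' Completeness is the percentage of the expected marker set present at
#' least once among the bin's contigs; contamination is the percentage of
#' excess copies: `100 * sum(max(0, copies_m - 1)) / |marker set|`, summing
#' copies of each marker over all member contigs. A bin holding one whole
#' genome scores (100, 0); a bin holding two whole genomes scores
#' (100, 100); heavily pooled communities can exceed 1000% contamination.
#'
#' @param contig_ids character vector: the bin's members.
#' @param markers a [marker_table()].
#' @return Named numeric vector `c(completeness =, contamination =)`, both
#'   in percent.
#' @export
score_bin <- function(contig_ids, markers) {
  stopifnot(inherits(markers, "marker_table"))
  m <- length(markers$markers)
  h <- markers$hits[markers$hits$contig_id %in% contig_ids, , drop = FALSE]
  copies <- vapply(
    split(as.numeric(h$copies), factor(h$marker_id, levels = markers$markers)),
    sum, numeric(1)
  )
  c(completeness = 100 * sum(copies >= 1) / m,
    contamination = 100 * sum(pmax(0, copies - 1)) / m)
}

#' Read a CheckM-style quality table
#'
#' Adapter for pre-computed completeness/contamination tables in the tabular
#' layout of CheckM's `qa` output (`--tab_table`): columns `Bin Id`,
#' `Completeness`, `Contamination` (extra columns ignored).
#'
#' @param path path to the tab-separated table.
#' @return Data frame `bin_id`, `completeness`, `contamination`.
#' @export
read_checkm_table <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Bin Id", "Completeness", "Contamination")
  if (!all(need %in% names(x)))
    stop("expected CheckM columns: ", paste(need, collapse = ", "))
  data.frame(bin_id = as.character(x[["Bin Id"]]),
             completeness = as.numeric(x[["Completeness"]]),
             contamination = as.numeric(x[["Contamination"]]),
             stringsAsFactors = FALSE)
}

#' Aggregate tRNA/rRNA features over bins
#'
#' Turns per-contig RNA annotations (tRNA isotypes and the three rRNA genes)
#' into the per-bin statistics the MIMAG tiers need: the number of distinct
#' tRNAs and presence flags for the 5S, 16S and 23S rRNA genes.
#'
#' @param bins data frame `contig_id`, `bin_id`.
#' @param rna data frame `contig_id`, `feature`, where features are tRNA
#'   isotype names (prefix `"tRNA-"`) or `"rRNA-5S"`, `"rRNA-16S"`,
#'   `"rRNA-23S"`.
#' @return Data frame `bin_id`, `n_trna`, `has_5S`, `has_16S`, `has_23S`.
#' @export
aggregate_rna <- function(bins, rna) {
  ids <- unique(bins$bin_id)
  merged <- merge(bins, rna, by = "contig_id")
  out <- do.call(rbind, lapply(ids, function(b) {
    f <- merged$feature[merged$bin_id == b]
    data.frame(bin_id = b,
               n_trna = length(unique(f[startsWith(f, "tRNA-")])),
               has_5S = "rRNA-5S" %in% f,
               has_16S = "rRNA-16S" %in% f,
               has_23S = "rRNA-23S" %in% f,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(bin_id = character(), n_trna = integer(),
                      has_5S = logical(), has_16S = logical(),
                      has_23S = logical())
  out
}

#' Assign MIMAG quality tiers
#'
#' Tiers follow the MIMAG draft-genome standards:
#' * `high` -- contamination < 5, completeness > 90, at least 18 distinct
#'   tRNAs and all of the 5S, 16S and 23S rRNA genes;
#' * `medium` -- contamination < 10 and completeness >= 50;
#' * `low` -- contamination < 10 and completeness < 50;
#' * `contaminated` -- contamination >= 10;
#' * `unevaluated` -- missing metrics (bin too small to score).
#'
#' The RNA criteria apply only to the high tier; a bin failing only the
#' 18-tRNA rule falls to medium, not out of the tier system.
#'
#' @param completeness,contamination numeric vectors, percent.
#' @param n_trna integer vector, distinct tRNAs per bin (default 0).
#' @param has_5S,has_16S,has_23S logical vectors (default FALSE).
#' @return Character vector of tiers.
#' @export
classify_mimag <- function(completeness, contamination, n_trna = 0L,
                           has_5S = FALSE, has_16S = FALSE, has_23S = FALSE) {
  n <- length(completeness)
  n_trna <- rep_len(n_trna, n)
  has_5S <- rep_len(has_5S, n)
  has_16S <- rep_len(has_16S, n)
  has_23S <- rep_len(has_23S, n)
  tier <- rep("contaminated", n)
  tier[contamination < 10 & completeness < 50] <- "low"
  tier[contamination < 10 & completeness >= 50] <- "medium"
  tier[contamination < 5 & completeness > 90 &
         n_trna >= 18L & has_5S & has_16S & has_23S] <- "high"
  tier[is.na(completeness) | is.na(contamination)] <- "unevaluated"
  tier
}

#' Summarize a binning run
#'
#' Counts bins and cumulative bp per size class (10--100 kb, 100--500 kb,
#' > 500 kb) and per MIMAG tier, in the layout of a standard
#' binning-comparison report.
#'
#' @param bins data frame with columns `bin_id`, `total_bp`, `tier`.
#' @return Data frame `group`, `n_bins`, `total_bp`.
#' @export
summarize_run <- function(bins) {
  size_rows <- list(
    c("bins 10-100 kb", 1e4, 1e5),
    c("bins 100-500 kb", 1e5, 5e5),
    c("bins > 500 kb", 5e5, Inf)
  )
  rows <- lapply(size_rows, function(r) {
    sel <- bins$total_bp > as.numeric(r[2]) & bins$total_bp <= as.numeric(r[3])
    data.frame(group = r[1], n_bins = sum(sel),
               total_bp = sum(as.numeric(bins$total_bp[sel])))
  })
  tiers <- c("low", "medium", "high", "contaminated", "unevaluated")
  rows2 <- lapply(tiers, function(t) {
    sel <- !is.na(bins$tier) & bins$tier == t
    data.frame(group = paste0(t, "-quality MAGs"), n_bins = sum(sel),
               total_bp = sum(as.numeric(bins$total_bp[sel])))
  })
  out <- do.call(rbind, c(rows, rows2))
  rownames(out) <- NULL
  out
}
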