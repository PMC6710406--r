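#' Select core communities large enough to evaluate
#'
#' Only CCs with more than `min_bp` of DNA are evaluated for completeness
#' and contamination; the conventional cutoff is 500 kb, roughly the lower
#' bound of a meaningful draft-genome fraction. The inequality is strict:
#' exactly `min_bp` bp is not enough.
#'
#' @param ccs a `core_communities` object.
#' @param min_bp minimum total bp, exclusive (default 500000).
#' @return The `cc_id`s passing the filter, in their original (size) order.
#' @export
select_evaluable <- function(ccs, min_bp = 500000) {
  stopifnot(min_bp >= 0)
  ccs$summary$cc_id[ccs$summary$total_bp > min_bp]
}

#' Validate a bin by contamination
#'
#' A candidate is accepted as a bin (a MAG) when its contamination is
#' strictly under the threshold (default 10%).
#'
#' @param contamination contamination percentage(s).
#' @param contamination_max exclusive upper bound (default 10).
#' @return Logical vector.
#' @export
validate_bin <- function(contamination, contamination_max = 10) {
  contamination < contamination_max
}

#' Recursion configuration
#'
#' Thresholds governing which contaminated CCs are re-partitioned:
#' completeness strictly above `completeness_min` AND contamination strictly
#' above `contamination_min` (defaults 70% and 10%), with
#' `n_recursive_runs` Louvain runs on the CC's sub-network (default 10).
#'
#' @param completeness_min completeness threshold, percent (exclusive).
#' @param contamination_min contamination threshold, percent (exclusive).
#' @param n_recursive_runs number of Louvain runs in the recursion.
#' @return A `recursion_config` list.
#' @export
recursion_config <- function(completeness_min = 70, contamination_min = 10,
                             n_recursive_runs = 10L) {
  stopifnot(completeness_min >= 0, contamination_min >= 0, n_recursive_runs >= 1L)
  structure(list(completeness_min = completeness_min,
                 contamination_min = contamination_min,
                 n_recursive_runs = as.integer(n_recursive_runs)),
            class = "recursion_config")
}

#' Select contaminated candidates for recursive partitioning
#'
#' High-completeness, high-contamination CCs typically pool several related
#' genomes bridged by conserved sequence; those are the ones worth
#' re-partitioning.
#'
#' @param candidates data frame with columns `bin_id`, `completeness`,
#'   `contamination` (percent).
#' @param cfg a [recursion_config()].
#' @return The subset of `candidates` selected for recursion.
#' @export
select_for_recursion <- function(candidates, cfg = recursion_config()) {
  keep <- !is.na(candidates$completeness) & !is.na(candidates$contamination) &
    candidates$completeness > cfg$completeness_min &
    candidates$contamination > cfg$contamination_min
  candidates[keep, , drop = FALSE]
}

#' Recursively partition one contaminated core community
#'
#' Re-runs the partition step -- `cfg$n_recursive_runs` seeded Louvain runs
#' followed by the core-community meet over all of them -- on the CC's
#' sub-network only. The resulting sub-CCs are returned with ids
#' `"<cc_id>.<k>"`, numbered by decreasing total bp. Membership never leaves
#' the parent: the union of sub-CC members equals the parent's members.
#'
#' @param net the full `contact_network` (the sub-network is extracted here).
#' @param ccs the `core_communities` the parent belongs to.
#' @param cc_id id of the CC to deconvolve.
#' @param cfg a [recursion_config()].
#' @param seed base seed for the recursive runs.
#' @return A list with `membership` (data frame `contig_id`, `bin_id`) and
#'   `summary` (data frame `bin_id`, `n_contigs`, `total_bp`).
#' @export
recursive_partition <- function(net, ccs, cc_id, cfg = recursion_config(),
                                seed = 1L) {
  members <- cc_members(ccs, cc_id)
  sub <- subset_network(net, members)
  if (nrow(sub$edges) == 0L) {
    warning("sub-network of CC ", cc_id, " has no edges; returning singleton sub-CCs")
    sub_m <- data.frame(contig_id = sort(members),
                        sub = seq_along(members), stringsAsFactors = FALSE)
    len <- stats::setNames(net$contigs$length, net$contigs$id)
    bp <- as.numeric(len[sub_m$contig_id])
    ord <- order(-bp, sub_m$contig_id)
    sub_m$sub[ord] <- seq_along(ord)
  } else {
    parts <- iterate_louvain(sub, n_runs = cfg$n_recursive_runs, base_seed = seed)
    sub_ccs <- core_communities(parts, catalog = sub$contigs)
    sub_m <- data.frame(contig_id = sub_ccs$membership$contig_id,
                        sub = sub_ccs$membership$cc_id,
                        stringsAsFactors = FALSE)
  }
  sub_m$bin_id <- paste(cc_id, sub_m$sub, sep = ".")
  len <- stats::setNames(as.numeric(net$contigs$length), net$contigs$id)
  bp_by_bin <- vapply(split(len[sub_m$contig_id], sub_m$bin_id), sum, numeric(1))
  agg <- data.frame(
    bin_id = names(bp_by_bin),
    n_contigs = as.integer(table(sub_m$bin_id)[names(bp_by_bin)]),
    total_bp = unname(bp_by_bin),
    stringsAsFactors = FALSE
  )
  agg <- agg[order(-agg$total_bp, agg$bin_id), , drop = FALSE]
  rownames(agg) <- NULL
  list(membership = sub_m[, c("contig_id", "bin_id")], summary = agg)
}

#' Assemble the final bin set
#'
#' Final bins are the primary CCs that were not sent to recursion plus all
#' sub-CCs produced by the recursion. The result must remain a partition of
#' the binned contigs: any contig appearing in two bins is an error.
#'
#' @param primary data frame `contig_id`, `bin_id` for primary CCs (those
#'   selected for recursion already removed).
#' @param recursive data frame `contig_id`, `bin_id` for all sub-CCs (may be
#'   empty).
#' @return Data frame `contig_id`, `bin_id`, `origin` (`"primary"` or
#'   `"recursive"`).
#' @export
finalize_bins <- function(primary, recursive = NULL) {
  primary$origin <- if (nrow(primary)) "primary" else character(0)
  if (!is.null(recursive) && nrow(recursive)) {
    recursive$origin <- "recursive"
    out <- rbind(primary[, c("contig_id", "bin_id", "origin")],
                 recursive[, c("contig_id", "bin_id", "origin")])
  } else {
    out <- primary[, c("contig_id", "bin_id", "origin")]
  }
  if (anyDuplicated(out$contig_id))
    stop("finalize_bins: a contig appears in more than one final bin")
  rownames(out) <- NULL
  out
}
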