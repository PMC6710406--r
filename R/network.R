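#' Contact networks
#'
#' A contact network is an undirected weighted graph whose nodes are the
#' contigs of a catalog and whose edges count proximity-ligation read pairs
#' bridging two different contigs. Raw pair counts are kept alongside the
#' coverage-normalized weights so either can be inspected or re-derived.
#'
#' @name contact_network
#' @keywords internal
NULL

new_contact_network <- function(contigs, edges, total_pairs_used, drops = integer()) {
  stopifnot(inherits(contigs, "contig_catalog"))
  structure(
    list(contigs = contigs, edges = edges,
         total_pairs_used = total_pairs_used, drops = drops),
    class = "contact_network"
  )
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf(
    "<contact_network> %d contigs, %d edges, %s read pairs used%s\n",
    nrow(x$contigs), nrow(x$edges),
    format(x$total_pairs_used, big.mark = ","),
    if (all(is.na(x$edges$weight))) " (unnormalized)" else ""
  ))
  invisible(x)
}

#' Build the raw contact network from contig pairs
#'
#' Tallies each unordered contig pair emitted by [pair_reads()] into an edge
#' whose `raw_count` is the pair's multiplicity in the stream. Pairs touching
#' contigs absent from the (filtered) catalog are dropped with a warning and
#' counted; self pairs are excluded defensively. Contigs with no inter-contig
#' pair remain in the catalog as isolated nodes.
#'
#' @param pairs data frame with columns `contig_a`, `contig_b`, one row per
#'   read pair (order within a row is irrelevant).
#' @param catalog the [contig_catalog()] defining the node universe.
#' @return A `contact_network`; weights are `NA` until [normalize_network()].
#' @export
build_network <- function(pairs, catalog) {
  stopifnot(all(c("contig_a", "contig_b") %in% names(pairs)))
  ca <- pmin(as.character(pairs$contig_a), as.character(pairs$contig_b))
  cb <- pmax(as.character(pairs$contig_a), as.character(pairs$contig_b))
  known <- ca %in% catalog$id & cb %in% catalog$id
  n_unknown <- sum(!known)
  if (n_unknown > 0L)
    warning(n_unknown, " pairs reference contigs absent from the catalog; dropped")
  self <- known & ca == cb
  keep <- known & !self
  key <- paste(ca[keep], cb[keep], sep = "\r")
  tab <- table(key)
  split_key <- strsplit(as.character(names(tab)), "\r", fixed = TRUE)
  edges <- data.frame(
    contig_a = vapply(split_key, `[`, "", 1L),
    contig_b = vapply(split_key, `[`, "", 2L),
    raw_count = as.integer(tab),
    weight = rep(NA_real_, length(tab)),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$contig_a, edges$contig_b), , drop = FALSE]
  rownames(edges) <- NULL
  new_contact_network(
    catalog, edges,
    total_pairs_used = sum(keep),
    drops = c(unknown_contig = n_unknown, self_pair = sum(self))
  )
}

#' Normalize edge weights by geometric-mean coverage
#'
#' Sets each edge weight to `raw_count / sqrt(coverage_a * coverage_b)`.
#' Dividing by the geometric mean of the two endpoint coverages removes the
#' abundance component of the contact signal, so that contigs from the same
#' genome end up with comparable weights whatever the genome's read depth.
#' The normalization is undefined when an endpoint has zero coverage; such
#' edges are dropped with a warning rather than patched with a pseudo-count.
#'
#' @param net a `contact_network` whose catalog carries coverages.
#' @return The network with weights filled in; raw counts are preserved.
#' @export
normalize_network <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  cov <- stats::setNames(net$contigs$coverage, net$contigs$id)
  ca <- cov[net$edges$contig_a]
  cb <- cov[net$edges$contig_b]
  zero <- ca <= 0 | cb <= 0
  if (any(zero))
    warning(sum(zero), " edges touch a zero-coverage contig; dropped")
  edges <- net$edges[!zero, , drop = FALSE]
  edges$weight <- edges$raw_count / sqrt(ca[!zero] * cb[!zero])
  rownames(edges) <- NULL
  net$edges <- edges
  net$drops <- c(net$drops, zero_coverage_edge = sum(zero))
  net
}

#' Convert a contact network to an igraph graph
#'
#' Nodes are all catalog contigs (isolated contigs included); edge weights
#' are the normalized weights when available, otherwise the raw counts.
#'
#' @param net a `contact_network`.
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  w <- net$edges$weight
  if (all(is.na(w))) w <- net$edges$raw_count
  el <- net$edges[, c("contig_a", "contig_b")]
  g <- igraph::graph_from_data_frame(
    cbind(el, weight = w),
    directed = FALSE,
    vertices = net$contigs$id
  )
  g
}

#' Restrict a network to a subset of contigs
#'
#' Keeps only the named contigs and the edges internal to them; used to
#' extract the sub-network of a core community for recursive partitioning.
#'
#' @param net a `contact_network`.
#' @param contig_ids character vector of member contig ids.
#' @return A `contact_network` over the subset.
#' @export
subset_network <- function(net, contig_ids) {
  stopifnot(inherits(net, "contact_network"))
  contigs <- net$contigs[net$contigs$id %in% contig_ids, , drop = FALSE]
  rownames(contigs) <- NULL
  class(contigs) <- c("contig_catalog", "data.frame")
  keep <- net$edges$contig_a %in% contig_ids & net$edges$contig_b %in% contig_ids
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_contact_network(contigs, edges,
                      total_pairs_used = sum(edges$raw_count))
}
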