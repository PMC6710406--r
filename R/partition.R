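#' One seeded Louvain run
#'
#' Runs greedy weighted modularity optimization (Louvain: local node moves
#' that maximize the Newman--Girvan modularity gain, then graph aggregation,
#' repeated to convergence) on the contact network. The node visit order is
#' randomized, so different seeds explore different local optima; a fixed
#' seed gives a fully reproducible labeling. Isolated contigs come out as
#' singleton communities.
#'
#' @param net a `contact_network` with at least one node; normalized weights
#'   are used when present, raw counts otherwise.
#' @param seed integer seed for this run.
#' @return A `louvain_partition`: list with `labels` (named integer vector,
#'   one community label per contig), `modularity` (Newman--Girvan Q of the
#'   labeling), `seed`, and `run_id` (NA for a standalone run).
#' @export
louvain_once <- function(net, seed) {
  stopifnot(inherits(net, "contact_network"))
  if (nrow(net$contigs) == 0L) stop("cannot partition an empty network")
  g <- as_igraph(net)
  labels <- withr_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = 1)
    igraph::membership(cl)
  })
  labels <- stats::setNames(as.integer(labels), igraph::V(g)$name)
  q <- if (igraph::ecount(g) > 0L)
    igraph::modularity(g, labels, weights = igraph::E(g)$weight)
  else 0
  structure(
    list(run_id = NA_integer_, seed = as.integer(seed),
         labels = labels, modularity = q),
    class = "louvain_partition"
  )
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.louvain_partition <- function(x, ...) {
  cat(sprintf("<louvain_partition> %d contigs, %d communities, Q = %.4f\n",
              length(x$labels), length(unique(x$labels)), x$modularity))
  invisible(x)
}

#' Iterate Louvain runs with derived seeds
#'
#' Repeats [louvain_once()] `n_runs` times with seeds `base_seed + 0 ..
#' base_seed + n_runs - 1`, so any individual run can be re-created in
#' isolation. The stochastic node order makes runs land in different local
#' optima; downstream, contigs that co-cluster in *every* run form the core
#' communities.
#'
#' @param net a `contact_network`.
#' @param n_runs number of independent runs (default 100; classically up to
#'   400 are run and the first 100 pooled).
#' @param base_seed integer; seed of run `i` is `base_seed + i - 1`.
#' @return A list of `louvain_partition` objects with `run_id` set.
#' @export
iterate_louvain <- function(net, n_runs = 100L, base_seed = 1L) {
  stopifnot(n_runs >= 1L)
  lapply(seq_len(n_runs), function(i) {
    p <- louvain_once(net, seed = base_seed + i - 1L)
    p$run_id <- i
    p
  })
}

#' Core communities: the meet of Louvain partitions
#'
#' Two contigs share a core community (CC) if and only if they carry a
#' common community label in all of the first `n_use` runs -- the CCs are
#' the common refinement (meet) of those partitions. CC ids are assigned by
#' decreasing total bp (ties broken by the lexicographically smallest member
#' contig id), so CC 1 is always the largest community by DNA content.
#'
#' @param partitions list of `louvain_partition` objects over one contig set.
#' @param n_use number of leading partitions to intersect (default: all).
#' @param catalog the [contig_catalog()] supplying member lengths.
#' @return A `core_communities` object: list with `membership` (data frame
#'   `contig_id`, `cc_id`) and `summary` (data frame `cc_id`, `n_contigs`,
#'   `total_bp`, ordered by `cc_id`).
#' @export
core_communities <- function(partitions, n_use = length(partitions), catalog) {
  if (n_use < 1L) stop("n_use must be >= 1")
  if (n_use > length(partitions)) stop("n_use exceeds the number of partitions")
  ids <- names(partitions[[1L]]$labels)
  lab <- vapply(partitions[seq_len(n_use)], function(p) {
    stopifnot(setequal(names(p$labels), ids))
    as.integer(unname(p$labels[ids]))
  }, integer(length(ids)))
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = length(ids))
  key <- do.call(paste, c(as.data.frame(lab), sep = "\r"))
  grp <- match(key, unique(key))

  len <- stats::setNames(catalog$length, catalog$id)[ids]
  total_bp <- vapply(split(as.numeric(len), grp), sum, numeric(1))
  min_id <- vapply(split(ids, grp), min, character(1))
  ord <- order(-total_bp, min_id)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  cc_id <- rank[grp]

  membership <- data.frame(contig_id = ids, cc_id = cc_id,
                           stringsAsFactors = FALSE)
  n_contigs <- as.integer(table(factor(cc_id, levels = seq_along(ord))))
  summary <- data.frame(
    cc_id = seq_along(ord),
    n_contigs = n_contigs,
    total_bp = as.numeric(total_bp[ord])
  )
  structure(list(membership = membership, summary = summary, n_use = n_use),
            class = "core_communities")
}

#' @export
print.core_communities <- function(x, ...) {
  cat(sprintf("<core_communities> %d CCs over %d contigs (meet of %d runs)\n",
              nrow(x$summary), nrow(x$membership), x$n_use))
  invisible(x)
}

#' Contig ids of one core community
#' @param ccs a `core_communities` object.
#' @param cc_id community id.
#' @return Character vector of member contig ids.
#' @export
cc_members <- function(ccs, cc_id) {
  ccs$membership$contig_id[ccs$membership$cc_id == cc_id]
}

#' Co-clustering scores between core communities
#'
#' For every pair of CCs, the score is the number of runs in which the two
#' CCs' contigs carried one common label. By construction each CC is
#' label-uniform within every run, so a single representative contig per CC
#' suffices. High scores between distinct CCs flag communities that the
#' clustering hesitates to merge -- often related genomes sharing sequence.
#'
#' @param partitions the run partitions the CCs were derived from.
#' @param ccs the `core_communities` object.
#' @return Data frame `cc_a`, `cc_b` (cc_a < cc_b), `score` in 0..n_use.
#' @export
co_cluster_scores <- function(partitions, ccs) {
  n_use <- ccs$n_use
  reps <- ccs$membership$contig_id[!duplicated(ccs$membership$cc_id)]
  rep_cc <- ccs$membership$cc_id[!duplicated(ccs$membership$cc_id)]
  ord <- order(rep_cc)
  reps <- reps[ord]
  k <- length(reps)
  if (k < 2L) {
    return(data.frame(cc_a = integer(), cc_b = integer(), score = integer()))
  }
  score <- matrix(0L, k, k)
  for (r in seq_len(n_use)) {
    l <- partitions[[r]]$labels[reps]
    score <- score + outer(l, l, "==")
  }
  iu <- which(upper.tri(score), arr.ind = TRUE)
  data.frame(
    cc_a = sort(rep_cc)[iu[, 1L]],
    cc_b = sort(rep_cc)[iu[, 2L]],
    score = score[iu]
  )
}
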