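#' Synthetic community specification
#'
#' Parameters of the ground-truthed community generator. The generator
#' emulates the one property proximity-ligation binning rests on: contigs of
#' the same genome (the same cells) contact each other far more often than
#' contigs of different genomes. Expected pair counts scale with the contig
#' length product and the geometric mean of the endpoint coverages, so that
#' coverage normalization approximately flattens intra-genome weights and
#' the planted structure is analytically predictable.
#'
#' The expected pair count for contigs a, b is
#' `rate * (len_a/1e4) * (len_b/1e4) * sqrt(cov_a * cov_b) / mean_depth`,
#' with `rate = intra_rate` when the contigs share a genome and `inter_rate`
#' otherwise; counts are Poisson. Lengths enter in units of 10 kb and the
#' coverage term is scaled by the community mean depth so the named rates
#' are of order 1 per contig pair.
#'
#' @param n_genomes number of genomes (default 10).
#' @param contigs_per_genome contigs per genome (default 50).
#' @param length_meanlog,length_sdlog lognormal contig-length parameters in
#'   bp (defaults give a median near 15 kb; minimum length 100 bp).
#' @param abundance_sdlog spread of per-genome relative abundances
#'   (lognormal, then normalized to sum to 1).
#' @param mean_depth community-average read depth (default 50x).
#' @param coverage_sdlog multiplicative per-contig coverage noise.
#' @param intra_rate expected pairs per same-genome contig pair at reference
#'   length/depth (default 5).
#' @param inter_rate cross-genome noise rate (default 0.05; intra/inter
#'   ratio 100).
#' @param shared_contig_frac fraction of contigs additionally placed in a
#'   second genome, emulating mobile/conserved elements (default 0).
#' @param marker_set_size size of the universal single-copy marker set
#'   (default 100).
#' @param n_trna distinct tRNA isotypes per genome (default 20).
#' @param seed integer seed; all generator randomness flows from it.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 10L, contigs_per_genome = 50L,
                           length_meanlog = log(15000), length_sdlog = 0.6,
                           abundance_sdlog = 0.5, mean_depth = 50,
                           coverage_sdlog = 0.25,
                           intra_rate = 5, inter_rate = 0.05,
                           shared_contig_frac = 0,
                           marker_set_size = 100L, n_trna = 20L,
                           seed = 1L) {
  stopifnot(n_genomes >= 1L, contigs_per_genome >= 1L,
            intra_rate >= 0, inter_rate >= 0,
            shared_contig_frac >= 0, shared_contig_frac <= 1,
            marker_set_size >= 1L)
  if (intra_rate <= inter_rate)
    stop("intra_rate must exceed inter_rate for planted structure to exist")
  structure(as.list(environment()), class = "community_spec")
}

#' Simulate a contig catalog with ground truth
#'
#' Draws contig lengths from the spec's lognormal, assigns per-genome
#' abundances, and sets coverage proportional to the (summed) abundance of
#' a contig's host genome(s) times the mean depth, with multiplicative
#' lognormal noise. A `shared_contig_frac` fraction of contigs is placed in
#' a second genome as well, so the truth table can carry multiple labels per
#' contig. Deterministic given `spec$seed`.
#'
#' @param spec a [community_spec()].
#' @return List with `catalog` (a [contig_catalog()]) and `truth`, a data
#'   frame `contig_id`, `genome` with one row per (contig, host genome).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr_seed(spec$seed, {
    g <- spec$n_genomes
    k <- spec$contigs_per_genome
    genome <- rep(sprintf("G%02d", seq_len(g)), each = k)
    id <- sprintf("%s_c%03d", genome, rep(seq_len(k), times = g))
    len <- pmax(100L, as.integer(round(
      stats::rlnorm(g * k, spec$length_meanlog, spec$length_sdlog))))
    ab <- stats::rlnorm(g, 0, spec$abundance_sdlog)
    ab <- ab / sum(ab)
    names(ab) <- sprintf("G%02d", seq_len(g))

    truth <- data.frame(contig_id = id, genome = genome,
                        stringsAsFactors = FALSE)
    n_shared <- round(spec$shared_contig_frac * g * k)
    if (n_shared > 0L && g > 1L) {
      pick <- sample(seq_along(id), n_shared)
      other <- vapply(genome[pick], function(h) {
        sample(setdiff(names(ab), h), 1L)
      }, character(1))
      truth <- rbind(truth, data.frame(contig_id = id[pick], genome = other,
                                       stringsAsFactors = FALSE))
    }
    host_ab <- vapply(split(ab[truth$genome], truth$contig_id), sum, numeric(1))
    cov <- unname(host_ab[id]) * g * spec$mean_depth *
      stats::rlnorm(g * k, -spec$coverage_sdlog^2 / 2, spec$coverage_sdlog)
    list(catalog = contig_catalog(id, len, cov),
         truth = truth[order(truth$contig_id, truth$genome), , drop = FALSE])
  })
}

# expected Poisson pair count for one contig pair under a spec
pair_rate <- function(rate, len_a, len_b, cov_a, cov_b, mean_depth) {
  rate * (len_a / 1e4) * (len_b / 1e4) * sqrt(cov_a * cov_b) / mean_depth
}

#' Simulate proximity-ligation contig pairs
#'
#' Draws a Poisson count of read pairs for every unordered contig pair at
#' the intra-genome rate when the contigs share at least one host genome and
#' at the inter-genome noise rate otherwise, then expands the counts into
#' one row per pair. Deterministic given `seed` (defaults to the spec's).
#'
#' @param catalog,truth output of [simulate_community()].
#' @param spec the [community_spec()].
#' @param seed seed for the pair draws (default `spec$seed + 1`).
#' @return Data frame `contig_a`, `contig_b` with one row per simulated
#'   read pair.
#' @export
simulate_pairs <- function(catalog, truth, spec, seed = spec$seed + 1L) {
  n <- nrow(catalog)
  if (n < 2L) return(data.frame(contig_a = character(), contig_b = character()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  hosts <- split(truth$genome, truth$contig_id)[catalog$id]
  same <- mapply(function(a, b) any(a %in% b), hosts[i], hosts[j])
  rate <- ifelse(same, spec$intra_rate, spec$inter_rate)
  lam <- pair_rate(rate, catalog$length[i], catalog$length[j],
                   catalog$coverage[i], catalog$coverage[j], spec$mean_depth)
  cnt <- withr_seed(seed, stats::rpois(length(lam), lam))
  keep <- cnt > 0L
  data.frame(
    contig_a = rep(catalog$id[i][keep], cnt[keep]),
    contig_b = rep(catalog$id[j][keep], cnt[keep]),
    stringsAsFactors = FALSE
  )
}

#' Expand contig pairs into single-end alignment records
#'
#' Converts a pair table into the per-mate record layout of [pair_reads()],
#' optionally corrupting a fraction of records with low mapping quality or
#' an ambiguity flag to exercise the alignment filters.
#'
#' @param pairs data frame `contig_a`, `contig_b`.
#' @param low_mapq_frac fraction of records emitted with mapq below 20.
#' @param ambiguous_frac fraction of records flagged ambiguous.
#' @param read_len read length to attach (default 65 bp).
#' @param seed seed for the corruption draws.
#' @return Data frame of alignment records (`read_id`, `mate`, `contig_id`,
#'   `position`, `mapq`, `ambiguous`, `read_len`).
#' @export
pairs_to_alignments <- function(pairs, low_mapq_frac = 0, ambiguous_frac = 0,
                                read_len = 65L, seed = 1L) {
  n <- nrow(pairs)
  withr_seed(seed, {
    rec <- data.frame(
      read_id = rep(sprintf("r%07d", seq_len(n)), 2L),
      mate = rep(c(1L, 2L), each = n),
      contig_id = c(pairs$contig_a, pairs$contig_b),
      position = 0L,
      mapq = 42L,
      ambiguous = FALSE,
      read_len = as.integer(read_len),
      stringsAsFactors = FALSE
    )
    m <- nrow(rec)
    low <- stats::runif(m) < low_mapq_frac
    rec$mapq[low] <- sample(0:19, sum(low), replace = TRUE)
    rec$ambiguous <- stats::runif(m) < ambiguous_frac
    rec
  })
}

#' Simulate marker and RNA annotations
#'
#' Gives every genome one copy of each marker in a universal single-copy
#' set, distributed round-robin over the genome's contigs, and likewise
#' distributes the genome's tRNA isotypes and the three rRNA genes. Shared
#' contigs receive annotations from each of their host genomes, so a bin
#' holding one whole genome scores (100, 0) and a bin holding two whole
#' genomes scores (100, 100).
#'
#' @param truth the truth table from [simulate_community()].
#' @param spec the [community_spec()].
#' @return List with `markers` (a [marker_table()]) and `rna` (data frame
#'   `contig_id`, `feature`).
#' @export
simulate_annotations <- function(truth, spec) {
  marker_ids <- sprintf("M%03d", seq_len(spec$marker_set_size))
  feats <- c(sprintf("tRNA-%02d", seq_len(spec$n_trna)),
             "rRNA-5S", "rRNA-16S", "rRNA-23S")
  per_genome <- split(truth$contig_id, truth$genome)
  hit_list <- lapply(per_genome, function(contigs) {
    contigs <- sort(contigs)
    data.frame(
      contig_id = contigs[(seq_along(marker_ids) - 1L) %% length(contigs) + 1L],
      marker_id = marker_ids,
      copies = 1L,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, hit_list)
  # collapse multiple copies of one marker landing on one contig
  key <- paste(hits$contig_id, hits$marker_id, sep = "\r")
  copies <- vapply(split(hits$copies, key), sum, integer(1))
  parts <- strsplit(names(copies), "\r", fixed = TRUE)
  hits <- data.frame(
    contig_id = vapply(parts, `[`, "", 1L),
    marker_id = vapply(parts, `[`, "", 2L),
    copies = unname(copies),
    stringsAsFactors = FALSE
  )
  rna_list <- lapply(per_genome, function(contigs) {
    contigs <- sort(contigs)
    data.frame(
      contig_id = contigs[(seq_along(feats) - 1L) %% length(contigs) + 1L],
      feature = feats,
      stringsAsFactors = FALSE
    )
  })
  rna <- unique(do.call(rbind, rna_list))
  rownames(rna) <- NULL
  list(markers = marker_table(marker_ids, hits), rna = rna)
}

#' Random contig sequences for a catalog
#'
#' Generates uniform-random DNA of each contig's stated length, for writing
#' FASTA output; sequence content is a placeholder, only ids and lengths are
#' meaningful.
#'
#' @param catalog a [contig_catalog()].
#' @param seed seed for the draws.
#' @return Named character vector of sequences.
#' @export
simulate_sequences <- function(catalog, seed = 1L) {
  withr_seed(seed, {
    stats::setNames(vapply(catalog$length, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1)), catalog$id)
  })
}
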