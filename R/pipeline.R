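#' Run the full binning pipeline
#'
#' Chains the stages end to end: contig filtering and network construction
#' from read pairs ([align]), iterated Louvain partitioning into core
#' communities ([partition]), size selection, marker scoring, recursion on
#' contaminated CCs and final bin assembly ([binning]), then MIMAG tier
#' assignment and the summary report ([quality]). Every intermediate is
#' written to `out_dir` together with a JSON manifest recording the
#' configuration, seeds, and per-stage record counts, so every number in
#' the summary can be recomputed from the written files. A failure aborts
#' with the stage named.
#'
#' @param config a [pipeline_config()].
#' @param catalog a [contig_catalog()] (lengths and coverages known).
#' @param pairs data frame `contig_a`, `contig_b` of read pairs, or a list
#'   as returned by [pair_reads()] (its drop counts then enter the
#'   manifest), or a path to a pairs TSV for [read_pairs_tsv()].
#' @param markers a [marker_table()], or `NULL` to skip quality scoring.
#' @param rna per-contig RNA features for [aggregate_rna()], or `NULL`.
#' @param out_dir output directory, created if needed.
#' @param seqs optional named character vector of contig sequences; when
#'   given, per-bin FASTA files are written under `out_dir/bins/`.
#' @return Invisibly, a list with the final `bins` table (contig level), the
#'   per-bin `quality` table, the `summary` report and the `manifest`.
#' @export
run_pipeline <- function(config, catalog, pairs, markers = NULL, rna = NULL,
                         out_dir, seqs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] stage failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(
    tool = "proxibin", version = as.character(utils::packageVersion("proxibin")),
    config = unclass(config)
  )

  # ---- [align] -------------------------------------------------------------
  net <- stage("align", {
    drops <- NULL
    if (is.character(pairs)) {
      if (!file.exists(pairs)) stop("pairs file not found: ", pairs)
      paired <- pair_reads(read_pairs_tsv(pairs), mapq_threshold = config$min_mapq)
      drops <- paired$drops
      pairs <- paired$pairs
    } else if (is.list(pairs) && !is.data.frame(pairs)) {
      drops <- pairs$drops
      pairs <- pairs$pairs
    }
    cat_f <- filter_contigs(catalog, config$min_contig_len)
    n <- suppressWarnings(build_network(pairs, cat_f))
    manifest$align <- list(
      contigs_in = nrow(catalog), contigs_kept = nrow(cat_f),
      pairs_in = nrow(pairs), pairs_used = n$total_pairs_used,
      read_filter_drops = as.list(drops), network_drops = as.list(n$drops)
    )
    normalize_network(n)
  })
  write_network(net, file.path(out_dir, "network.txt"))

  # ---- [partition] ---------------------------------------------------------
  parts <- stage("partition", iterate_louvain(net, n_runs = config$iterations,
                                              base_seed = config$seed))
  ccs <- stage("partition",
               core_communities(parts, n_use = config$use_iterations,
                                catalog = net$contigs))
  run_tab <- do.call(rbind, lapply(parts, function(p) {
    data.frame(contig_id = names(p$labels), run_id = p$run_id,
               label = unname(p$labels), stringsAsFactors = FALSE)
  }))
  utils::write.table(run_tab, file.path(out_dir, "partitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ccs$membership, file.path(out_dir, "cc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  size_class <- cut(ccs$summary$total_bp, c(-Inf, 1e4, 1e5, 5e5, Inf),
                    labels = c("<10kb", "10-100kb", "100-500kb", ">500kb"))
  manifest$partition <- list(
    runs = config$iterations, runs_used = config$use_iterations,
    n_ccs = nrow(ccs$summary),
    ccs_by_size = as.list(table(size_class)),
    modularity_mean = mean(vapply(parts, `[[`, numeric(1), "modularity"))
  )

  # ---- [binning] -----------------------------------------------------------
  res <- stage("binning", {
    evaluable <- select_evaluable(ccs, config$cc_min_bp)
    qual <- NULL
    if (!is.null(markers) && length(evaluable)) {
      sc <- t(vapply(evaluable, function(cc)
        score_bin(cc_members(ccs, cc), markers), numeric(2)))
      qual <- data.frame(bin_id = as.character(evaluable),
                         completeness = sc[, 1L], contamination = sc[, 2L],
                         stringsAsFactors = FALSE)
    }
    rec_cfg <- recursion_config(config$rec_completeness,
                                config$rec_contamination,
                                config$rec_iterations)
    rec_ids <- character(0)
    rec_membership <- NULL
    if (!is.null(qual)) {
      sel <- select_for_recursion(qual, rec_cfg)
      rec_ids <- sel$bin_id
      if (length(rec_ids)) {
        rec_list <- lapply(rec_ids, function(cc)
          recursive_partition(net, ccs, as.integer(cc), rec_cfg,
                              seed = config$seed + config$iterations +
                                as.integer(cc) * rec_cfg$n_recursive_runs))
        rec_membership <- do.call(rbind, lapply(rec_list, `[[`, "membership"))
      }
    }
    primary <- ccs$membership
    names(primary) <- c("contig_id", "bin_id")
    primary$bin_id <- as.character(primary$bin_id)
    primary <- primary[!(primary$bin_id %in% rec_ids), , drop = FALSE]
    bins <- finalize_bins(primary, rec_membership)
    list(bins = bins, recursed = rec_ids, primary_quality = qual)
  })
  utils::write.table(res$bins, file.path(out_dir, "bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$binning <- list(n_bins = length(unique(res$bins$bin_id)),
                           recursed_ccs = as.list(res$recursed))

  # ---- [quality] -----------------------------------------------------------
  quality <- stage("quality", {
    len <- stats::setNames(as.numeric(catalog$length), catalog$id)
    bp <- vapply(split(len[res$bins$contig_id], res$bins$bin_id), sum, numeric(1))
    q <- data.frame(bin_id = names(bp),
                    total_bp = unname(bp),
                    origin = res$bins$origin[match(names(bp), res$bins$bin_id)],
                    completeness = NA_real_, contamination = NA_real_,
                    n_trna = NA_integer_, has_5S = NA, has_16S = NA, has_23S = NA,
                    stringsAsFactors = FALSE)
    if (!is.null(markers)) {
      evalq <- q$total_bp > config$cc_min_bp
      if (any(evalq)) {
        sc <- t(vapply(q$bin_id[evalq], function(b)
          score_bin(res$bins$contig_id[res$bins$bin_id == b], markers),
          numeric(2)))
        q$completeness[evalq] <- sc[, 1L]
        q$contamination[evalq] <- sc[, 2L]
      }
    }
    if (!is.null(rna)) {
      ag <- aggregate_rna(res$bins, rna)
      i <- match(q$bin_id, ag$bin_id)
      q$n_trna <- ag$n_trna[i]
      q$has_5S <- ag$has_5S[i]; q$has_16S <- ag$has_16S[i]; q$has_23S <- ag$has_23S[i]
    }
    q$valid <- validate_bin(q$contamination, config$contamination_max)
    q$tier <- classify_mimag(q$completeness, q$contamination,
                             ifelse(is.na(q$n_trna), 0L, q$n_trna),
                             isTRUE_v(q$has_5S), isTRUE_v(q$has_16S),
                             isTRUE_v(q$has_23S))
    q[order(-q$total_bp, q$bin_id), , drop = FALSE]
  })
  utils::write.table(quality, file.path(out_dir, "quality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- summarize_run(quality)
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$quality <- list(
    n_evaluated = sum(!is.na(quality$completeness)),
    tiers = as.list(table(quality$tier))
  )
  if (!is.null(seqs)) {
    write_bin_fasta(seqs, res$bins, file.path(out_dir, "bins"))
  }
  write_config(config, file.path(out_dir, "config.txt"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bins = res$bins, quality = quality, summary = summary,
                 manifest = manifest))
}

# vectorized NA-safe truthiness
isTRUE_v <- function(x) !is.na(x) & x
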