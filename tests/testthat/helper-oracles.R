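# Independent brute-force oracles. These deliberately share no code with the
# package: loops and dictionaries only, so they can arbitrate the vectorized
# implementations.

# filter read pairs one by one, mirroring the filtering rules literally
bf_pair_filter <- function(alignments, mapq_threshold = 20L) {
  by_read <- split(seq_len(nrow(alignments)), alignments$read_id)
  out <- list()
  drops <- c(ambiguous = 0L, low_mapq = 0L, unmatched = 0L, same_contig = 0L)
  for (idx in by_read) {
    if (length(idx) == 1L) { drops["unmatched"] <- drops["unmatched"] + 1L; next }
    if (length(idx) > 2L) { drops["ambiguous"] <- drops["ambiguous"] + 1L; next }
    a <- alignments[idx[1L], ]; b <- alignments[idx[2L], ]
    if (a$mate == b$mate || isTRUE(a$ambiguous) || isTRUE(b$ambiguous)) {
      drops["ambiguous"] <- drops["ambiguous"] + 1L; next
    }
    if (a$mapq < mapq_threshold || b$mapq < mapq_threshold) {
      drops["low_mapq"] <- drops["low_mapq"] + 1L; next
    }
    if (a$contig_id == b$contig_id) {
      drops["same_contig"] <- drops["same_contig"] + 1L; next
    }
    out[[length(out) + 1L]] <- sort(c(a$contig_id, b$contig_id))
  }
  pairs <- if (length(out)) do.call(rbind, out) else matrix(character(), 0, 2)
  list(pairs = data.frame(contig_a = pairs[, 1], contig_b = pairs[, 2],
                          stringsAsFactors = FALSE),
       drops = drops)
}

# tally raw counts pair by pair in a hash, then normalize by hand
bf_network <- function(pairs, catalog) {
  env <- new.env(hash = TRUE)
  used <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$contig_a[r]; b <- pairs$contig_b[r]
    if (!(a %in% catalog$id) || !(b %in% catalog$id) || a == b) next
    key <- paste(min(a, b), max(a, b), sep = "|")
    env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    used <- used + 1L
  }
  keys <- ls(env)
  cov <- stats::setNames(catalog$coverage, catalog$id)
  rows <- lapply(keys, function(k) {
    ab <- strsplit(k, "|", fixed = TRUE)[[1L]]
    w <- if (cov[ab[1]] > 0 && cov[ab[2]] > 0)
      env[[k]] / sqrt(cov[ab[1]] * cov[ab[2]]) else NA_real_
    data.frame(contig_a = ab[1], contig_b = ab[2], raw_count = env[[k]],
               weight = w, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_a = character(), contig_b = character(),
               raw_count = integer(), weight = numeric())
  out <- out[order(out$contig_a, out$contig_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs_used") <- used
  out
}

# O(n^2 * runs) pairwise co-membership closure: i and j share a group iff
# their labels agree in every run; groups recovered by row-scanning the
# boolean co-membership matrix
bf_meet <- function(label_matrix) {
  n <- nrow(label_matrix)
  same <- matrix(TRUE, n, n)
  for (r in seq_len(ncol(label_matrix))) {
    l <- label_matrix[, r]
    same <- same & outer(l, l, "==")
  }
  grp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      next_id <- next_id + 1L
      grp[which(same[i, ])] <- next_id
    }
  }
  grp
}

# random partitions of `ids` into up to k parts
random_partitions <- function(ids, n_runs, k, seed) {
  set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    structure(list(run_id = r, seed = NA_integer_,
                   labels = stats::setNames(sample.int(k, length(ids), replace = TRUE), ids),
                   modularity = NA_real_),
              class = "louvain_partition")
  })
}

# is partition `fine` a refinement of partition `coarse`? (both: named labels)
is_refinement <- function(fine, coarse) {
  if (!is.null(names(fine)) && !is.null(names(coarse)))
    coarse <- coarse[names(fine)]
  stopifnot(length(fine) == length(coarse))
  all(vapply(split(coarse, fine), function(x) length(unique(x)) == 1L, logical(1)))
}

# a contact network with planted blocks: dense in-block weights, weak
# between-block weights; deterministic
planted_network <- function(block_sizes, w_in = 1, w_between = 0,
                            contig_len = 20000L, bridges = NULL) {
  n <- sum(block_sizes)
  ids <- sprintf("n%03d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  cat <- contig_catalog(ids, rep(contig_len, n), rep(1, n))
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      w <- if (block[i] == block[j]) w_in else w_between
      if (w > 0) edges[[length(edges) + 1L]] <-
          data.frame(contig_a = ids[i], contig_b = ids[j],
                     raw_count = 1L, weight = w, stringsAsFactors = FALSE)
    }
  }
  e <- do.call(rbind, edges)
  if (!is.null(bridges)) e <- rbind(e, bridges)
  net <- proxibin::build_network(e[, c("contig_a", "contig_b")], cat)
  net$edges <- e[order(e$contig_a, e$contig_b), , drop = FALSE]
  rownames(net$edges) <- NULL
  net$total_pairs_used <- nrow(e)
  attr(net, "block") <- stats::setNames(block, ids)
  net
}

# simulated single-end alignment records with controlled mapq/ambiguity
random_alignments <- function(n_pairs, contig_ids, seed,
                              p_lowq = 0.15, p_amb = 0.1, p_same = 0.1,
                              p_extra = 0.05, read_len = 65L) {
  set.seed(seed)
  recs <- list()
  for (p in seq_len(n_pairs)) {
    c1 <- sample(contig_ids, 1L)
    c2 <- if (runif(1) < p_same) c1 else sample(contig_ids, 1L)
    q1 <- if (runif(1) < p_lowq) sample(0:19, 1L) else sample(20:60, 1L)
    q2 <- if (runif(1) < p_lowq) sample(0:19, 1L) else sample(20:60, 1L)
    rid <- sprintf("read%05d", p)
    recs[[length(recs) + 1L]] <- data.frame(
      read_id = rid, mate = 1L, contig_id = c1, position = sample(0:1000, 1L),
      mapq = q1, ambiguous = runif(1) < p_amb, read_len = read_len,
      stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <- data.frame(
      read_id = rid, mate = 2L, contig_id = c2, position = sample(0:1000, 1L),
      mapq = q2, ambiguous = runif(1) < p_amb, read_len = read_len,
      stringsAsFactors = FALSE)
    if (runif(1) < p_extra) {
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = rid, mate = sample(1:2, 1L), contig_id = sample(contig_ids, 1L),
        position = 0L, mapq = 42L, ambiguous = FALSE, read_len = read_len,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}
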