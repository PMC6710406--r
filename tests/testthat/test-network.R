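test_that("contig length filter discards strictly shorter contigs", {
  cat <- contig_catalog(c("a", "b", "c"), c(499L, 500L, 1200L))
  out <- filter_contigs(cat, 500L)
  expect_identical(out$id, c("b", "c"))
  expect_identical(filter_contigs(cat, 0L)$id, cat$id)

  set.seed(11)
  lens <- sample(100:1000, 100, replace = TRUE)
  big <- contig_catalog(sprintf("c%03d", 1:100), lens)
  n_kept <- 0L
  for (l in lens) if (l >= 500L) n_kept <- n_kept + 1L
  expect_equal(nrow(filter_contigs(big, 500L)), n_kept)
  expect_warning(filter_contigs(big, 10000L), "no contigs")
})

test_that("read pairing keeps only clean inter-contig pairs and counts drops", {
  mk <- function(rid, mate, contig, mapq, amb = FALSE)
    data.frame(read_id = rid, mate = mate, contig_id = contig,
               position = 0L, mapq = mapq, ambiguous = amb,
               stringsAsFactors = FALSE)
  aln <- rbind(
    mk("r1", 1, "c1", 42), mk("r1", 2, "c2", 42),   # kept
    mk("r2", 1, "c1", 19), mk("r2", 2, "c2", 42),   # low mapq
    mk("r3", 1, "c1", 20), mk("r3", 2, "c2", 20),   # boundary: kept
    mk("r4", 1, "c1", 42), mk("r4", 2, "c1", 42),   # same contig
    mk("r5", 1, "c1", 42), mk("r5", 2, "c2", 42, amb = TRUE),
    mk("r6", 1, "c2", 42),                          # singleton
    mk("r7", 1, "c1", 42), mk("r7", 2, "c2", 42), mk("r7", 1, "c3", 42) # >2 recs
  )
  res <- pair_reads(aln)
  expect_equal(nrow(res$pairs), 2L)
  expect_true(all(res$pairs$contig_a == "c1" & res$pairs$contig_b == "c2"))
  expect_equal(unname(res$drops["low_mapq"]), 1L)
  expect_equal(unname(res$drops["same_contig"]), 1L)
  expect_equal(unname(res$drops["ambiguous"]), 2L)
  expect_equal(unname(res$drops["unmatched"]), 1L)
})

test_that("read pairing matches the pair-by-pair brute-force filter", {
  aln <- random_alignments(1000, sprintf("c%02d", 1:20), seed = 5)
  got <- pair_reads(aln)
  want <- bf_pair_filter(aln)
  key <- function(p) sort(paste(p$contig_a, p$contig_b))
  expect_identical(key(got$pairs), key(want$pairs))
  expect_identical(got$drops, want$drops)
})

test_that("network construction tallies unordered pair multiplicities", {
  cat <- contig_catalog(c("a", "b", "c"), c(1000L, 1000L, 1000L))
  pairs <- data.frame(contig_a = c("a", "b", "b"), contig_b = c("b", "a", "c"))
  net <- build_network(pairs, cat)
  expect_equal(net$edges$raw_count, c(2L, 1L))
  expect_equal(net$edges$contig_a, c("a", "b"))
  expect_equal(net$total_pairs_used, 3L)

  empty <- build_network(pairs[0, ], cat)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$contigs), 3L)

  expect_warning(
    net2 <- build_network(data.frame(contig_a = c("a", "zz"), contig_b = c("b", "a")), cat),
    "absent"
  )
  expect_equal(net2$total_pairs_used, 1L)
})

test_that("raw counts and weights match the hash-tally oracle on random input", {
  set.seed(21)
  ids <- sprintf("c%02d", 1:50)
  cat <- contig_catalog(ids, sample(500:5000, 50, TRUE), runif(50, 0.5, 50))
  pairs <- data.frame(contig_a = sample(ids, 10000, TRUE),
                      contig_b = sample(ids, 10000, TRUE),
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$contig_a != pairs$contig_b, ]
  net <- normalize_network(build_network(pairs, cat))
  want <- bf_network(pairs, cat)
  expect_identical(net$edges$contig_a, want$contig_a)
  expect_identical(net$edges$contig_b, want$contig_b)
  expect_identical(net$edges$raw_count, want$raw_count)
  expect_equal(net$edges$weight, want$weight, tolerance = 1e-12)
})

test_that("normalization divides by the geometric mean of coverages", {
  cat <- contig_catalog(c("a", "b"), c(1000L, 1000L), c(4, 9))
  net <- build_network(data.frame(contig_a = rep("a", 12), contig_b = rep("b", 12)), cat)
  expect_equal(normalize_network(net)$edges$weight, 2.0)

  cat1 <- contig_catalog(c("a", "b"), c(1000L, 1000L), c(1, 1))
  net1 <- build_network(data.frame(contig_a = rep("a", 7), contig_b = rep("b", 7)), cat1)
  expect_equal(normalize_network(net1)$edges$weight, 7)

  cat0 <- contig_catalog(c("a", "b", "c"), rep(1000L, 3), c(0, 2, 2))
  net0 <- build_network(data.frame(contig_a = c("a", "b"), contig_b = c("b", "c")), cat0)
  expect_warning(n0 <- normalize_network(net0), "zero-coverage")
  expect_equal(nrow(n0$edges), 1L)
})

test_that("scaling all coverages by k scales all weights by 1/k", {
  set.seed(3)
  ids <- sprintf("c%02d", 1:30)
  cat <- contig_catalog(ids, rep(1000L, 30), runif(30, 0.5, 20))
  pairs <- data.frame(contig_a = sample(ids, 2000, TRUE),
                      contig_b = sample(ids, 2000, TRUE))
  pairs <- pairs[pairs$contig_a != pairs$contig_b, ]
  w1 <- normalize_network(build_network(pairs, cat))$edges$weight
  for (k in c(0.5, 3, 10)) {
    cat_k <- cat
    cat_k$coverage <- cat_k$coverage * k
    wk <- normalize_network(build_network(pairs, cat_k))$edges$weight
    expect_equal(wk, w1 / k, tolerance = 1e-14)
  }
})

test_that("pair conservation: used + dropped + cis accounts for every pair", {
  aln <- random_alignments(800, sprintf("c%02d", 1:10), seed = 9)
  res <- pair_reads(aln)
  cat <- contig_catalog(sprintf("c%02d", 1:10), rep(1000L, 10), rep(1, 10))
  net <- build_network(res$pairs, cat)
  n_reads <- length(unique(aln$read_id))
  expect_equal(sum(net$edges$raw_count) + sum(res$drops), n_reads)
  expect_equal(net$total_pairs_used, nrow(res$pairs))
})

test_that("coverage equals total aligned bases over contig length", {
  cat <- contig_catalog(c("a", "b"), c(650L, 1000L))
  one <- data.frame(read_id = "r1", mate = 1L, contig_id = "a", position = 10L,
                    mapq = 42L, ambiguous = FALSE, read_len = 65L)
  got <- compute_coverage(one, cat)
  expect_equal(got$coverage, c(0.1, 0))
  expect_equal(compute_coverage(one[0, ], cat)$coverage, c(0, 0))

  # oracle: literal per-base depth array, mean over positions
  set.seed(17)
  ids <- sprintf("c%02d", 1:10)
  lens <- sample(500:2000, 10, TRUE)
  cat10 <- contig_catalog(ids, lens)
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:500), mate = 1L,
    contig_id = sample(ids, 500, TRUE), mapq = sample(0:60, 500, TRUE),
    ambiguous = runif(500) < 0.1, read_len = 65L, stringsAsFactors = FALSE)
  reads$position <- vapply(reads$contig_id,
                           function(c) sample.int(lens[match(c, ids)] - 65L, 1L) - 1L,
                           integer(1))
  depth <- lapply(lens, numeric)
  names(depth) <- ids
  for (r in seq_len(nrow(reads))) {
    if (reads$ambiguous[r] || reads$mapq[r] < 20L) next
    c <- reads$contig_id[r]
    span <- (reads$position[r] + 1L):(reads$position[r] + 65L)
    depth[[c]][span] <- depth[[c]][span] + 1
  }
  want <- vapply(depth, mean, numeric(1))
  got10 <- compute_coverage(reads, cat10)
  expect_equal(got10$coverage, unname(want[got10$id]), tolerance = 1e-12)
})
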