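test_that("Louvain separates two cliques joined by one weak edge", {
  bridge <- data.frame(contig_a = "n001", contig_b = "n005",
                       raw_count = 1L, weight = 0.01, stringsAsFactors = FALSE)
  net <- planted_network(c(4, 4), w_in = 1, bridges = bridge)
  block <- attr(net, "block")
  for (seed in c(1L, 7L, 99L)) {
    p <- louvain_once(net, seed)
    expect_equal(length(unique(p$labels)), 2L)
    expect_true(is_refinement(block, p$labels))
    expect_true(is_refinement(p$labels, block))
  }
})

test_that("edgeless and single-clique networks give the degenerate partitions", {
  cat <- contig_catalog(c("a", "b", "c"), rep(1000L, 3), rep(1, 3))
  net <- build_network(data.frame(contig_a = character(), contig_b = character()), cat)
  p <- louvain_once(net, 1L)
  expect_equal(length(unique(p$labels)), 3L)
  expect_equal(p$modularity, 0)

  clique <- planted_network(5, w_in = 1)
  pc <- louvain_once(clique, 1L)
  expect_equal(length(unique(pc$labels)), 1L)
  # one community holding every edge: Q = w_in/W - (w_tot/W)^2 = 1 - 1 = 0
  expect_equal(pc$modularity, 0)

  empty <- build_network(data.frame(contig_a = character(), contig_b = character()),
                         contig_catalog(character(), integer())[0, ])
  expect_error(louvain_once(empty, 1L), "empty")
})

test_that("iterated runs are reproducible and derived from the base seed", {
  net <- planted_network(c(6, 6, 6), w_in = 1, w_between = 0.02)
  runs1 <- iterate_louvain(net, n_runs = 5, base_seed = 42L)
  runs2 <- iterate_louvain(net, n_runs = 5, base_seed = 42L)
  expect_identical(lapply(runs1, `[[`, "labels"), lapply(runs2, `[[`, "labels"))
  single <- louvain_once(net, seed = 42L)
  expect_identical(runs1[[1L]]$labels, single$labels)
  expect_equal(runs1[[3L]]$seed, 44L)
})

test_that("core communities are the meet of the input partitions", {
  ids <- c("a", "b", "c", "d")
  cat <- contig_catalog(ids, rep(1000L, 4))
  mk <- function(labs, run) structure(
    list(run_id = run, seed = run, labels = stats::setNames(labs, ids),
         modularity = NA_real_), class = "louvain_partition")

  one <- core_communities(list(mk(c(1, 1, 1, 2), 1)), catalog = cat)
  expect_equal(length(unique(one$membership$cc_id)), 2L)

  two <- core_communities(list(mk(c(1, 1, 2, 2), 1), mk(c(1, 1, 1, 2), 2)),
                          catalog = cat)
  grp <- split(two$membership$contig_id, two$membership$cc_id)
  expect_setequal(unname(vapply(grp, paste, "", collapse = "")),
                  c("ab", "c", "d"))

  expect_error(core_communities(list(mk(c(1, 1, 1, 1), 1)), n_use = 0, catalog = cat),
               "n_use")
})

test_that("meet matches the pairwise co-membership oracle on random partitions", {
  set.seed(31)
  ids <- sprintf("c%03d", 1:200)
  cat <- contig_catalog(ids, sample(500:50000, 200, TRUE))
  parts <- random_partitions(ids, n_runs = 50, k = 8, seed = 31)
  ccs <- core_communities(parts, catalog = cat)
  lab <- vapply(parts, function(p) unname(p$labels[ids]), integer(200))
  want <- bf_meet(lab)
  # same grouping up to relabeling
  expect_equal(length(unique(ccs$membership$cc_id)), length(unique(want)))
  got <- ccs$membership$cc_id[match(ids, ccs$membership$contig_id)]
  expect_true(is_refinement(stats::setNames(got, ids), stats::setNames(want, ids)) &&
                is_refinement(stats::setNames(want, ids), stats::setNames(got, ids)))
})

test_that("cc ids rank communities by total bp, ties by smallest member id", {
  ids <- c("z", "a", "m", "q")
  cat <- contig_catalog(ids, c(100L, 50L, 50L, 500L))
  mk <- structure(list(run_id = 1L, seed = 1L,
                       labels = stats::setNames(c(1, 2, 3, 4), ids),
                       modularity = NA_real_), class = "louvain_partition")
  ccs <- core_communities(list(mk), catalog = cat)
  m <- ccs$membership
  expect_equal(m$cc_id[m$contig_id == "q"], 1L)  # 500 bp
  expect_equal(m$cc_id[m$contig_id == "z"], 2L)  # 100 bp
  expect_equal(m$cc_id[m$contig_id == "a"], 3L)  # 50 bp, "a" < "m"
  expect_equal(m$cc_id[m$contig_id == "m"], 4L)
  expect_equal(ccs$summary$total_bp, c(500, 100, 50, 50))
})

test_that("adding runs only ever splits core communities", {
  ids <- sprintf("c%03d", 1:80)
  cat <- contig_catalog(ids, rep(1000L, 80))
  parts <- random_partitions(ids, n_runs = 12, k = 4, seed = 13)
  prev <- NULL
  for (n in 1:12) {
    ccs <- core_communities(parts, n_use = n, catalog = cat)
    cur <- stats::setNames(ccs$membership$cc_id, ccs$membership$contig_id)[ids]
    for (p in parts[seq_len(n)]) expect_true(is_refinement(cur, p$labels[ids]))
    if (!is.null(prev)) expect_true(is_refinement(cur, prev))
    prev <- cur
  }
})

test_that("co-cluster scores count runs where two CCs share a label", {
  ids <- c("a", "b", "c", "d")
  cat <- contig_catalog(ids, c(400L, 300L, 200L, 100L))
  mk <- function(labs, run) structure(
    list(run_id = run, seed = run, labels = stats::setNames(labs, ids),
         modularity = NA_real_), class = "louvain_partition")
  # a|b always apart from c|d in run 1; everything merged in runs 2 and 3
  parts <- list(mk(c(1, 1, 2, 2), 1), mk(c(5, 5, 5, 5), 2), mk(c(9, 9, 9, 9), 3))
  ccs <- core_communities(parts, catalog = cat)
  sc <- co_cluster_scores(parts, ccs)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$score, 2L)  # merged in 2 of 3 runs

  # orthogonal partitions: the meet is all singletons, some pairs never co-labeled
  parts2 <- list(mk(c(1, 1, 2, 2), 1), mk(c(1, 2, 1, 2), 2))
  ccs2 <- core_communities(parts2, catalog = cat)
  sc2 <- co_cluster_scores(parts2, ccs2)
  expect_equal(nrow(sc2), 6L)
  # brute force: count label agreements between representatives
  reps <- ccs2$membership$contig_id[match(sort(unique(ccs2$membership$cc_id)),
                                          ccs2$membership$cc_id)]
  for (r in seq_len(nrow(sc2))) {
    i <- reps[sc2$cc_a[r]]; j <- reps[sc2$cc_b[r]]
    want <- sum(vapply(parts2, function(p) p$labels[i] == p$labels[j], logical(1)))
    expect_equal(sc2$score[r], want)
  }
  expect_true(any(sc2$score == 0L))
})

test_that("Louvain beats the all-singletons partition on planted structure", {
  net <- planted_network(c(8, 8, 8), w_in = 1, w_between = 0.01)
  p <- louvain_once(net, 4L)
  g <- as_igraph(net)
  q_singletons <- igraph::modularity(g, seq_len(igraph::vcount(g)),
                                     weights = igraph::E(g)$weight)
  expect_gt(p$modularity, q_singletons)
})

test_that("the count of large CCs plateaus as runs accumulate", {
  spec <- community_spec(n_genomes = 8L, contigs_per_genome = 30L, seed = 3L)
  sim <- simulate_community(spec)
  pairs <- simulate_pairs(sim$catalog, sim$truth, spec)
  net <- normalize_network(build_network(pairs, filter_contigs(sim$catalog)))
  parts <- iterate_louvain(net, n_runs = 60, base_seed = 2L)
  n_large <- vapply(1:60, function(n) {
    ccs <- core_communities(parts, n_use = n, catalog = net$contigs)
    sum(ccs$summary$total_bp > 5e5)
  }, numeric(1))
  expect_equal(length(unique(n_large[41:60])), 1L)
})
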