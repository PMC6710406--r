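---
title: "Binning metagenomes from proximity-ligation contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning metagenomes from proximity-ligation contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxibin)
```

## The model

Proximity-ligation assays (meta3C, Hi-C) cross-link DNA inside intact
cells, so a chimeric read pair almost always joins two loci of the *same*
cell. Mapped onto a metagenome assembly, such pairs induce a weighted graph
over contigs in which each genome is a dense block and inter-genome edges
are rare noise. `proxibin` recovers genomes from this graph in four stages.

**Contact network.** Both mates are treated as independent single-end
alignments. A read pair contributes one count to the edge between two
contigs when both mates are unambiguous (no secondary/supplementary or
multi-mapping records), have mapping quality of at least 20, and map to two
different contigs. Pairs failing a rule are counted by category
(`ambiguous`, `low_mapq`, `unmatched`, `same_contig`) so the manifest can
account for every input pair. The raw count is then divided by the
geometric mean of the endpoint coverages. The motivation is that the
expected number of cross-links between two contigs of one genome scales
with how much DNA each contributes — roughly length times copy number — so
dividing by `sqrt(cov_a * cov_b)` flattens the within-genome weights and
makes communities comparable across abundance scales. An exact consequence,
used as a test invariant, is that scaling every coverage by *k* scales every
weight by *1/k*.

**Iterated Louvain and core communities.** Louvain community detection is a
greedy local optimizer of Newman–Girvan modularity; its result depends on
the (randomized) node visit order. Rather than trusting one local optimum,
the partition step runs Louvain many times under derived seeds
(`base_seed + run index`, so any run is re-creatable) and pools contigs
that share a community in *every* one of the first `n_use` runs into core
communities — the meet, or common refinement, of the run partitions. Two
exact laws follow and are asserted in the tests: the CC partition refines
every input run, and adding runs can only split CCs, never merge them. The
meet is computed over the full graph; isolated contigs become singleton
communities. CC ids rank communities by total bp (ties broken by smallest
member id), so CC 1 is always the largest.

**Validation, recursion and tiers.** CCs above 500 kb are scored against a
single-copy marker set: completeness is the fraction of the set present at
least once, contamination the excess copy fraction,
`100 * sum(max(0, copies - 1)) / |set|`. A CC is validated as a bin when
contamination is strictly under 10%. CCs with completeness strictly above
70% *and* contamination strictly above 10% — typically several related
genomes bridged by conserved or mobile sequence — are re-partitioned: 10
Louvain runs on their own sub-network, the meet over all 10, sub-CCs named
`<cc>.<k>`. Recursion depth is one; sub-CCs re-enter scoring like any bin.
MIMAG tiers then apply: high needs contamination < 5, completeness > 90,
at least 18 distinct tRNAs and all three rRNA genes; medium needs < 10 and
≥ 50; low is < 10 and < 50; anything at or above 10% contamination is
`contaminated`. The tRNA/rRNA requirements apply to the high tier only, per
the MIMAG standard; a bin failing only the RNA rules falls to medium.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_contig_len` | 500 bp | contigs strictly shorter are discarded; 500 bp is retained |
| `min_mapq` | 20 | alignments strictly below are discarded; 20 is retained |
| `iterations` / `use_iterations` | 400 / 100 | Louvain runs executed / leading runs intersected into CCs |
| `cc_min_bp` | 500 kb | CCs strictly above this size are scored |
| `contamination_max` | 10% | bin validation bound (strict) |
| `rec_completeness` / `rec_contamination` | 70% / 10% | recursion rule, both strict lower bounds |
| `rec_iterations` | 10 | Louvain runs in the recursive step |

All boundaries are strict in the directions listed; they are encoded once
and covered by a table-driven boundary test. The function-level default for
CC extraction is 100 runs — the number the meet actually consumes — while
the pipeline configuration keeps 400/100 so per-run logs can show the CC
count stabilizing well before the runs are exhausted.

Louvain itself is delegated to `igraph::cluster_louvain()` (weighted,
resolution 1, vertex-order randomization driven by R's RNG), wrapped so
that each run is seeded and reproducible. Modularity of a labeling is
computed with `igraph::modularity()` on the same weights.

## The synthetic community generator

Every stage is testable without external data through a generator that
emulates the single property the method rests on: enriched intra-genome
contact frequency. For contigs *a*, *b* the pair count is Poisson with mean

```
rate * (len_a / 1e4) * (len_b / 1e4) * sqrt(cov_a * cov_b) / mean_depth
```

where `rate` is `intra_rate` (default 5) if the contigs share a host genome
and `inter_rate` (default 0.05) otherwise. Lengths enter in units of 10 kb
and the coverage term is scaled by the community mean depth so the named
rates are of order one per contig pair; the default ratio of 100 gives a
clearly planted but not trivial structure. Because the mean carries the
same `sqrt(cov_a * cov_b)` factor the network normalization divides out,
normalized intra-genome weights are approximately flat — which is exactly
the regime the normalization is designed to produce on real data.

Defaults describe a small but realistic mock community: 10 genomes of 50
contigs each, lognormal contig lengths with median about 15 kb (minimum
100 bp), lognormal genome abundances, 50x community mean depth with 25%
multiplicative per-contig noise. Each genome carries one copy of every
marker in a universal 100-marker single-copy set, 20 tRNA isotypes and the
three rRNA genes, spread round-robin over its contigs — so a bin equal to
one genome scores (100, 0) and a union of two genomes scores (100, 100) by
construction. A `shared_contig_frac` places contigs into a second genome
with contacts to both hosts, emulating the mobile or conserved elements
that bridge communities; such contigs carry both genomes' annotations and
both truth labels.

What the generator does *not* emulate: sequencing errors and read-level
alignment, restriction-fragment geometry and distance-dependent contact
decay, assembly artifacts (chimeras, repeats collapsing into one contig),
and realistic marker phylogenetics. Passing tests therefore demonstrate the
correctness and the statistical behavior of the engine on its idealized
input, not end-to-end accuracy on real sequencing runs — on real data the
alignment and annotation quality dominate.

## Numerical and design choices

* **Meet computation.** Labels across runs are combined into a composite
  key per contig; grouping is exact integer matching, no tolerance. The
  brute-force pairwise co-membership closure is kept in the test suite as
  an oracle.
* **Seeding.** Run *i* uses `base_seed + i - 1`; the recursive step derives
  its seed from the master seed, the run count and the parent CC id, so
  pipelines are byte-reproducible end to end given one seed.
* **Zero-coverage endpoints.** The normalization is undefined there; the
  edge is dropped with a warning rather than patched with a pseudo-count,
  keeping weights interpretable.
* **Cis pairs.** Both-mates-on-one-contig pairs never form edges but do
  contribute aligned bases to coverage: they are genuine alignments, and
  coverage should reflect all mapped DNA.
* **Degenerate inputs.** An edgeless network partitions into singletons
  with modularity 0; an edgeless recursion sub-network returns singleton
  sub-CCs with a warning; an empty catalog is an error.
* **Tie-breaks.** CC ids order by total bp, then lexicographically smallest
  member id; Louvain's own tie-breaking is whatever the seeded igraph run
  produces, which the derived-seed scheme makes reproducible.
* **Recursion ARI.** When scoring recursion against ground truth, contigs
  planted in more than one genome are excluded from the adjusted Rand
  index: each can legitimately land in exactly one sub-CC, so no single
  truth label exists for them.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen to exercise every code path while keeping a full run in
the low minutes on one core: oracle comparisons on up to 200 networks of at
most 100 contigs, meets of 50 random partitions of 200 contigs, and
recovery experiments on 10-genome communities of 500 contigs (about 2 x
10^5 simulated pairs) across 10 seeds. Real deployments are limited mainly
by the number of Louvain runs times the network size; the per-run cost of
`igraph`'s Louvain is near-linear in edges.

## Limitations

The marker model is intentionally flat: no lineage-specific marker sets,
no collocation correction, so absolute completeness/contamination values on
real annotations will differ from CheckM's; `read_checkm_table()` ingests
externally computed scores when fidelity matters. Host assignment of
phages and plasmids, re-assembly per bin, and alternative clustering
objectives (Leiden, CPM) are out of scope, though the partition stage is
isolated enough that another clusterer could be substituted.
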