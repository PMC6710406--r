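#' Write a contact network to plain text
#'
#' The primary output is the classic three-column network file: node1,
#' node2, weight, tab-separated, no header. Weights are serialized with 15
#' significant digits so a write/read round trip is bit-stable. Two sidecar
#' files accompany it: `<path>.raw.tsv` (contig_a, contig_b, raw_count) and
#' `<path>.nodes.tsv` (id, length, coverage).
#'
#' @param net a `contact_network` (normalized or raw; unnormalized networks
#'   write raw counts into the weight column).
#' @param path output path for the 3-column file.
#' @param sidecar write the raw-count and node sidecars (default TRUE).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, sidecar = TRUE) {
  w <- net$edges$weight
  if (all(is.na(w))) w <- net$edges$raw_count
  lines <- sprintf("%s\t%s\t%s", net$edges$contig_a, net$edges$contig_b,
                   formatC(w, digits = 17, format = "g"))
  writeLines(lines, path)
  if (sidecar) {
    utils::write.table(net$edges[, c("contig_a", "contig_b", "raw_count")],
                       paste0(path, ".raw.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(net$contigs),
                       paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a contact network from plain text
#'
#' Reads the three-column (node1, node2, weight) format, canonicalizing each
#' pair to `contig_a < contig_b`. A malformed line or a duplicate unordered
#' pair is an error reporting the line number. When the node sidecar exists
#' (or a catalog is given) it supplies lengths/coverages and isolated nodes;
#' otherwise the catalog is inferred from the edge endpoints with unit
#' lengths.
#'
#' @param path path to the network file.
#' @param catalog optional [contig_catalog()] overriding the sidecar.
#' @return A `contact_network` with weights as stored; raw counts restored
#'   from the sidecar when present.
#' @export
read_network <- function(path, catalog = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed network line ", bad[1L], ": expected 3 tab-separated fields")
  a0 <- vapply(parts, `[`, "", 1L)
  b0 <- vapply(parts, `[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(w))
    stop("malformed network line ", which(is.na(w))[1L], ": non-numeric weight")
  a <- pmin(a0, b0); b <- pmax(a0, b0)
  if (any(a == b)) stop("self edge at line ", which(a == b)[1L])
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge at line ", which(duplicated(key))[1L])

  if (is.null(catalog)) {
    nodes_path <- paste0(path, ".nodes.tsv")
    if (file.exists(nodes_path)) {
      nd <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
      catalog <- contig_catalog(nd$id, nd$length, nd$coverage)
    } else {
      ids <- sort(unique(c(a, b)))
      catalog <- contig_catalog(ids, rep(1L, length(ids)))
    }
  }
  raw <- rep(NA_integer_, length(a))
  raw_path <- paste0(path, ".raw.tsv")
  if (file.exists(raw_path)) {
    rd <- utils::read.delim(raw_path, stringsAsFactors = FALSE)
    raw <- rd$raw_count[match(key, paste(rd$contig_a, rd$contig_b, sep = "\r"))]
  }
  edges <- data.frame(contig_a = a, contig_b = b,
                      raw_count = raw, weight = w, stringsAsFactors = FALSE)
  edges <- edges[order(edges$contig_a, edges$contig_b), , drop = FALSE]
  rownames(edges) <- NULL
  new_contact_network(catalog, edges,
                      total_pairs_used = sum(raw, na.rm = TRUE))
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping ids verbatim; sequences are written
#' wrapped at 80 columns. Duplicate ids on read are an error; an empty file
#' yields an empty store with a warning.
#'
#' @param path FASTA path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) warning("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  stats::setNames(as.character(x), ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA ids")
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write one FASTA per bin
#'
#' @param seqs named character vector of contig sequences.
#' @param bins data frame `contig_id`, `bin_id`.
#' @param dir output directory; files are named `<bin_id>.fa`.
#' @return Character vector of written paths, invisibly.
#' @export
write_bin_fasta <- function(seqs, bins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_bin <- split(bins$contig_id, bins$bin_id)
  paths <- vapply(names(by_bin), function(b) {
    p <- file.path(dir, paste0(b, ".fa"))
    write_fasta(seqs[by_bin[[b]]], p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Pipeline configuration
#'
#' All thresholds and flags of the pipeline in one flat record, serializable
#' as `key=value` lines. Defaults are the method's standard parameters:
#' contigs under 500 bp discarded, mapping quality under 20 discarded, 400
#' Louvain runs of which the first 100 are pooled into core communities,
#' CCs over 500 kb evaluated, recursion on CCs with completeness > 70% and
#' contamination > 10% using 10 recursive runs.
#'
#' @param min_contig_len,min_mapq,iterations,use_iterations,cc_min_bp
#'   pipeline thresholds (see description).
#' @param rec_completeness,rec_contamination,rec_iterations recursion rule.
#' @param contamination_max bin-validation cutoff, percent (exclusive).
#' @param seed master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_contig_len = 500L, min_mapq = 20L,
                            iterations = 400L, use_iterations = 100L,
                            cc_min_bp = 500000, rec_completeness = 70,
                            rec_contamination = 10, rec_iterations = 10L,
                            contamination_max = 10, seed = 1L) {
  cfg <- list(min_contig_len = as.integer(min_contig_len),
              min_mapq = as.integer(min_mapq),
              iterations = as.integer(iterations),
              use_iterations = as.integer(use_iterations),
              cc_min_bp = as.numeric(cc_min_bp),
              rec_completeness = as.numeric(rec_completeness),
              rec_contamination = as.numeric(rec_contamination),
              rec_iterations = as.integer(rec_iterations),
              contamination_max = as.numeric(contamination_max),
              seed = as.integer(seed))
  if (cfg$use_iterations > cfg$iterations)
    stop("use_iterations cannot exceed iterations")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s=%s", names(cfg), vapply(cfg, format, character(1))),
             path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  defaults <- pipeline_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- lapply(names(vals), function(k) as.numeric(vals[[k]]))
  names(args) <- names(vals)
  do.call(pipeline_config, args)
}
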