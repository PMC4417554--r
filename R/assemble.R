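#' Inspect the de Bruijn graph of a read set
#'
#' Builds the graph of canonical k-mers (a k-mer and its reverse
#' complement are the same node; k must be odd so no k-mer is its own
#' reverse complement) and observed (k+1)-mer adjacencies, after the
#' multiplicity cutoff but before any cleanup.
#'
#' @param reads character vector of read sequences, a `read_set`, or a
#'   data.frame with a `sequence` column.
#' @param k odd k-mer size, `3 <= k <= read length`.
#' @param cutoff minimum k-mer multiplicity kept; `NULL` (default) picks 2
#'   when the mean k-mer multiplicity exceeds 10 and 1 otherwise.
#' @return list of two data.frames: `nodes` (`kmer`, `count`) and `edges`
#'   (`kmer`, `count`), both canonical and lexicographically sorted.
#' @export
dbg_graph <- function(reads, k, cutoff = NULL) {
  seqs <- read_sequences(reads)
  res <- cpp_graph_summary(seqs, as.integer(k),
                           if (is.null(cutoff)) -1L else as.integer(cutoff))
  list(nodes = data.frame(kmer = res$node, count = res$node_count,
                          stringsAsFactors = FALSE),
       edges = data.frame(kmer = res$edge, count = res$edge_count,
                          stringsAsFactors = FALSE))
}

#' Assemble reads with the built-in de Bruijn assembler
#'
#' Euler-path style assembly at a single k: build the canonical k-mer
#' graph, drop low-multiplicity k-mers, clip short low-coverage dead ends
#' ("tips"), pop simple two-arm bubbles ("detours") keeping the
#' higher-coverage arm, and emit maximal non-branching paths as contigs.
#' Output is deterministic given the reads and parameters: contigs are
#' reported in canonical orientation, ordered by length (descending) then
#' lexicographically.
#'
#' @inheritParams dbg_graph
#' @param min_contig minimum contig length reported (default 100 bp).
#' @param clip_tips,pop_bubbles logical switches for the two cleanup
#'   passes (both default `TRUE`).
#' @param max_tip_len maximum tip length removed, in bp (default `2 * k`).
#' @param max_divergence maximum length difference (in nodes) between the
#'   two arms of a poppable bubble (default 2).
#' @return an object of class `contig_set`: data.frame with `id`,
#'   `sequence`, `length`, `coverage` (mean k-mer multiplicity), with `k`
#'   attached as an attribute.
#' @export
dbg_assemble <- function(reads, k, cutoff = NULL, min_contig = 100,
                         clip_tips = TRUE, pop_bubbles = TRUE,
                         max_tip_len = NULL, max_divergence = 2) {
  seqs <- read_sequences(reads)
  res <- cpp_assemble(seqs, as.integer(k),
                      if (is.null(cutoff)) -1L else as.integer(cutoff),
                      as.integer(min_contig), clip_tips, pop_bubbles,
                      if (is.null(max_tip_len)) -1L
                      else as.integer(max_tip_len),
                      as.integer(max_divergence))
  contig_set(res$sequence, res$coverage, k = k)
}

#' Construct a contig set
#'
#' Container used for every assembly in the package; build one from a
#' character vector (or [read_fasta()] output) to import contigs produced
#' by an external assembler into the merge/evaluate stages.
#'
#' @param sequences character vector of contig sequences.
#' @param coverage optional mean k-mer multiplicity per contig.
#' @param k the k the contigs were assembled with, if known.
#' @param ids optional ids (default `contig_1`, `contig_2`, ...).
#' @return a `contig_set` data.frame (`id`, `sequence`, `length`,
#'   `coverage`).
#' @export
contig_set <- function(sequences, coverage = NA_real_, k = NA_integer_,
                       ids = NULL) {
  n <- length(sequences)
  if (is.null(ids)) ids <- if (n) sprintf("contig_%d", seq_len(n))
                           else character(0)
  structure(data.frame(id = ids, sequence = as.character(sequences),
                       length = nchar(sequences),
                       coverage = rep_len(coverage, n),
                       stringsAsFactors = FALSE),
            k = k, class = c("contig_set", "data.frame"))
}

#' Write contigs to FASTA
#'
#' Headers carry the assembly provenance:
#' `contig_<n> k=<k> cov=<mean k-mer multiplicity>`.
#'
#' @param contigs a `contig_set` (or any data.frame with `id`,
#'   `sequence`, optionally `coverage`).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  k <- attr(contigs, "k")
  hdr <- contigs$id
  if (!is.null(k) && !is.na(k)) hdr <- paste0(hdr, " k=", k)
  if (!is.null(contigs$coverage) && !all(is.na(contigs$coverage)))
    hdr <- paste0(hdr, " cov=", formatC(contigs$coverage, format = "g"))
  write_fasta(contigs, path, headers = hdr)
}
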