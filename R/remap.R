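#' Remap reads to contigs and count per-contig expression
#'
#' Stage 3 of the multi-k procedure. Each read (both mates of a pair are
#' mapped independently) is assigned to at most one contig: exact seeds at
#' the two read ends are looked up in a k-mer index of the contigs (both
#' strands), candidate placements are verified by full-length comparison
#' allowing at most `max_mismatch` substitutions, and the placement with
#' the fewest mismatches wins; ties go to the longer contig, then to the
#' lexicographically smaller contig id. Deterministic.
#'
#' @param reads a `read_set`, data.frame with mate columns, or character
#'   vector of read sequences.
#' @param contigs a `contig_set` (or data.frame with `id`, `sequence`).
#' @param seed_len exact seed length (default 17).
#' @param max_mismatch maximum substitutions tolerated over the full read
#'   (default 2).
#' @return an object of class `expression_table`: list with `table`
#'   (data.frame `contig_id`, `length`, `mapped_reads`, `reads_per_base`),
#'   `unmapped`, `total_reads` and the per-read `assignments` (contig id
#'   or `NA`). `mapped + unmapped = total` always holds.
#' @export
map_reads <- function(reads, contigs, seed_len = 17, max_mismatch = 2) {
  seqs <- read_sequences(reads)
  if (seed_len > min(c(nchar(seqs), Inf)))
    stop("seed_len exceeds the read length")
  idx <- cpp_map_reads(seqs, contigs$sequence, contigs$id,
                       as.integer(seed_len), as.integer(max_mismatch))
  assignments <- ifelse(idx == 0L, NA_character_, contigs$id[idx])
  counts <- table(factor(assignments, levels = contigs$id))
  tab <- data.frame(contig_id = contigs$id, length = contigs$length,
                    mapped_reads = as.integer(counts),
                    reads_per_base = as.integer(counts) / contigs$length,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, unmapped = sum(idx == 0L),
                 total_reads = length(seqs), assignments = assignments),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", nrow(x$table), "contigs,",
      x$total_reads - x$unmapped, "of", x$total_reads, "reads mapped",
      sprintf("(%.1f%%)\n",
              100 * (x$total_reads - x$unmapped) / max(1, x$total_reads)))
  invisible(x)
}

#' Write an expression table to TSV
#'
#' @param x an `expression_table` from [map_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expression_table"))
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
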