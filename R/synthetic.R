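#' Generate a synthetic reference transcript set
#'
#' Draws `n` transcripts of i.i.d. uniform A/C/G/T bases with lengths
#' uniform over `length_range`. These stand in for a curated reference
#' transcript catalogue so the whole pipeline is testable offline.
#'
#' @param n number of transcripts (>= 1).
#' @param length_range integer vector `c(min, max)` of lengths in bp.
#' @param seed integer seed; the generator is deterministic given it.
#' @return data.frame with columns `id`, `sequence`, `length`, `est_count`
#'   (initialised to `NA`; see [sample_power_law_expression()]).
#' @export
#' @examples
#' tx <- generate_transcripts(3, c(100, 200), seed = 1)
#' tx$length
generate_transcripts <- function(n, length_range, seed = NULL) {
  if (length(n) != 1L || n < 1) stop("n must be a single value >= 1")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2])
    stop("length_range must be c(min, max) with 1 <= min <= max")
  with_seed(seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n,
                 replace = TRUE) - 1L
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
    data.frame(id = sprintf("tx_%d", seq_len(n)), sequence = seqs,
               length = as.integer(lens), est_count = NA_integer_,
               stringsAsFactors = FALSE)
  })
}

#' Assign power-law (Zipf-like) expression levels
#'
#' Draws per-transcript EST counts from a discrete power law
#' `P(X = x) proportional to x^-exponent` on `1..max_count`, emulating the
#' heavy-tailed expression distribution of real transcriptomes where
#' coverage depths span several orders of magnitude.
#'
#' @param transcripts data.frame from [generate_transcripts()].
#' @param exponent power-law exponent, must be > 1 (default 2).
#' @param seed integer seed.
#' @param max_count upper truncation of the count support; since read
#'   allocation is proportional to `est_count * length`, coverage is
#'   proportional to `est_count` and `max_count` controls the
#'   max/min coverage ratio (default 10000, giving a spread of up to four
#'   orders of magnitude).
#' @return `transcripts` with `est_count` filled in; at least one count is
#'   >= 1 by construction.
#' @export
sample_power_law_expression <- function(transcripts, exponent = 2,
                                        seed = NULL, max_count = 10000) {
  if (exponent <= 1) stop("exponent must be > 1")
  if (max_count < 1) stop("max_count must be >= 1")
  support <- seq_len(max_count)
  prob <- support^(-exponent)
  with_seed(seed, {
    transcripts$est_count <- as.integer(
      sample(support, nrow(transcripts), replace = TRUE, prob = prob))
    transcripts
  })
}

#' Allocate a read budget across transcripts
#'
#' Splits `total_reads` read pairs proportionally to
#' `est_count * length` (the expression proxy times transcript length),
#' using largest-remainder rounding so the allocation sums exactly to
#' `total_reads`.
#'
#' @param transcripts data.frame with `id`, `length`, `est_count`.
#' @param total_reads total number of read pairs to allocate (>= 0).
#' @param read_length read length in bp used for the coverage column
#'   (default 36).
#' @param weights optional explicit weights overriding
#'   `est_count * length`.
#' @return an object of class `expression_profile`: a list with
#'   `transcripts`, `total_reads`, `read_length` and an `allocation`
#'   data.frame (`id`, `length`, `est_count`, `reads`, `coverage`), where
#'   `coverage = reads * 2 * read_length / length`.
#' @export
allocate_reads <- function(transcripts, total_reads, read_length = 36,
                           weights = NULL) {
  if (total_reads < 0) stop("total_reads must be >= 0")
  if (is.null(weights))
    weights <- as.numeric(transcripts$est_count) * transcripts$length
  if (any(is.na(weights)) || any(weights < 0))
    stop("weights must be non-negative and non-missing")
  if (sum(weights) == 0) stop("all allocation weights are zero")
  weights <- as.numeric(weights)
  share <- as.numeric(total_reads) * weights / sum(weights)
  reads <- floor(share)
  rem <- share - reads
  short <- total_reads - sum(reads)
  if (short > 0) {
    # largest remainders win; ties broken by transcript order
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    reads[top] <- reads[top] + 1
  }
  alloc <- data.frame(id = transcripts$id, length = transcripts$length,
                      est_count = transcripts$est_count,
                      reads = as.integer(reads),
                      coverage = reads * 2 * read_length / transcripts$length,
                      stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, total_reads = total_reads,
                 read_length = read_length, allocation = alloc),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile:", nrow(x$allocation), "transcripts,",
      x$total_reads, "read pairs\n")
  cov <- x$allocation$coverage
  cat(sprintf("  coverage: min %.2fx, median %.2fx, max %.2fx\n",
              min(cov), stats::median(cov), max(cov)))
  invisible(x)
}

#' Write transcripts to FASTA
#'
#' @param transcripts data.frame with `id` and `sequence`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  write_fasta(transcripts, path)
}

#' Write an expression profile to TSV
#'
#' Columns: id, length, est_count, reads, coverage.
#'
#' @param profile an `expression_profile`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  write.table(profile$allocation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
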