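#' Position-ramped substitution error profile
#'
#' Short-read substitution error rates grow towards the 3' end of a read.
#' The profile is a linear ramp: the rate at 0-based read position `i` is
#' `start_rate + i * increment`.
#'
#' @param start_rate substitution probability at the first read position
#'   (a fraction, e.g. 0.002 for 0.2\%).
#' @param increment additive per-position step (default 5e-5, i.e. 0.005
#'   percentage points per nucleotide).
#' @param read_length read length in bp (default 36).
#' @return an object of class `error_profile`.
#' @export
#' @examples
#' p <- error_profile(0.002)
#' position_error_rate(p, 35)
error_profile <- function(start_rate, increment = 5e-5, read_length = 36) {
  if (start_rate < 0) stop("start_rate must be >= 0")
  if (increment < 0) stop("increment must be >= 0")
  if (read_length < 1) stop("read_length must be >= 1")
  if (start_rate + increment * (read_length - 1) >= 1)
    stop("error rate reaches 1 within the read; profile infeasible")
  structure(list(start_rate = start_rate, increment = increment,
                 read_length = as.integer(read_length)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "Error profile: start %.4g%%, +%.4g%% per position, %d bp reads (mean %.4g%%)\n",
    100 * x$start_rate, 100 * x$increment, x$read_length,
    100 * mean(position_error_rate(x, seq_len(x$read_length) - 1))))
  invisible(x)
}

#' Substitution probability at a read position
#'
#' @param profile an [error_profile()].
#' @param i 0-based read position(s), each in `[0, read_length)`.
#' @return numeric vector of probabilities `start_rate + i * increment`.
#' @export
position_error_rate <- function(profile, i) {
  stopifnot(inherits(profile, "error_profile"))
  if (any(i < 0 | i >= profile$read_length))
    stop("position out of range [0, read_length)")
  profile$start_rate + i * profile$increment
}

#' Error profile for a target average error rate
#'
#' For the standard series of average rates 0.3\%, 0.6\%, ..., 2.4\% at
#' 36 bp reads with a 0.005 percentage-point per-position increment, the
#' starting rate is the average minus 0.1 percentage points (0.3\% -> 0.2\%,
#' ..., 2.4\% -> 2.3\%). For any other average, the start rate is chosen so
#' that the ramp's analytic mean equals the average:
#' `start = avg - increment * (read_length - 1) / 2`.
#'
#' @param avg_rate target average substitution rate (fraction).
#' @param read_length read length in bp (default 36).
#' @param increment per-position step (default 5e-5).
#' @return an [error_profile()].
#' @export
#' @examples
#' profile_for_average(0.003)$start_rate  # 0.002
profile_for_average <- function(avg_rate, read_length = 36,
                                increment = 5e-5) {
  series <- seq(0.003, 0.024, by = 0.003)
  if (read_length == 36 && identical(increment, 5e-5) &&
      any(abs(avg_rate - series) < 1e-12)) {
    start <- avg_rate - 0.001
  } else {
    start <- avg_rate - increment * (read_length - 1) / 2
  }
  if (start < 0)
    stop("infeasible average rate: implied start rate is negative")
  error_profile(start, increment, read_length)
}

# Phred+33 quality string encoding the expected per-position error rate.
profile_quality_string <- function(profile) {
  p <- position_error_rate(profile, seq_len(profile$read_length) - 1)
  q <- ifelse(p <= 0, 40L, pmin(40L, as.integer(round(-10 * log10(p)))))
  intToUtf8(33L + q)
}

#' Simulate read pairs from one transcript
#'
#' Fragments ("inserts", total sequenced fragment length) are drawn
#' uniformly over `insert_range` and placed uniformly on the transcript;
#' mate 1 is the 5' prefix of the fragment and mate 2 the reverse
#' complement of its 3' suffix (FR orientation). Each base is substituted
#' independently, to a uniformly chosen different base, with the
#' position-dependent probability of `profile`.
#'
#' Uses the current RNG state; wrap in `set.seed()` (or use
#' [simulate_dataset()]) for reproducibility.
#'
#' @param sequence transcript sequence (single string).
#' @param n_pairs number of pairs to draw.
#' @param profile an [error_profile()].
#' @param insert_range integer `c(min, max)` fragment length in bp.
#' @return data.frame with `frag_start` (0-based), `insert`, `mate1`,
#'   `mate2`, `mate1_errors`, `mate2_errors` (comma-separated 0-based
#'   positions of substituted bases).
#' @export
simulate_pairs <- function(sequence, n_pairs, profile,
                           insert_range = c(175, 225)) {
  stopifnot(inherits(profile, "error_profile"))
  check_insert_range(insert_range, profile$read_length)
  if (nchar(sequence) < insert_range[2])
    stop("transcript shorter than the maximum insert size")
  res <- cpp_simulate_pairs(sequence, as.integer(n_pairs),
                            profile$read_length,
                            insert_range[1], insert_range[2],
                            profile$start_rate, profile$increment)
  data.frame(frag_start = res$frag_start, insert = res$insert,
             mate1 = res$mate1, mate2 = res$mate2,
             mate1_errors = res$mate1_errors,
             mate2_errors = res$mate2_errors, stringsAsFactors = FALSE)
}

check_insert_range <- function(insert_range, read_length) {
  if (length(insert_range) != 2L || insert_range[1] > insert_range[2] ||
      insert_range[1] < read_length)
    stop("insert_range must be c(min, max) with read_length <= min <= max")
  invisible(TRUE)
}

#' Simulate a full paired-end dataset from an expression profile
#'
#' Draws exactly the per-transcript pair counts of `expression` (see
#' [allocate_reads()]) under the given error profile and insert model.
#' Deterministic given `seed`. Transcripts shorter than the maximum insert
#' are skipped with a warning (or abort if `short = "error"`).
#'
#' @param expression an `expression_profile`.
#' @param profile an [error_profile()]; its `read_length` is used.
#' @param insert_range integer `c(min, max)` fragment length (default
#'   `c(175, 225)`).
#' @param seed integer seed.
#' @param short what to do with transcripts shorter than the maximum
#'   insert: `"skip"` (default) or `"error"`.
#' @return an object of class `read_set`: a data.frame with `read_id`,
#'   `transcript_id`, `frag_start`, `insert`, `mate1`, `mate2`,
#'   `mate1_errors`, `mate2_errors`, with the error profile and insert
#'   range attached as attributes.
#' @export
simulate_dataset <- function(expression, profile,
                             insert_range = c(175, 225), seed = NULL,
                             short = c("skip", "error")) {
  stopifnot(inherits(expression, "expression_profile"),
            inherits(profile, "error_profile"))
  short <- match.arg(short)
  check_insert_range(insert_range, profile$read_length)
  alloc <- expression$allocation
  tx <- expression$transcripts
  too_short <- tx$length < insert_range[2] & alloc$reads > 0
  if (any(too_short)) {
    if (short == "error")
      stop(sum(too_short), " transcript(s) shorter than the maximum insert")
    warning(sum(too_short),
            " transcript(s) shorter than the maximum insert; skipped")
  }
  n_pairs <- ifelse(too_short, 0L, alloc$reads)
  res <- with_seed(seed,
    cpp_simulate_pairs(tx$sequence, as.integer(n_pairs),
                       profile$read_length, insert_range[1],
                       insert_range[2], profile$start_rate,
                       profile$increment))
  out <- data.frame(
    read_id = if (length(res$transcript)) sprintf("read_%d",
      seq_along(res$transcript)) else character(0),
    transcript_id = tx$id[res$transcript],
    frag_start = res$frag_start, insert = res$insert,
    mate1 = res$mate1, mate2 = res$mate2,
    mate1_errors = res$mate1_errors, mate2_errors = res$mate2_errors,
    stringsAsFactors = FALSE)
  structure(out, profile = profile, insert_range = insert_range,
            class = c("read_set", "data.frame"))
}

#' Write a simulated read set to paired FASTQ plus a truth TSV
#'
#' Emits `<prefix>_1.fastq`, `<prefix>_2.fastq` (Phred+33; the quality
#' string encodes the expected per-position error rate of the profile) and
#' `<prefix>_truth.tsv` with the provenance of every pair.
#'
#' @param reads a `read_set` from [simulate_dataset()].
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_reads_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  profile <- attr(reads, "profile")
  qual <- profile_quality_string(profile)
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  pt <- paste0(prefix, "_truth.tsv")
  write_fastq(paste0(reads$read_id, "/1"), reads$mate1,
              rep(qual, nrow(reads)), p1)
  write_fastq(paste0(reads$read_id, "/2"), reads$mate2,
              rep(qual, nrow(reads)), p2)
  truth <- reads[, c("read_id", "transcript_id", "frag_start", "insert",
                     "mate1_errors", "mate2_errors")]
  write.table(truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, pt))
}

# All mate sequences of a read set (or pass a character vector through).
read_sequences <- function(reads) {
  if (inherits(reads, "read_set") ||
      (is.data.frame(reads) && all(c("mate1", "mate2") %in% names(reads))))
    return(c(reads$mate1, reads$mate2))
  if (is.data.frame(reads) && "sequence" %in% names(reads))
    return(reads$sequence)
  as.character(reads)
}
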