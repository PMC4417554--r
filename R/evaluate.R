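#' Align contigs to reference transcripts with the built-in aligner
#'
#' Ungapped seed-and-extend local alignment on both strands: exact
#' `min_seed`-mers of the contig are looked up in an index of the
#' references and extended in both directions with an X-drop rule
#' (match +1, mismatch -2). Reports percent identity and a BLAST-like bit
#' score (monotone in aligned length and identity). Deterministic.
#'
#' @param contigs a `contig_set` or data.frame with `id`, `sequence`.
#' @param references data.frame with `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param min_seed exact seed length (default 16).
#' @param xdrop X-drop threshold ending an extension (default 20).
#' @param min_aln_len shortest alignment reported (default `min_seed`).
#' @return alignment data.frame: `contig_id`, `ref_id`, `c_start`,
#'   `c_end`, `r_start`, `r_end` (0-based half-open, forward frames),
#'   `strand`, `identity` (percent), `bit_score`, `aligned_length`.
#' @export
builtin_align <- function(contigs, references, min_seed = 16, xdrop = 20,
                          min_aln_len = min_seed) {
  if (!nrow(contigs) || !nrow(references))
    return(empty_alignments())
  res <- cpp_align(contigs$sequence, references$sequence,
                   as.integer(min_seed), as.integer(xdrop),
                   as.integer(min_aln_len))
  data.frame(contig_id = contigs$id[res$contig],
             ref_id = references$id[res$ref],
             c_start = res$c_start, c_end = res$c_end,
             r_start = res$r_start, r_end = res$r_end,
             strand = res$strand, identity = res$identity,
             bit_score = res$bit_score,
             aligned_length = res$c_end - res$c_start,
             stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(contig_id = character(), ref_id = character(),
             c_start = integer(), c_end = integer(),
             r_start = integer(), r_end = integer(),
             strand = character(), identity = numeric(),
             bit_score = numeric(), aligned_length = integer(),
             stringsAsFactors = FALSE)
}

#' Read BLAST 12-column tabular alignments (outfmt 6)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. The query is taken as the contig and the
#' subject as the reference. 1-based inclusive coordinates are converted
#' to 0-based half-open; a subject interval given in descending order
#' means a minus-strand alignment and is normalised.
#'
#' @param path tabular file.
#' @return alignment data.frame in the layout of [builtin_align()].
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("malformed BLAST tabular line ", bad[1], ": expected 12 columns, ",
         "got ", lengths(parts)[bad[1]])
  m <- do.call(rbind, parts)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("malformed BLAST tabular line ", which(is.na(v))[1],
           ": non-numeric field in column ", j)
    v
  }
  qstart <- num(7); qend <- num(8); sstart <- num(9); send <- num(10)
  minus <- sstart > send
  data.frame(contig_id = m[, 1], ref_id = m[, 2],
             c_start = as.integer(qstart - 1), c_end = as.integer(qend),
             r_start = as.integer(ifelse(minus, send, sstart) - 1),
             r_end = as.integer(ifelse(minus, sstart, send)),
             strand = ifelse(minus, "-", "+"),
             identity = num(3), bit_score = num(12),
             aligned_length = as.integer(num(4)),
             stringsAsFactors = FALSE)
}

#' Write alignments as BLAST 12-column tabular
#'
#' Inverse of [read_blast_tabular()] (mismatch and gapopen are derived
#' from identity over the aligned length; evalue is written as 0).
#'
#' @param alignments alignment data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(alignments, path) {
  a <- alignments
  mism <- round(a$aligned_length * (1 - a$identity / 100))
  sstart <- ifelse(a$strand == "-", a$r_end, a$r_start + 1)
  send <- ifelse(a$strand == "-", a$r_start + 1, a$r_end)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1g\t%.6g",
                   a$contig_id, a$ref_id, a$identity, a$aligned_length,
                   as.integer(mism), 0L, a$c_start + 1L, a$c_end,
                   as.integer(sstart), as.integer(send), 0, a$bit_score)
  writeLines(lines, path)
  invisible(path)
}

#' Filter alignments by identity and contig length
#'
#' Keeps alignments whose contig is at least `min_contig_len` bp and whose
#' identity is at least `min_identity` percent; both boundaries are
#' inclusive.
#'
#' @param alignments alignment data.frame.
#' @param contigs `contig_set` (or data.frame with `id`, `length`) used
#'   to look up contig lengths.
#' @param min_identity percent identity threshold (default 95).
#' @param min_contig_len contig length threshold in bp (default 100).
#' @return filtered alignment data.frame.
#' @export
filter_alignments <- function(alignments, contigs, min_identity = 95,
                              min_contig_len = 100) {
  if (!nrow(alignments)) return(alignments)
  len <- setNames(contigs$length, contigs$id)[alignments$contig_id]
  keep <- !is.na(len) & len >= min_contig_len &
    alignments$identity >= min_identity
  alignments[keep, , drop = FALSE]
}

# total bases covered by the union of [start, end) intervals, per group
union_bases <- function(start, end, group) {
  if (!length(start)) return(0)
  ir <- IRanges::IRanges(start = start + 1L, end = end)  # to 1-based closed
  total <- 0
  for (g in unique(group)) {
    sel <- group == g
    total <- total + sum(IRanges::width(IRanges::reduce(ir[sel])))
  }
  total
}

f_measure <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Overlap precision, recall and F-measure
#'
#' Counts the union of all alignment areas as true positive, once per
#' base, on each side: recall is the union of reference-side intervals
#' over the total length of all references; precision is the union of
#' contig-side intervals over the total length of contigs passing the
#' length filter. F is the harmonic mean (0 when both are 0). Overlapping
#' alignments are never excluded, so these measures upper-bound the
#' stricter consistent measures.
#'
#' @param alignments filtered alignments (see [filter_alignments()]).
#' @param references data.frame with `id`, `length` for every reference
#'   transcript, aligned or not.
#' @param contigs `contig_set`; only contigs of at least
#'   `min_contig_len` bp enter the precision denominator.
#' @param min_contig_len contig length filter (default 100).
#' @return named list `precision`, `recall`, `f` in percent.
#' @export
overlap_measures <- function(alignments, references, contigs,
                             min_contig_len = 100) {
  denom_r <- sum(references$length)
  if (denom_r == 0) stop("reference set has zero total length")
  denom_c <- sum(contigs$length[contigs$length >= min_contig_len])
  tp_r <- union_bases(alignments$r_start, alignments$r_end,
                      alignments$ref_id)
  tp_c <- union_bases(alignments$c_start, alignments$c_end,
                      alignments$contig_id)
  p <- if (denom_c == 0) 0 else 100 * tp_c / denom_c
  r <- 100 * tp_r / denom_r
  list(precision = p, recall = r, f = f_measure(p, r))
}

#' Greedy consistent alignment selection
#'
#' Walks the alignments from highest to lowest bit score and accepts one
#' when (a) on both the reference side and the contig side its overlap
#' with every already-accepted alignment is at most `max_overlap_frac` of
#' the shorter of the two spans on that side, and (b) it is consistent
#' with the acceptances of its contig: all acceptances of one contig must
#' share the reference and strand (one contig stands for one transcript)
#' and be colinear (same relative order on contig and reference,
#' orientation-adjusted, so rearrangements are excluded). Bit-score ties
#' are broken by longer alignment, then reference id, reference start and
#' contig id, so the result is invariant to input order.
#'
#' @param alignments filtered alignment data.frame.
#' @param max_overlap_frac allowed pairwise overlap fraction (default
#'   0.05, i.e. the 5 percent rule).
#' @return the accepted subset, in acceptance order, with class
#'   `alignment_collection`.
#' @export
build_consistent_collection <- function(alignments,
                                        max_overlap_frac = 0.05) {
  a <- alignments
  if (!nrow(a)) {
    class(a) <- c("alignment_collection", class(a))
    return(a)
  }
  ord <- order(-a$bit_score, -a$aligned_length, a$ref_id, a$r_start,
               a$contig_id)
  a <- a[ord, , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(a))) {
    ok <- TRUE
    if (length(acc)) {
      b <- a[acc, , drop = FALSE]
      # (a) 5% rule on the reference side
      same_r <- b$ref_id == a$ref_id[i]
      if (any(same_r)) {
        ov <- pmin(b$r_end[same_r], a$r_end[i]) -
              pmax(b$r_start[same_r], a$r_start[i])
        shorter <- pmin(b$r_end[same_r] - b$r_start[same_r],
                        a$r_end[i] - a$r_start[i])
        if (any(ov > max_overlap_frac * shorter)) ok <- FALSE
      }
      # (a) 5% rule on the contig side
      same_c <- b$contig_id == a$contig_id[i]
      if (ok && any(same_c)) {
        ov <- pmin(b$c_end[same_c], a$c_end[i]) -
              pmax(b$c_start[same_c], a$c_start[i])
        shorter <- pmin(b$c_end[same_c] - b$c_start[same_c],
                        a$c_end[i] - a$c_start[i])
        if (any(ov > max_overlap_frac * shorter)) ok <- FALSE
      }
      # (b) consistency within the contig
      if (ok && any(same_c)) {
        bc <- b[same_c, , drop = FALSE]
        if (any(bc$ref_id != a$ref_id[i]) || any(bc$strand != a$strand[i]))
          ok <- FALSE
        if (ok) {
          dc <- a$c_start[i] - bc$c_start
          dr <- a$r_start[i] - bc$r_start
          colinear <- if (a$strand[i] == "+") dc * dr > 0 else dc * dr < 0
          if (!all(colinear)) ok <- FALSE
        }
      }
    }
    if (ok) acc <- c(acc, i)
  }
  out <- a[acc, , drop = FALSE]
  class(out) <- c("alignment_collection", class(out))
  out
}

#' Consistent precision, recall and F-measure
#'
#' Same formulas as [overlap_measures()], restricted to the greedily
#' selected consistent collection; componentwise never larger than the
#' overlap measures.
#'
#' @param collection an `alignment_collection` (built on the fly from a
#'   plain alignment data.frame).
#' @inheritParams overlap_measures
#' @return named list `precision`, `recall`, `f` in percent.
#' @export
consistent_measures <- function(collection, references, contigs,
                                min_contig_len = 100) {
  if (!inherits(collection, "alignment_collection"))
    collection <- build_consistent_collection(collection)
  overlap_measures(collection, references, contigs, min_contig_len)
}

#' Per-transcript recall
#'
#' Union of reference-side alignment bases of each reference over its own
#' length, in percent; references without alignments score 0.
#'
#' @param alignments alignment data.frame (filtered or a consistent
#'   collection, depending on the recall flavour wanted).
#' @param references data.frame with `id`, `length`.
#' @return named numeric vector, one entry per reference.
#' @export
per_transcript_recall <- function(alignments, references) {
  out <- setNames(numeric(nrow(references)), references$id)
  if (nrow(alignments)) {
    for (rid in unique(alignments$ref_id)) {
      sel <- alignments$ref_id == rid
      tp <- union_bases(alignments$r_start[sel], alignments$r_end[sel],
                        alignments$ref_id[sel])
      out[rid] <- 100 * tp / references$length[references$id == rid]
    }
  }
  out
}

#' Transcripts detected by an assembly
#'
#' Number of reference transcripts whose per-transcript overlap recall is
#' at least `threshold` percent (boundary inclusive).
#'
#' @inheritParams per_transcript_recall
#' @param threshold recall threshold in percent (default 80).
#' @return integer count.
#' @export
transcripts_detected <- function(alignments, references, threshold = 80) {
  sum(per_transcript_recall(alignments, references) >= threshold)
}

#' Empirical optimum k per transcript
#'
#' A k is empirically optimum for a transcript when the assembly at that
#' k recovers the transcript with consistent recall strictly above
#' `threshold` percent.
#'
#' @param assemblies named list (names = k) of `contig_set`s.
#' @param references data.frame with `id`, `sequence`, `length`.
#' @param threshold consistent-recall cutoff in percent (default 95;
#'   strict inequality).
#' @param min_identity,min_contig_len alignment filters (see
#'   [filter_alignments()]).
#' @param ... passed to [builtin_align()].
#' @return logical matrix, rows = transcripts, cols = k: `TRUE` where k
#'   is optimum.
#' @export
empirical_optimum_k <- function(assemblies, references, threshold = 95,
                                min_identity = 95, min_contig_len = 100,
                                ...) {
  ks <- names(assemblies)
  m <- matrix(FALSE, nrow = nrow(references), ncol = length(assemblies),
              dimnames = list(references$id, ks))
  for (j in seq_along(assemblies)) {
    ctg <- assemblies[[j]]
    if (!nrow(ctg)) next
    aln <- builtin_align(ctg, references, ...)
    aln <- filter_alignments(aln, ctg, min_identity, min_contig_len)
    coll <- build_consistent_collection(aln)
    rec <- per_transcript_recall(coll, references)
    m[, j] <- rec > threshold
  }
  m
}

#' Contig length statistics
#'
#' Over contigs of at least `min_len` bp: the count, mean size, largest
#' contig and N50 (the length of the shortest contig in the smallest set
#' of longest contigs whose summed length reaches half the total).
#'
#' @param contigs `contig_set` or data.frame with `length`.
#' @param min_len length filter in bp (default 100).
#' @return named list `n`, `mean_size`, `largest`, `n50` (zeros when no
#'   contig qualifies).
#' @export
contig_stats <- function(contigs, min_len = 100) {
  len <- sort(contigs$length[contigs$length >= min_len], decreasing = TRUE)
  if (!length(len))
    return(list(n = 0L, mean_size = 0, largest = 0L, n50 = 0L))
  n50 <- len[which(cumsum(as.numeric(len)) >= sum(len) / 2)[1]]
  list(n = length(len), mean_size = mean(len), largest = len[1],
       n50 = as.integer(n50))
}

#' Score an assembly against reference transcripts
#'
#' One-stop evaluation: aligns (unless alignments are supplied), applies
#' the identity/length filters, and reports overlap measures, consistent
#' measures, contig statistics and the transcripts-detected count.
#'
#' @param contigs `contig_set`.
#' @param references data.frame with `id`, `sequence`, `length`.
#' @param alignments optional precomputed alignments (e.g. from
#'   [read_blast_tabular()]); computed with [builtin_align()] otherwise.
#' @param min_identity identity filter in percent (default 95).
#' @param min_contig_len contig length filter in bp (default 100).
#' @param detect_threshold overlap-recall threshold for
#'   transcripts-detected (default 80).
#' @param ... passed to [builtin_align()].
#' @return an object of class `assembly_eval`: list with `overlap`,
#'   `consistent` (each `precision`, `recall`, `f` in percent), `stats`,
#'   `transcripts_detected`, plus the filtered `alignments` and the
#'   accepted `collection`.
#' @export
evaluate_assembly <- function(contigs, references, alignments = NULL,
                              min_identity = 95, min_contig_len = 100,
                              detect_threshold = 80, ...) {
  if (is.null(alignments)) alignments <- builtin_align(contigs, references, ...)
  flt <- filter_alignments(alignments, contigs, min_identity,
                           min_contig_len)
  coll <- build_consistent_collection(flt)
  structure(list(
    overlap = overlap_measures(flt, references, contigs, min_contig_len),
    consistent = overlap_measures(coll, references, contigs,
                                  min_contig_len),
    stats = contig_stats(contigs, min_contig_len),
    transcripts_detected = transcripts_detected(flt, references,
                                                detect_threshold),
    alignments = flt, collection = coll),
    class = "assembly_eval")
}

#' @export
print.assembly_eval <- function(x, ...) {
  fmt <- function(m) sprintf("P %.2f%%  R %.2f%%  F %.2f%%",
                             m$precision, m$recall, m$f)
  cat("Assembly evaluation\n")
  cat("  overlap:    ", fmt(x$overlap), "\n")
  cat("  consistent: ", fmt(x$consistent), "\n")
  s <- x$stats
  cat(sprintf("  contigs >= filter: %d  mean %.1f bp  largest %d  N50 %d\n",
              s$n, s$mean_size, s$largest, s$n50))
  cat("  transcripts detected:", x$transcripts_detected, "\n")
  invisible(x)
}
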