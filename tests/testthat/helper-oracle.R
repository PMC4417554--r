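# Brute-force per-base oracle for the precision/recall measures: marks
# every aligned base in logical vectors over the actual sequences, so any
# interval-arithmetic bug in the package shows up as a disagreement.

oracle_measures <- function(alignments, references, contigs,
                            min_contig_len = 100) {
  ref_cov <- lapply(setNames(references$length, references$id),
                    function(l) logical(l))
  ctg_cov <- lapply(setNames(contigs$length, contigs$id),
                    function(l) logical(l))
  if (nrow(alignments)) {
    for (i in seq_len(nrow(alignments))) {
      a <- alignments[i, ]
      ref_cov[[a$ref_id]][(a$r_start + 1):a$r_end] <- TRUE
      ctg_cov[[a$contig_id]][(a$c_start + 1):a$c_end] <- TRUE
    }
  }
  qualifying <- contigs$id[contigs$length >= min_contig_len]
  tp_r <- sum(vapply(ref_cov, sum, 0))
  tp_c <- sum(vapply(ctg_cov[qualifying], sum, 0))
  denom_r <- sum(references$length)
  denom_c <- sum(contigs$length[contigs$length >= min_contig_len])
  p <- if (denom_c == 0) 0 else 100 * tp_c / denom_c
  r <- 100 * tp_r / denom_r
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f = f)
}

# Random alignment fixture: a handful of references and contigs with
# alignment intervals placed at random. Sequences are irrelevant for the
# measures, only the interval geometry matters.
random_alignment_fixture <- function(n_refs = NULL, n_contigs = NULL) {
  n_refs <- if (is.null(n_refs)) sample(1:10, 1) else n_refs
  n_contigs <- if (is.null(n_contigs)) sample(1:20, 1) else n_contigs
  refs <- data.frame(id = sprintf("r%d", seq_len(n_refs)),
                     length = sample(100:1000, n_refs, replace = TRUE),
                     stringsAsFactors = FALSE)
  contigs <- data.frame(id = sprintf("c%d", seq_len(n_contigs)),
                        length = sample(50:800, n_contigs, replace = TRUE),
                        stringsAsFactors = FALSE)
  n_aln <- sample(0:30, 1)
  if (n_aln == 0) return(list(refs = refs, contigs = contigs,
                              alignments = mixasm:::empty_alignments()))
  ci <- sample(n_contigs, n_aln, replace = TRUE)
  ri <- sample(n_refs, n_aln, replace = TRUE)
  len <- pmin(sample(20:400, n_aln, replace = TRUE),
              contigs$length[ci], refs$length[ri])
  cs <- vapply(seq_len(n_aln), function(j)
    sample.int(contigs$length[ci[j]] - len[j] + 1, 1) - 1L, 0L)
  rs <- vapply(seq_len(n_aln), function(j)
    sample.int(refs$length[ri[j]] - len[j] + 1, 1) - 1L, 0L)
  aln <- data.frame(contig_id = contigs$id[ci], ref_id = refs$id[ri],
                    c_start = cs, c_end = cs + len,
                    r_start = rs, r_end = rs + len,
                    strand = sample(c("+", "-"), n_aln, replace = TRUE),
                    identity = round(runif(n_aln, 95, 100), 2),
                    bit_score = round(runif(n_aln, 30, 800), 1),
                    aligned_length = len, stringsAsFactors = FALSE)
  list(refs = refs, contigs = contigs, alignments = aln)
}

# Random DNA string.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plant a substitution at 1-based position i (to a fixed different base).
substitute_base <- function(seq, i) {
  b <- substr(seq, i, i)
  repl <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
  paste0(substr(seq, 1, i - 1), repl, substr(seq, i + 1, nchar(seq)))
}

# Error-free reads tiling a sequence at every position (both strands via
# the assembler's canonical representation; forward is enough).
tiling_reads <- function(seq, read_len = 36, step = 1) {
  n <- nchar(seq)
  starts <- seq(1, n - read_len + 1, by = step)
  vapply(starts, function(s) substr(seq, s, s + read_len - 1), "")
}
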