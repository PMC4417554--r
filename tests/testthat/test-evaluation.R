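make_aln <- function(contig_id, ref_id, c_start, c_end, r_start, r_end,
                     bit, strand = "+", identity = 100) {
  data.frame(contig_id = contig_id, ref_id = ref_id, c_start = c_start,
             c_end = c_end, r_start = r_start, r_end = r_end,
             strand = strand, identity = identity, bit_score = bit,
             aligned_length = c_end - c_start, stringsAsFactors = FALSE)
}

test_that("BLAST tabular conversion and round trip", {
  tmp <- tempfile()
  writeLines(c("c1\tr1\t98.50\t200\t3\t0\t1\t200\t101\t300\t1e-50\t350.5",
               "c2\tr1\t100.00\t150\t0\t0\t11\t160\t450\t301\t1e-30\t277.1"),
             tmp)
  a <- read_blast_tabular(tmp)
  expect_equal(a$c_start, c(0L, 10L))
  expect_equal(a$c_end, c(200L, 160L))
  # minus strand inferred from descending subject coordinates
  expect_equal(a$strand, c("+", "-"))
  expect_equal(a$r_start, c(100L, 300L))
  expect_equal(a$r_end, c(300L, 450L))
  out <- tempfile()
  write_blast_tabular(a, out)
  b <- read_blast_tabular(out)
  for (col in c("contig_id", "ref_id", "c_start", "c_end", "r_start",
                "r_end", "strand", "identity", "aligned_length"))
    expect_equal(b[[col]], a[[col]])
  # empty file -> empty alignments
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_blast_tabular(empty)), 0)
  # malformed line reports its number
  bad <- tempfile()
  writeLines(c("c1\tr1\t98.5\t200\t3\t0\t1\t200\t101\t300\t1e-50\t350",
               "c1\tr1\tbroken"), bad)
  expect_error(read_blast_tabular(bad), "line 2")
})

test_that("the built-in aligner recovers planted alignments", {
  set.seed(91)
  ref <- data.frame(id = "r1", sequence = rand_dna(600), length = 600L,
                    stringsAsFactors = FALSE)
  # identical contig: one full-length perfect alignment
  ctg <- contig_set(ref$sequence, ids = "c1")
  a <- builtin_align(ctg, ref)
  full <- a[a$aligned_length == 600, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$identity, 100)
  expect_equal(full$strand, "+")
  expect_equal(c(full$c_start, full$c_end, full$r_start, full$r_end),
               c(0L, 600L, 0L, 600L))
  # reverse complement: minus strand, still perfect
  arc <- builtin_align(contig_set(revcomp(ref$sequence)), ref)
  frc <- arc[arc$aligned_length == 600, ]
  expect_equal(frc$strand, "-")
  expect_equal(frc$identity, 100)
  # planted substitutions are counted in the identity
  mut <- substitute_base(substitute_base(substr(ref$sequence, 101, 400),
                                         100), 200)
  am <- builtin_align(contig_set(mut), ref)
  best <- am[which.max(am$aligned_length), ]
  expect_equal(best$identity, 100 * (best$aligned_length - 2) /
                 best$aligned_length, tolerance = 1e-6)
  expect_equal(best$r_start, 100L)
})

test_that("identity and length filters use inclusive boundaries", {
  ctgs <- data.frame(id = c("ok", "short"), length = c(100L, 99L),
                     stringsAsFactors = FALSE)
  a <- rbind(make_aln("ok", "r1", 0, 50, 0, 50, 100, identity = 95.0),
             make_aln("ok", "r1", 0, 50, 50, 100, 90, identity = 94.9),
             make_aln("short", "r1", 0, 50, 100, 150, 80, identity = 100))
  f <- filter_alignments(a, ctgs)
  expect_equal(nrow(f), 1)
  expect_equal(f$identity, 95.0)  # 95.0 kept, 94.9 dropped, 99 bp dropped
  expect_equal(nrow(filter_alignments(a[0, ], ctgs)), 0)
})

test_that("overlap measures match hand-computed unions", {
  refs <- data.frame(id = c("R1", "R2"), length = c(100L, 100L),
                     stringsAsFactors = FALSE)
  ctgs <- data.frame(id = "c1", length = 50L, stringsAsFactors = FALSE)
  a <- make_aln("c1", "R1", 0, 50, 0, 50, 100)
  m <- overlap_measures(a, refs, ctgs, min_contig_len = 50)
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 25)
  expect_equal(m$f, 40)
  # overlapping reference intervals count once
  a2 <- rbind(make_aln("c1", "R1", 0, 50, 0, 60, 100),
              make_aln("c1", "R1", 0, 50, 40, 100, 90))
  m2 <- overlap_measures(a2, refs, ctgs, min_contig_len = 50)
  expect_equal(m2$recall, 100 * 100 / 200)
  # empty alignments: all zero, F defined as 0
  m0 <- overlap_measures(a[0, ], refs, ctgs, min_contig_len = 50)
  expect_equal(unlist(m0), c(precision = 0, recall = 0, f = 0))
  expect_error(overlap_measures(a, refs[0, ], ctgs), "zero")
})

test_that("measures equal the per-base oracle on random fixtures", {
  set.seed(92)
  for (i in 1:25) {
    fx <- random_alignment_fixture()
    fx$alignments <- filter_alignments(fx$alignments, fx$contigs)
    m <- overlap_measures(fx$alignments, fx$refs, fx$contigs)
    o <- oracle_measures(fx$alignments, fx$refs, fx$contigs)
    expect_equal(m, o)
    coll <- build_consistent_collection(fx$alignments)
    cm <- consistent_measures(coll, fx$refs, fx$contigs)
    co <- oracle_measures(coll, fx$refs, fx$contigs)
    expect_equal(cm, co)
    # subset property
    expect_lte(cm$precision, m$precision)
    expect_lte(cm$recall, m$recall)
    # F between min and max of P and R
    expect_gte(m$f + 1e-9, min(m$precision, m$recall))
    expect_lte(m$f - 1e-9, max(m$precision, m$recall))
  }
})

test_that("greedy selection enforces the one-alignment-per-conflict rules", {
  # overlapping on the reference: keep the higher bit score
  a <- rbind(make_aln("c1", "R1", 0, 100, 0, 100, 500),
             make_aln("c2", "R1", 0, 100, 10, 110, 300))
  coll <- build_consistent_collection(a)
  expect_equal(coll$bit_score, 500)
  # rearranged pair within one contig: second acceptance refused
  r <- rbind(make_aln("cz", "R1", 0, 100, 100, 200, 500),
             make_aln("cz", "R1", 100, 200, 0, 100, 400))
  collr <- build_consistent_collection(r)
  expect_equal(nrow(collr), 1)
  expect_equal(collr$bit_score, 500)
  # one contig aligning two transcripts: only the stronger one chosen
  d <- rbind(make_aln("cw", "R1", 0, 100, 0, 100, 500),
             make_aln("cw", "R2", 100, 200, 0, 100, 400))
  colld <- build_consistent_collection(d)
  expect_equal(nrow(colld), 1)
  expect_equal(colld$ref_id, "R1")
  # colinear same-contig alignments are all kept
  ok <- rbind(make_aln("cv", "R1", 0, 100, 0, 100, 500),
              make_aln("cv", "R1", 120, 200, 120, 200, 400))
  expect_equal(nrow(build_consistent_collection(ok)), 2)
  # on the minus strand colinearity is orientation-adjusted
  mi <- rbind(make_aln("cm", "R1", 0, 100, 100, 200, 500, strand = "-"),
              make_aln("cm", "R1", 120, 200, 10, 90, 400, strand = "-"))
  expect_equal(nrow(build_consistent_collection(mi)), 2)
  mi_bad <- rbind(make_aln("cm", "R1", 0, 100, 0, 100, 500, strand = "-"),
                  make_aln("cm", "R1", 120, 200, 110, 190, 400,
                           strand = "-"))
  expect_equal(nrow(build_consistent_collection(mi_bad)), 1)
  # acceptance is invariant to input order
  shuffled <- d[c(2, 1), ]
  expect_equal(build_consistent_collection(shuffled)$ref_id, "R1")
})

test_that("accepted alignments pairwise satisfy the 5% and consistency rules", {
  set.seed(93)
  for (i in 1:10) {
    fx <- random_alignment_fixture()
    coll <- build_consistent_collection(fx$alignments)
    if (nrow(coll) < 2) next
    for (i1 in seq_len(nrow(coll) - 1)) {
      for (i2 in (i1 + 1):nrow(coll)) {
        x <- coll[i1, ]; y <- coll[i2, ]
        if (x$ref_id == y$ref_id) {
          ov <- min(x$r_end, y$r_end) - max(x$r_start, y$r_start)
          expect_lte(ov, 0.05 * min(x$r_end - x$r_start,
                                    y$r_end - y$r_start))
        }
        if (x$contig_id == y$contig_id) {
          ov <- min(x$c_end, y$c_end) - max(x$c_start, y$c_start)
          expect_lte(ov, 0.05 * min(x$c_end - x$c_start,
                                    y$c_end - y$c_start))
          expect_equal(x$ref_id, y$ref_id)
          expect_equal(x$strand, y$strand)
        }
      }
    }
  }
})

test_that("composite conflict fixture scores exactly as hand-derived", {
  refs <- data.frame(id = c("R1", "R2"), length = c(300L, 200L),
                     stringsAsFactors = FALSE)
  ctgs <- data.frame(id = c("C1", "C2"), length = c(200L, 100L),
                     stringsAsFactors = FALSE)
  a <- rbind(
    make_aln("C1", "R1", 0, 200, 0, 200, 500),    # accepted
    make_aln("C2", "R1", 0, 100, 150, 250, 300),  # ref overlap: rejected
    make_aln("C2", "R2", 0, 100, 50, 150, 200))   # accepted
  coll <- build_consistent_collection(a)
  expect_equal(coll$bit_score, c(500, 200))
  cm <- consistent_measures(coll, refs, ctgs, min_contig_len = 100)
  # accepted bases: (200 + 100) over C1+C2 = 300 and R1+R2 = 500
  expect_equal(cm$precision, 100)
  expect_equal(cm$recall, 60)
  expect_equal(cm, oracle_measures(coll, refs, ctgs, 100))
  om <- overlap_measures(a, refs, ctgs, min_contig_len = 100)
  expect_gte(om$recall, cm$recall)
})

test_that("per-transcript recall and detection thresholds", {
  refs <- data.frame(id = c("R1", "R2", "R3"),
                     length = c(100L, 100L, 100L), stringsAsFactors = FALSE)
  a <- rbind(make_aln("c1", "R1", 0, 100, 0, 100, 500),
             make_aln("c2", "R2", 0, 50, 25, 75, 300),
             make_aln("c3", "R2", 0, 30, 50, 80, 200))
  rec <- per_transcript_recall(a, refs)
  expect_equal(unname(rec), c(100, 55, 0))  # union [25,80) on R2
  expect_equal(transcripts_detected(a, refs, threshold = 80), 1L)
  # boundary inclusive: exactly 80% counts
  a80 <- make_aln("c1", "R1", 0, 80, 0, 80, 100)
  expect_equal(transcripts_detected(a80, refs, threshold = 80), 1L)
  expect_equal(transcripts_detected(a[0, ], refs), 0L)
})

test_that("contig statistics follow the N50 convention", {
  s <- contig_stats(data.frame(length = c(300L, 200L, 100L)))
  expect_equal(s, list(n = 3L, mean_size = 200, largest = 300L,
                       n50 = 300L))
  s1 <- contig_stats(data.frame(length = 500L))
  expect_equal(s1, list(n = 1L, mean_size = 500, largest = 500L,
                        n50 = 500L))
  expect_equal(contig_stats(data.frame(length = c(100L, 100L)))$n50, 100L)
  # sub-threshold contigs are excluded everywhere
  s2 <- contig_stats(data.frame(length = c(99L, 300L)))
  expect_equal(s2$n, 1L)
  expect_equal(contig_stats(data.frame(length = 10L)),
               list(n = 0L, mean_size = 0, largest = 0L, n50 = 0L))
})

test_that("a perfect assembly scores 100 on all six measures", {
  set.seed(94)
  tx <- generate_transcripts(4, c(200, 600), seed = 95)
  ctgs <- contig_set(tx$sequence)
  ev <- evaluate_assembly(ctgs, tx)
  for (m in list(ev$overlap, ev$consistent)) {
    expect_equal(m$precision, 100)
    expect_equal(m$recall, 100)
    expect_equal(m$f, 100)
  }
  expect_equal(ev$transcripts_detected, 4L)
})

test_that("empirical optimum k responds to coverage", {
  set.seed(96)
  tx <- generate_transcripts(1, c(800, 800), seed = 97)
  tx$est_count <- 1L
  reads50 <- simulate_dataset(allocate_reads(tx, 550),
                              error_profile(0, 0, 36), seed = 98)
  asm <- lapply(c(21, 27), function(k) dbg_assemble(reads50, k = k))
  names(asm) <- c(21, 27)
  m <- empirical_optimum_k(asm, tx)
  expect_true(any(m))  # ~50x error-free: some k reaches >95% recall
  # a transcript with no reads has an empty optimum set
  asm0 <- list(`21` = dbg_assemble(character(0), k = 21))
  expect_false(any(empirical_optimum_k(asm0, tx)))
})
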