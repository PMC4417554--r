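test_that("graph of a single read is enumerable by hand", {
  # ACGTACGT, k=3: canonical 3-mers ACG (x4: ACG,CGT twice each, and
  # rc(CGT)=ACG) and GTA (x2: GTA,TAC); canonical 4-mer edges
  # ACGT (palindromic, x2), CGTA (=rc TACG, x2), GTAC (palindromic, x1)
  g <- dbg_graph("ACGTACGT", k = 3, cutoff = 1)
  expect_equal(g$nodes$kmer, c("ACG", "GTA"))
  expect_equal(g$nodes$count, c(4L, 2L))
  expect_equal(g$edges$kmer, c("ACGT", "CGTA", "GTAC"))
  expect_equal(g$edges$count, c(2L, 2L, 1L))
})

test_that("duplicate reads collapse onto the transcript's own graph", {
  set.seed(61)
  tx <- rand_dna(300)
  g1 <- dbg_graph(tx, k = 21, cutoff = 1)
  g2 <- dbg_graph(rep(tx, 7), k = 21, cutoff = 1)
  expect_equal(g1$nodes$kmer, g2$nodes$kmer)
  expect_equal(g1$edges$kmer, g2$edges$kmer)
  expect_equal(g2$nodes$count, 7L * g1$nodes$count)
  g0 <- dbg_graph(character(0), k = 21)
  expect_equal(nrow(g0$nodes), 0)
  expect_error(dbg_graph("ACGT", k = 4), "odd")
})

test_that("error-free tiling reads assemble into the full transcript", {
  set.seed(62)
  tx <- rand_dna(500)
  reads <- rep(tiling_reads(tx), 2)  # ~70x after both tilings
  ctg <- dbg_assemble(reads, k = 21)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(tx, revcomp(tx)))
  # assembly is deterministic
  expect_identical(ctg, dbg_assemble(reads, k = 21))
})

test_that("single-substitution tips are clipped, and clipping is stable", {
  set.seed(63)
  tx <- rand_dna(200)
  good <- rep(tiling_reads(tx), 10)
  bad <- substitute_base(substr(tx, 1, 36), 36)  # terminal substitution
  reads <- c(good, bad)
  clean <- dbg_assemble(reads, k = 21, cutoff = 1, min_contig = 100)
  expect_equal(nrow(clean), 1)
  expect_true(clean$sequence %in% c(tx, revcomp(tx)))
  # without clipping the erroneous branch survives as extra k-mers
  km_on <- mixasm:::cpp_clean_kmers(reads, 21L, 1L, TRUE, FALSE, -1L, 2L)
  km_off <- mixasm:::cpp_clean_kmers(reads, 21L, 1L, FALSE, FALSE, -1L, 2L)
  expect_lt(length(km_on), length(km_off))
  # clipped graph equals the error-free graph
  expect_identical(km_on, dbg_graph(good, k = 21, cutoff = 1)$nodes$kmer)
  # error-free graph is a fixed point of clipping
  km_free <- mixasm:::cpp_clean_kmers(good, 21L, 1L, TRUE, TRUE, -1L, 2L)
  expect_identical(km_free, dbg_graph(good, k = 21, cutoff = 1)$nodes$kmer)
})

test_that("bubbles pop towards the higher-coverage arm", {
  set.seed(64)
  tx <- rand_dna(300)
  variant <- substitute_base(tx, 150)  # mid-sequence SNP
  reads <- c(rep(tiling_reads(tx), 10), tiling_reads(variant))
  ctg <- dbg_assemble(reads, k = 21, cutoff = 1, min_contig = 100)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(tx, revcomp(tx)))
  # popping disabled: the SNP branch fragments the assembly
  frag <- dbg_assemble(reads, k = 21, cutoff = 1, min_contig = 100,
                       pop_bubbles = FALSE)
  expect_gt(nrow(frag), 1)
})

test_that("symmetric bubbles resolve deterministically", {
  set.seed(65)
  tx <- rand_dna(300)
  variant <- substitute_base(tx, 150)
  reads <- c(tiling_reads(tx), tiling_reads(variant))  # equal coverage
  a <- dbg_assemble(reads, k = 21, cutoff = 1, min_contig = 100)
  b <- dbg_assemble(reads, k = 21, cutoff = 1, min_contig = 100)
  expect_identical(a, b)
  expect_equal(nrow(a), 1)
  expect_true(a$sequence %in% c(tx, revcomp(tx), variant, revcomp(variant)))
})

test_that("contig k-mers are a subset of the cleaned graph's k-mers", {
  set.seed(66)
  tx <- rand_dna(400)
  reads <- c(rep(tiling_reads(tx), 3),
             vapply(1:20, function(i)
               substitute_base(substr(tx, i * 15 + 1, i * 15 + 36),
                               sample(36, 1)), ""))
  ctg <- dbg_assemble(reads, k = 21, cutoff = 1, min_contig = 50)
  kms <- mixasm:::cpp_clean_kmers(reads, 21L, 1L, TRUE, TRUE, -1L, 2L)
  canon <- function(s) pmin(s, revcomp(s))
  for (sq in ctg$sequence) {
    pos <- seq_len(nchar(sq) - 20)
    contig_kmers <- canon(substring(sq, pos, pos + 20))
    expect_true(all(contig_kmers %in% kms))
  }
})

test_that("a lone short read only surfaces when the filter allows it", {
  rd <- "ACGGTTACCAGGTTACGGATCCAGTTACGGTACGGA"
  expect_equal(nrow(dbg_assemble(rd, k = 21, min_contig = 100)), 0)
  ctg <- dbg_assemble(rd, k = 21, cutoff = 1, min_contig = 36)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(rd, revcomp(rd)))
})

test_that("low coverage fragments; smaller k recovers more of it", {
  set.seed(67)
  tx <- rand_dna(1000)
  prof <- error_profile(0, 0, 36)
  hi <- simulate_dataset(
    allocate_reads(data.frame(id = "t", sequence = tx, length = 1000L,
                              est_count = 1L), 700),
    prof, seed = 1)  # ~50x
  hi_ctg <- dbg_assemble(hi, k = 21, min_contig = 100)
  expect_equal(nrow(hi_ctg), 1)
  # at ~4x the assembly fragments relative to 50x
  lo <- simulate_dataset(
    allocate_reads(data.frame(id = "t", sequence = tx, length = 1000L,
                              est_count = 1L), 56),
    prof, seed = 2)
  lo_ctg <- dbg_assemble(lo, k = 21, min_contig = 100)
  expect_lt(sum(lo_ctg$length), sum(hi_ctg$length))
  # pooled over seeds, smaller k assembles at least as much as larger k
  tot <- c(`19` = 0, `31` = 0)
  for (s in 1:5) {
    rs <- simulate_dataset(
      allocate_reads(data.frame(id = "t", sequence = tx, length = 1000L,
                                est_count = 1L), 56),
      prof, seed = 10 + s)
    for (k in c(19, 31)) {
      tot[as.character(k)] <- tot[as.character(k)] +
        sum(dbg_assemble(rs, k = k, min_contig = 100)$length)
    }
  }
  expect_gte(tot[["19"]], tot[["31"]])
})

test_that("contig FASTA headers carry k and coverage provenance", {
  set.seed(68)
  tx <- rand_dna(300)
  ctg <- dbg_assemble(rep(tiling_reads(tx), 2), k = 21)
  fa <- tempfile(fileext = ".fa")
  write_contigs_fasta(ctg, fa)
  hdr <- grep("^>", readLines(fa), value = TRUE)
  expect_match(hdr[1], "^>contig_1 k=21 cov=")
  expect_equal(read_fasta(fa)$sequence, ctg$sequence)
})
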