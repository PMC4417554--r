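test_that("position error rate follows the linear ramp", {
  p <- error_profile(0.002, 5e-5, 36)
  expect_equal(position_error_rate(p, 0), 0.002)
  expect_equal(position_error_rate(p, 35), 0.00375)
  expect_equal(position_error_rate(p, 0:35), 0.002 + (0:35) * 5e-5)
  flat <- error_profile(0.002, 0, 36)
  expect_equal(position_error_rate(flat, c(0, 17, 35)), rep(0.002, 3))
  expect_error(position_error_rate(p, 36), "range")
  expect_error(error_profile(-0.001), "start_rate")
  expect_error(error_profile(0.9999, 0.1, 36), "infeasible")
})

test_that("profile_for_average reproduces the standard series", {
  # the published series maps average -> start by -0.1 percentage points
  for (i in 1:8) {
    avg <- 0.003 * i
    prof <- profile_for_average(avg)
    expect_equal(prof$start_rate, avg - 0.001, tolerance = 1e-12)
  }
  # arbitrary averages match the analytic mean of the ramp
  prof <- profile_for_average(0.004, read_length = 36)
  expect_equal(mean(position_error_rate(prof, 0:35)), 0.004)
  prof50 <- profile_for_average(0.003, read_length = 50)
  expect_equal(mean(position_error_rate(prof50, 0:49)), 0.003)
  expect_error(profile_for_average(0.0001, read_length = 36), "infeasible")
})

test_that("error-free pairs are exact substrings in FR orientation", {
  set.seed(21)
  tx <- rand_dna(600)
  prof <- error_profile(0, 0, 36)
  prs <- simulate_pairs(tx, 50, prof, insert_range = c(200, 200))
  expect_equal(nrow(prs), 50)
  expect_true(all(prs$insert == 200))
  for (i in seq_len(nrow(prs))) {
    frag <- substr(tx, prs$frag_start[i] + 1, prs$frag_start[i] + 200)
    expect_equal(prs$mate1[i], substr(frag, 1, 36))
    expect_equal(prs$mate2[i], revcomp(substr(frag, 165, 200)))
  }
  expect_true(all(prs$mate1_errors == "" & prs$mate2_errors == ""))
  expect_error(simulate_pairs(rand_dna(100), 5, prof, c(175, 225)),
               "shorter")
})

test_that("recorded error positions match the truth against the source", {
  set.seed(22)
  tx <- rand_dna(500)
  prof <- profile_for_average(0.024)  # high rate so errors are plentiful
  prs <- simulate_pairs(tx, 200, prof, insert_range = c(180, 220))
  mism <- function(read, truth) which(strsplit(read, "")[[1]] !=
                                        strsplit(truth, "")[[1]]) - 1L
  for (i in seq_len(nrow(prs))) {
    frag <- substr(tx, prs$frag_start[i] + 1,
                   prs$frag_start[i] + prs$insert[i])
    t1 <- substr(frag, 1, 36)
    t2 <- revcomp(substr(frag, prs$insert[i] - 35, prs$insert[i]))
    e1 <- if (prs$mate1_errors[i] == "") integer(0) else
      as.integer(strsplit(prs$mate1_errors[i], ",")[[1]])
    e2 <- if (prs$mate2_errors[i] == "") integer(0) else
      as.integer(strsplit(prs$mate2_errors[i], ",")[[1]])
    expect_identical(mism(prs$mate1[i], t1), e1)
    expect_identical(mism(prs$mate2[i], t2), e2)
  }
})

test_that("pooled substitution rate matches the analytic ramp mean", {
  set.seed(23)
  tx <- rand_dna(2000)
  prof <- profile_for_average(0.003)
  n_pairs <- 15000  # > 1e6 bases
  prs <- simulate_pairs(tx, n_pairs, prof)
  n_err <- sum(lengths(strsplit(prs$mate1_errors[prs$mate1_errors != ""],
                                ","))) +
           sum(lengths(strsplit(prs$mate2_errors[prs$mate2_errors != ""],
                                ",")))
  bases <- 2 * 36 * n_pairs
  p_mean <- mean(position_error_rate(prof, 0:35))  # 0.2875%
  se <- sqrt(p_mean * (1 - p_mean) / bases)
  expect_lt(abs(n_err / bases - p_mean), 3 * se)
})

test_that("insert sizes are uniform on the configured range", {
  set.seed(24)
  tx <- rand_dna(3000)
  prs <- simulate_pairs(tx, 1e5, error_profile(0, 0, 36),
                        insert_range = c(175, 225))
  expect_true(all(prs$insert >= 175 & prs$insert <= 225))
  tab <- table(factor(prs$insert, levels = 175:225))
  gof <- stats::chisq.test(tab)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulate_dataset honours the allocation and the seed", {
  tx <- generate_transcripts(4, c(400, 800), seed = 31)
  tx$est_count <- c(5L, 1L, 3L, 2L)
  ep <- allocate_reads(tx, 500)
  prof <- profile_for_average(0.003)
  rs1 <- simulate_dataset(ep, prof, seed = 99)
  rs2 <- simulate_dataset(ep, prof, seed = 99)
  expect_identical(as.data.frame(rs1), as.data.frame(rs2))
  counts <- table(factor(rs1$transcript_id, levels = tx$id))
  expect_equal(as.integer(counts), ep$allocation$reads)

  # zero reads -> empty files
  ep0 <- allocate_reads(tx, 0)
  rs0 <- simulate_dataset(ep0, prof, seed = 1)
  expect_equal(nrow(rs0), 0)
  pre0 <- tempfile()
  write_reads_fastq(rs0, pre0)
  expect_equal(file.size(paste0(pre0, "_1.fastq")), 0)
})

test_that("FASTQ output is byte-identical across reruns and well-formed", {
  tx <- generate_transcripts(2, c(400, 500), seed = 41)
  tx$est_count <- c(2L, 3L)
  ep <- allocate_reads(tx, 60)
  prof <- profile_for_average(0.003)
  p1 <- tempfile(); p2 <- tempfile()
  write_reads_fastq(simulate_dataset(ep, prof, seed = 5), p1)
  write_reads_fastq(simulate_dataset(ep, prof, seed = 5), p2)
  for (suf in c("_1.fastq", "_2.fastq", "_truth.tsv"))
    expect_identical(readLines(paste0(p1, suf)),
                     readLines(paste0(p2, suf)))
  fq <- read_fastq(paste0(p1, "_1.fastq"))
  expect_equal(nrow(fq), 60)
  expect_true(all(fq$length == 36))
  # qualities encode the ramp: Phred of the per-position error rate
  qline <- readLines(paste0(p1, "_1.fastq"))[4]
  q <- utf8ToInt(qline) - 33L
  expect_equal(q, as.integer(round(-10 * log10(
    position_error_rate(prof, 0:35)))))
})

test_that("short transcripts are skipped or rejected as configured", {
  tx <- data.frame(id = c("long", "short"),
                   sequence = c(rand_dna(400), rand_dna(150)),
                   length = c(400L, 150L), est_count = c(1L, 1L),
                   stringsAsFactors = FALSE)
  ep <- allocate_reads(tx, 100)
  prof <- error_profile(0, 0, 36)
  expect_warning(rs <- simulate_dataset(ep, prof, seed = 2), "skipped")
  expect_true(all(rs$transcript_id == "long"))
  expect_error(simulate_dataset(ep, prof, seed = 2, short = "error"),
               "shorter")
})
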