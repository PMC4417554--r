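#' Pipeline configuration
#'
#' Collects and validates every knob of the three-stage multi-k pipeline.
#' Defaults follow the standard desk-scale setup: 36 bp paired-end reads,
#' inserts uniform on 175..225, a 0.3 percent average ramped error
#' profile, odd k from 19 to the read length, overlap merging at 40 bp.
#'
#' @param k_schedule odd k values for stage 1 (default
#'   `seq(19, read_length, by = 2)`).
#' @param read_length read length in bp (default 36).
#' @param insert_range fragment length range (default `c(175, 225)`).
#' @param avg_error average substitution rate for the simulator (default
#'   0.003; see [profile_for_average()]).
#' @param merge_strategy `"overlap"` or `"dbg"` (default `"overlap"`).
#' @param min_overlap stage-2 overlap size in bp (default 40).
#' @param k2 stage-2 k for the `"dbg"` strategy (default 39).
#' @param min_contig minimum contig length carried forward and evaluated
#'   (default 100).
#' @param cutoff k-mer multiplicity cutoff, `NULL` = automatic.
#' @param map_seed_len,map_max_mismatch stage-3 read mapping parameters.
#' @param min_identity evaluation identity filter in percent.
#' @return a validated list of class `mixasm_config`.
#' @export
mixasm_config <- function(k_schedule = NULL, read_length = 36,
                          insert_range = c(175, 225), avg_error = 0.003,
                          merge_strategy = c("overlap", "dbg"),
                          min_overlap = 40, k2 = 39, min_contig = 100,
                          cutoff = NULL, map_seed_len = 17,
                          map_max_mismatch = 2, min_identity = 95) {
  merge_strategy <- match.arg(merge_strategy)
  if (is.null(k_schedule)) {
    top <- if (read_length %% 2 == 0) read_length - 1 else read_length
    k_schedule <- seq(19, top, by = 2)
  }
  k_schedule <- sort(unique(as.integer(k_schedule)))
  if (any(k_schedule %% 2 == 0)) stop("k_schedule must contain odd k only")
  if (any(k_schedule < 3) || any(k_schedule > read_length))
    stop("k_schedule must lie within [3, read_length]")
  check_insert_range(insert_range, read_length)
  if (avg_error < 0) stop("avg_error must be >= 0")
  structure(list(k_schedule = k_schedule, read_length = read_length,
                 insert_range = insert_range, avg_error = avg_error,
                 merge_strategy = merge_strategy, min_overlap = min_overlap,
                 k2 = k2, min_contig = min_contig, cutoff = cutoff,
                 map_seed_len = map_seed_len,
                 map_max_mismatch = map_max_mismatch,
                 min_identity = min_identity),
            class = "mixasm_config")
}

error_profile_for <- function(config) {
  if (config$avg_error == 0)
    error_profile(0, 0, config$read_length)
  else
    profile_for_average(config$avg_error, config$read_length)
}

#' Run the three-stage multi-k assembly pipeline
#'
#' Stage 1 assembles the reads at every k of the schedule with the
#' built-in de Bruijn assembler (or accepts precomputed per-k contig sets
#' from an external assembler); stage 2 pools and merges them; stage 3
#' remaps the reads to the merged contigs for expression counts. When
#' references are supplied the merged assembly (and optionally every
#' single-k assembly) is scored. Fully deterministic given the inputs.
#'
#' @param reads a `read_set` from [simulate_dataset()], or a character
#'   vector of read sequences.
#' @param config a [mixasm_config()].
#' @param references optional reference transcripts (`id`, `sequence`,
#'   `length`) for evaluation.
#' @param per_k_contigs optional named list (names = k) of precomputed
#'   `contig_set`s standing in for stage 1.
#' @param evaluate_per_k also score every single-k assembly (default
#'   `FALSE`; needed for multi-k vs single-k comparisons).
#' @param out_dir optional directory; when given, per-k FASTA, merged
#'   FASTA and the expression TSV are written there.
#' @return an object of class `mixasm_run`: list with `per_k` (contig
#'   sets), `merged`, `expression`, `eval` (or `NULL`), `per_k_eval`
#'   (or `NULL`) and the `config`.
#' @export
run_pipeline <- function(reads, config = mixasm_config(),
                         references = NULL, per_k_contigs = NULL,
                         evaluate_per_k = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "mixasm_config"))
  seqs <- read_sequences(reads)
  if (is.null(per_k_contigs)) {
    per_k <- lapply(config$k_schedule, function(k)
      dbg_assemble(seqs, k, cutoff = config$cutoff,
                   min_contig = config$min_contig))
    names(per_k) <- as.character(config$k_schedule)
  } else {
    per_k <- per_k_contigs
  }
  pool <- pool_contigs(per_k)
  merged <- merge_contigs(pool, strategy = config$merge_strategy,
                          min_overlap = config$min_overlap, k2 = config$k2,
                          min_contig = config$min_contig)
  expression <- map_reads(seqs, merged, seed_len = config$map_seed_len,
                          max_mismatch = config$map_max_mismatch)
  ev <- NULL
  per_k_eval <- NULL
  if (!is.null(references)) {
    ev <- evaluate_assembly(merged, references,
                            min_identity = config$min_identity,
                            min_contig_len = config$min_contig)
    if (evaluate_per_k)
      per_k_eval <- lapply(per_k, evaluate_assembly, references = references,
                           min_identity = config$min_identity,
                           min_contig_len = config$min_contig)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in names(per_k))
      write_contigs_fasta(per_k[[k]],
                          file.path(out_dir, paste0("contigs_k", k, ".fa")))
    write_contigs_fasta(merged, file.path(out_dir, "merged.fa"))
    write_expression_table(expression, file.path(out_dir, "expression.tsv"))
  }
  structure(list(per_k = per_k, merged = merged, expression = expression,
                 eval = ev, per_k_eval = per_k_eval, config = config),
            class = "mixasm_run")
}

#' @export
print.mixasm_run <- function(x, ...) {
  cat("Multi-k assembly run: k in {",
      paste(names(x$per_k), collapse = ", "), "}\n", sep = "")
  cat("  per-k contigs:", paste(vapply(x$per_k, nrow, 0L), collapse = ", "),
      "\n")
  cat("  merged contigs:", nrow(x$merged), "\n")
  if (!is.null(x$eval)) {
    cat("  merged consistent F:",
        sprintf("%.2f%%", x$eval$consistent$f), "\n")
  }
  invisible(x)
}

#' Desk-scale benchmark transcriptome ("mini" preset)
#'
#' 200 random transcripts of 500-3000 bp with power-law expression whose
#' coverage spans roughly 2x to 500x once [mini_expression()] allocates
#' reads -- a small-scale analogue of a mouse transcriptome shotgun
#' experiment.
#'
#' @param seed integer seed.
#' @param n number of transcripts (default 200).
#' @param length_range transcript lengths (default `c(500, 3000)`).
#' @return transcripts data.frame with `est_count` set.
#' @export
mini_transcripts <- function(seed, n = 200, length_range = c(500, 3000)) {
  tx <- generate_transcripts(n, length_range, seed = seed)
  # cap the count support at 250 so coverage spans ~2-500x after
  # allocation anchors the least-expressed transcript near 2x
  sample_power_law_expression(tx, exponent = 2, seed = seed + 1,
                              max_count = 250)
}

#' Read allocation for the mini benchmark
#'
#' Chooses the total read-pair budget so that the least-expressed
#' transcript sits at `min_coverage` (default 2x); with the capped
#' power-law counts of [mini_transcripts()] coverage then spans about
#' 2-500x.
#'
#' @param transcripts output of [mini_transcripts()].
#' @param min_coverage target coverage of the least-expressed transcript.
#' @param read_length read length in bp (default 36).
#' @return an `expression_profile`.
#' @export
mini_expression <- function(transcripts, min_coverage = 2,
                            read_length = 36) {
  w <- as.numeric(transcripts$est_count) * transcripts$length
  total <- ceiling(min_coverage * sum(w) /
                     (2 * read_length * min(transcripts$est_count)))
  allocate_reads(transcripts, total, read_length = read_length)
}

#' Optimum-k grid experiment (empirical vs model)
#'
#' For every coverage depth in `coverages` and every error rate in
#' `error_rates`, simulates reads from a fixed transcript set at that
#' uniform coverage, assembles at every k of `k_values`, and classifies k
#' as empirically optimum per transcript when the consistent recall
#' exceeds 95 percent. The Lander-Waterman model grid is computed for the
#' same transcripts for side-by-side comparison.
#'
#' @param seed integer seed.
#' @param coverages coverage depths (default `2^(1:11)`, i.e.
#'   2x to 2048x).
#' @param k_values odd k values (default `seq(19, 35, 2)`).
#' @param error_rates average substitution rates (default `c(0, 0.003)`).
#' @param n_transcripts,transcript_length size of the fixed transcript
#'   set (default 4 transcripts of 1000 bp).
#' @param read_length,insert_range read model (defaults 36 bp, 175..225).
#' @return an object of class `optimum_k_grid`: list with `empirical`
#'   (one fraction matrix per error rate, rows = coverages, cols = k),
#'   `detail` (per-transcript logical arrays), `model` (fraction matrix),
#'   `coverages`, `k_values`, `error_rates`.
#' @export
optimum_k_experiment <- function(seed, coverages = 2^(1:11),
                                 k_values = seq(19, 35, 2),
                                 error_rates = c(0, 0.003),
                                 n_transcripts = 4,
                                 transcript_length = 1000,
                                 read_length = 36,
                                 insert_range = c(175, 225)) {
  tx <- generate_transcripts(n_transcripts,
                             rep(transcript_length, 2), seed = seed)
  tx$est_count <- 1L
  empirical <- list()
  detail <- list()
  for (e in error_rates) {
    prof <- if (e == 0) error_profile(0, 0, read_length)
            else profile_for_average(e, read_length)
    frac <- matrix(NA_real_, length(coverages), length(k_values),
                   dimnames = list(as.character(coverages),
                                   as.character(k_values)))
    det <- array(FALSE, c(n_transcripts, length(coverages),
                          length(k_values)),
                 dimnames = list(tx$id, as.character(coverages),
                                 as.character(k_values)))
    for (ci in seq_along(coverages)) {
      cv <- coverages[ci]
      pairs <- pmax(0L, as.integer(round(cv * tx$length /
                                           (2 * read_length))))
      prof_expr <- allocate_reads(tx, sum(pairs), read_length,
                                  weights = pairs)
      # force the exact per-transcript counts (allocation is proportional
      # already, but guard against rounding drift)
      prof_expr$allocation$reads <- pairs
      rs <- simulate_dataset(prof_expr, prof, insert_range,
                             seed = seed + 1000L * ci + round(1e5 * e))
      assemblies <- lapply(k_values, function(k)
        dbg_assemble(rs, k, min_contig = 100))
      names(assemblies) <- as.character(k_values)
      m <- empirical_optimum_k(assemblies, tx)
      det[, ci, ] <- m
      frac[ci, ] <- colMeans(m)
    }
    key <- as.character(e)
    empirical[[key]] <- frac
    detail[[key]] <- det
  }
  model <- lw_grid(rep(transcript_length, length(coverages) *
                         n_transcripts),
                   read_length,
                   rep(coverages, each = n_transcripts), k_values,
                   bin_edges = coverages)
  structure(list(empirical = empirical, detail = detail, model = model,
                 coverages = coverages, k_values = k_values,
                 error_rates = error_rates, transcripts = tx),
            class = "optimum_k_grid")
}

#' @export
print.optimum_k_grid <- function(x, ...) {
  cat("Optimum-k experiment:", length(x$coverages), "coverage depths x",
      length(x$k_values), "k values\n")
  for (e in names(x$empirical)) {
    cat("\nEmpirical grid, error rate ", e, ":\n", sep = "")
    print(round(x$empirical[[e]], 2))
  }
  cat("\nLander-Waterman model grid:\n")
  print(round(x$model, 2))
  invisible(x)
}
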