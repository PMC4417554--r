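#' Lander-Waterman expected number of contigs
#'
#' For a genome (here: a single transcript) of length `G` sequenced with
#' reads of length `L` at coverage depth `c`, requiring an overlap of at
#' least `k` bases to join two reads, the expected number of contigs is
#'
#'   `(c * G / L) * exp(-(1 - k/L) * c)`.
#'
#' At `k = L` no overlap ever suffices and the expectation reduces to the
#' number of read starts per genome, `c * G / L`; at `c = 0` it is 0.
#'
#' @param G genome (transcript) length in bp.
#' @param L read length in bp.
#' @param coverage coverage depth `c` (>= 0).
#' @param k minimum detectable overlap in bp, `0 <= k <= L`.
#' @return expected contig count; arguments recycle like in `pmax()`.
#' @export
#' @examples
#' lw_expected_contigs(1000, 36, 10, 19)
lw_expected_contigs <- function(G, L, coverage, k) {
  if (any(G < 1) || any(L < 1)) stop("G and L must be >= 1")
  if (any(coverage < 0)) stop("coverage must be >= 0")
  if (any(k < 0 | k > L)) stop("k must satisfy 0 <= k <= L")
  (coverage * G / L) * exp(-(1 - k / L) * coverage)
}

#' Model-based optimum k values for a transcript
#'
#' A candidate k is optimum when the expected number of contigs under the
#' Lander-Waterman model is at most one, i.e. the transcript is expected
#' to assemble into a single contig. Because the expectation is
#' nondecreasing in k at fixed coverage, the result is a downward-closed
#' prefix of the sorted candidates.
#'
#' @inheritParams lw_expected_contigs
#' @param k_candidates integer vector of candidate k values in `[1, L]`.
#' @return the sorted subset of `k_candidates` classified optimum.
#' @export
lw_optimum_k <- function(G, L, coverage, k_candidates) {
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 1 | k_candidates > L))
    stop("k_candidates must lie in [1, L]")
  e <- lw_expected_contigs(G, L, coverage, k_candidates)
  k_candidates[e <= 1]
}

#' Model-based optimum-k grid over coverage bins
#'
#' For a population of transcripts with known lengths and coverage depths,
#' computes for every (coverage bin, k) cell the fraction of transcripts in
#' the bin for which k is model-optimum. Coverage bins default to powers of
#' two, matching the usual 2x, 4x, ..., 16384x ladder.
#'
#' @param G integer vector of transcript lengths.
#' @param L read length in bp.
#' @param coverage numeric vector of per-transcript coverage depths.
#' @param k_values integer vector of k values (columns).
#' @param bin_edges strictly increasing coverage bin edges; transcripts
#'   with coverage in `(edge[i], edge[i+1]]` fall in bin i, and a leading
#'   0 edge is prepended automatically.
#' @return matrix of fractions in `[0, 1]` (rows = bins, cols = k), `NaN`
#'   for empty bins, with edges/k as dimnames.
#' @export
lw_grid <- function(G, L, coverage, k_values, bin_edges = 2^(1:14)) {
  stopifnot(length(G) == length(coverage))
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  edges <- c(0, bin_edges)
  k_values <- sort(unique(as.integer(k_values)))
  bin <- cut(coverage, breaks = edges, include.lowest = TRUE)
  grid <- matrix(NaN, nrow = length(edges) - 1, ncol = length(k_values),
                 dimnames = list(levels(bin), as.character(k_values)))
  for (b in seq_len(nlevels(bin))) {
    sel <- which(as.integer(bin) == b)
    if (!length(sel)) next
    for (j in seq_along(k_values)) {
      opt <- vapply(sel, function(i)
        lw_expected_contigs(G[i], L, coverage[i], k_values[j]) <= 1,
        logical(1))
      grid[b, j] <- mean(opt)
    }
  }
  grid
}

#' Write an optimum-k grid as TSV
#'
#' Rows are coverage bins, columns k values, cells fractions.
#'
#' @param grid matrix from [lw_grid()] or [optimum_k_experiment()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  df <- data.frame(coverage_bin = rownames(grid), grid,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
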