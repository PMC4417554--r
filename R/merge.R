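#' Pool per-k contig sets and remove redundancy
#'
#' Concatenates the contig sets produced at different k, then removes
#' exact duplicates and contigs contained (as an exact substring, in
#' either orientation) in a longer contig; containment keeps the longer
#' sequence. Provenance (source k and source contig id) is recorded for
#' every surviving contig.
#'
#' @param contig_sets a named list of `contig_set` data.frames, names
#'   giving the source k (a single `contig_set` is also accepted).
#' @return an object of class `contig_pool`: a `contig_set` with extra
#'   columns `source_k` and `source_id`.
#' @export
pool_contigs <- function(contig_sets) {
  if (is.data.frame(contig_sets)) contig_sets <- list(contig_sets)
  if (!length(contig_sets) || !any(vapply(contig_sets, nrow, 0L) > 0))
    stop("at least one nonempty contig set is required")
  ks <- names(contig_sets)
  if (is.null(ks))
    ks <- vapply(contig_sets, function(s) {
      k <- attr(s, "k")
      if (is.null(k) || is.na(k)) NA_character_ else as.character(k)
    }, character(1))
  seqs <- unlist(lapply(contig_sets, function(s) s$sequence),
                 use.names = FALSE)
  src_id <- unlist(lapply(contig_sets, function(s) s$id), use.names = FALSE)
  src_k <- rep(ks, vapply(contig_sets, nrow, 0L))
  keep <- cpp_dedupe_contained(seqs)
  out <- contig_set(seqs[keep], ids = sprintf("pool_%d", seq_along(keep)))
  out$source_k <- src_k[keep]
  out$source_id <- src_id[keep]
  class(out) <- c("contig_pool", class(out))
  out
}

#' Merge pooled contigs into a non-redundant assembly
#'
#' Stage 2 of the multi-k procedure. Two strategies:
#'
#' * `"overlap"` (default): join contigs across exact suffix-prefix
#'   overlaps of at least `min_overlap` bp (both orientations), merging
#'   only unambiguous junctions -- each contig end may pair with at most
#'   one partner, mirroring a conservative lightweight overlap assembler
#'   with overlap size 40.
#' * `"dbg"`: re-assemble the pooled contigs as single-end reads with the
#'   built-in de Bruijn assembler at `k2` (default 39), mirroring a
#'   second-stage single-end de Bruijn pass.
#'
#' Merging never invents sequence: every merged contig is a chain of
#' pooled contigs with exact junction overlaps (overlap strategy), and the
#' merged contig count never exceeds the pooled count.
#'
#' @param pool a `contig_pool` from [pool_contigs()] (a plain
#'   `contig_set` is pooled first).
#' @param strategy `"overlap"` or `"dbg"`.
#' @param min_overlap minimum exact overlap in bp (default 40).
#' @param k2 odd k for the `"dbg"` strategy (default 39); must not exceed
#'   the shortest pooled contig.
#' @param min_contig minimum merged contig length reported (default 100).
#' @param drop_redundant before merging, remove contigs that are
#'   near-duplicates of a longer pooled contig (default `TRUE`): contig
#'   sets assembled at different k re-assemble the same region with
#'   occasional single-base differences (e.g. differently resolved error
#'   bubbles), which exact containment cannot collapse; a second-stage
#'   consensus assembler collapses them, and this filter plays that role.
#'   A contig is dropped when at least `redundant_frac` of its bases align
#'   to one longer surviving contig at `min_identity` percent identity.
#' @param redundant_frac,min_identity thresholds of the redundancy filter
#'   (defaults 0.95 and 95, mirroring the evaluation conventions).
#' @return a `contig_set` of merged contigs.
#' @export
merge_contigs <- function(pool, strategy = c("overlap", "dbg"),
                          min_overlap = 40, k2 = 39, min_contig = 100,
                          drop_redundant = TRUE, redundant_frac = 0.95,
                          min_identity = 95) {
  strategy <- match.arg(strategy)
  if (!inherits(pool, "contig_pool")) pool <- pool_contigs(pool)
  if (drop_redundant && nrow(pool) > 1)
    pool <- drop_redundant_contigs(pool, redundant_frac, min_identity)
  if (strategy == "overlap") {
    if (min_overlap < 1) stop("min_overlap must be >= 1")
    merged <- cpp_merge_overlap(pool$sequence, as.integer(min_overlap))
    merged <- merged[nchar(merged) >= min_contig]
    contig_set(merged)
  } else {
    if (k2 %% 2 == 0 || k2 < 3) stop("k2 must be odd and >= 3")
    if (k2 > min(pool$length))
      stop("k2 exceeds the shortest pooled contig (", min(pool$length), ")")
    dbg_assemble(pool$sequence, k2, cutoff = 1, min_contig = min_contig)
  }
}

# Remove pooled contigs inexactly contained in a longer surviving contig.
# Deterministic: contigs are examined from shortest to longest (ties by
# id), and a host must be strictly longer (or equal-length with a
# lexicographically smaller sequence) and still alive.
drop_redundant_contigs <- function(pool, frac = 0.95, min_identity = 95) {
  aln <- builtin_align(pool, pool)
  aln <- aln[aln$contig_id != aln$ref_id & aln$identity >= min_identity, ,
             drop = FALSE]
  if (!nrow(aln)) return(pool)
  len <- setNames(pool$length, pool$id)
  seqs <- setNames(pool$sequence, pool$id)
  alive <- setNames(rep(TRUE, nrow(pool)), pool$id)
  ord <- order(pool$length, pool$id)
  for (i in ord) {
    cid <- pool$id[i]
    sel <- which(aln$contig_id == cid)
    if (!length(sel)) next
    for (host in unique(aln$ref_id[sel])) {
      if (!alive[host]) next
      longer <- len[host] > len[cid] ||
        (len[host] == len[cid] && seqs[host] < seqs[cid])
      if (!longer) next
      hs <- sel[aln$ref_id[sel] == host]
      covered <- union_bases(aln$c_start[hs], aln$c_end[hs],
                             aln$contig_id[hs])
      if (covered >= frac * len[cid]) {
        alive[cid] <- FALSE
        break
      }
    }
  }
  pool[alive[pool$id], , drop = FALSE]
}
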