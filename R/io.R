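#' Read a FASTA file into a data frame
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the
#' `(id, sequence, length)` layout used throughout the package. Only the
#' first whitespace-delimited token of each header is kept as the id.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(id = ids, sequence = as.character(ss),
             length = Biostrings::width(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path output file.
#' @param headers optional full header lines (defaults to the ids).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, headers = NULL) {
  if (is.data.frame(x)) {
    seqs <- x$sequence
    ids <- x$id
  } else {
    seqs <- as.character(x)
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  }
  if (is.null(headers)) headers <- ids
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

# FASTQ with a fixed, position-derived quality string (see error_profile).
write_fastq <- function(ids, seqs, qual, path) {
  if (length(seqs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `length`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(ss)), sequence = as.character(ss),
             length = Biostrings::width(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}
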