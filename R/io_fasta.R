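#' Read a DNA or protein FASTA file with alphabet validation
#'
#' Thin wrappers around Biostrings' FASTA readers that uppercase residues and
#' enforce the pipeline's alphabets: `{A,C,G,T,N}` for genomic DNA (assembly
#' gaps are legal input, but any signal window containing N fails its test
#' downstream) and the 20 standard amino acids for proteins. An illegal
#' symbol is reported with its record id and 1-based position.
#'
#' @param path path to a FASTA file.
#' @return `read_genome_fasta`: a named [Biostrings::DNAStringSet], one
#'   element per record in file order; `read_protein_fasta`: a named
#'   [Biostrings::AAStringSet].
#' @export
read_genome_fasta <- function(path) {
  raw <- .read_fasta_checked(path, alphabet = "ACGTN", what = "DNA")
  Biostrings::DNAStringSet(raw)
}

#' @rdname read_genome_fasta
#' @export
read_protein_fasta <- function(path) {
  raw <- .read_fasta_checked(path, alphabet = "ACDEFGHIKLMNPQRSTVWY",
                             what = "protein")
  Biostrings::AAStringSet(raw)
}

.read_fasta_checked <- function(path, alphabet, what) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(raw))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  bad <- regexpr(sprintf("[^%s]", alphabet), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 what, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param x a named character vector, `DNAStringSet` or `AAStringSet`.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
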