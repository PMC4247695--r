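#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

## transition partner (A<->G, C<->T); transversion candidates per base
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), C = c("A", "G"),
                      G = c("C", "T"), T = c("A", "G"))

#' Generate a random nucleotide sequence
#'
#' Uniform i.i.d. bases over A/C/G/T. Used to build synthetic viral genomes
#' for mock communities and fixtures.
#'
#' @param length Sequence length in bp.
#' @return A single character string.
#' @export
random_genome <- function(length) {
  stopifnot(length >= 1)
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## split a sequence string into a character vector of bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Write sequences to a FASTA file
#'
#' Wraps lines at 70 columns. Thin wrapper over Biostrings.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  ## keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write reads to a FASTQ file
#'
#' Emits a constant placeholder quality (Q30, '?') per base; quality-aware
#' trimming is an upstream concern for real data, not modelled here.
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  n <- length(seqs)
  qual <- vapply(nchar(seqs), function(k) strrep("?", k), character(1))
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", names(seqs))
  lines[seq(2L, by = 4L, length.out = n)] <- unname(seqs)
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences (qualities discarded).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
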