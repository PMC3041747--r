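# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,U,N}; T and U are equivalent.

SEQ_ALPHABET <- c("A", "C", "G", "T", "U", "N")

#' Normalize a nucleotide sequence
#'
#' Uppercases and validates against the `{A,C,G,T,U,N}` alphabet.
#' @param sequence character scalar.
#' @param to `"DNA"` maps U to T, `"RNA"` maps T to U.
#' @return normalized character scalar.
#' @keywords internal
normalize_seq <- function(sequence, to = c("DNA", "RNA")) {
  to <- match.arg(to)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), SEQ_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid characters in sequence: ", paste(bad, collapse = ", "))
  }
  if (to == "DNA") chartr("U", "T", s) else chartr("T", "U", s)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Count of G+C characters in a sequence (N counts as non-GC)
#' @param sequence character scalar.
#' @return integer count.
#' @export
gc_count <- function(sequence) {
  ch <- seq_chars(toupper(sequence))
  sum(ch == "G" | ch == "C")
}

# reverse complement preserving the DNA/RNA alphabet of the input
revcomp <- function(sequence) {
  s <- toupper(sequence)
  rc <- chartr("ACGTUN", "TGCAAN", s)
  paste(rev(seq_chars(rc)), collapse = "")
}

# integer base codes for the folding engine: A=0, C=1, G=2, U/T=3, N=4
seq_codes <- function(sequence) {
  ch <- seq_chars(chartr("T", "U", toupper(sequence)))
  codes <- match(ch, c("A", "C", "G", "U", "N")) - 1L
  if (anyNA(codes)) stop("invalid characters in sequence")
  codes
}

#' Coerce a genome to a named character vector
#'
#' Accepts a named character vector, a `Biostrings::DNAStringSet`, or a
#' path to a FASTA file.
#' @param genome genome in any accepted representation.
#' @return named character vector of uppercase DNA sequences.
#' @export
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTUN]+$", toupper(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      any(!nzchar(names(genome)))) {
    stop("genome must be a named character vector, DNAStringSet, or FASTA path")
  }
  toupper(genome)
}

#' Write a genome to FASTA
#' @param genome named character vector or DNAStringSet.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
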