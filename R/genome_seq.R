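#' Genome sequence container
#'
#' A light container for a named nucleotide sequence, optionally marking
#' it as a circular chromosome.  The sequence is upper-cased, RNA `U` is
#' mapped to `T`, and any character outside `A/C/G/T/N` is rejected.
#'
#' @param id Single character label, unique within a file.
#' @param seq Nucleotide string over `A/C/G/T/N` (case-insensitive,
#'   `U` accepted and mapped to `T`).
#' @param circular Logical; `TRUE` for a circular chromosome.
#' @return An object of class `genome_seq`: a list with elements `id`,
#'   `seq` and `circular`.
#' @examples
#' g <- genome_seq("chr", "acgtn")
#' g$seq
#' @export
genome_seq <- function(id, seq, circular = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("genome_seq: 'id' must be a non-empty string")
  if (!is.character(seq) || length(seq) != 1L)
    stop("genome_seq: 'seq' must be a single string")
  seq <- chartr("U", "T", toupper(seq))
  if (!nzchar(seq))
    stop("genome_seq: sequence for '", id, "' is empty")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(sprintf(
      "genome_seq: sequence '%s' contains character(s) outside A/C/G/T/N (e.g. '%s')",
      id, substr(bad, 1L, 1L)))
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp%s\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' @export
as.character.genome_seq <- function(x, ...) x$seq

#' Sequence length in base pairs
#' @param x A `genome_seq` or nucleotide string.
#' @return Integer length.
#' @export
seq_length <- function(x) {
  if (inherits(x, "genome_seq")) nchar(x$seq) else nchar(x)
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string over `A/C/G/T/N`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# complement of single bases, vectorised, no reversal
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# coerce genome_seq or string to plain string
as_seq_string <- function(x) {
  if (inherits(x, "genome_seq")) x$seq
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a genome_seq or a single nucleotide string")
}
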