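# Codon-level utilities shared by the simulator and the effect
# annotator.  Translation uses the standard genetic code (identical to
# bacterial table 11 for elongation); ATG/GTG/TTG are accepted as start
# codons and reported as Met at residue 1.

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code_table <- function() Biostrings::GENETIC_CODE

# one-letter -> three-letter amino-acid labels ("*" kept as "*")
aa_three_letter <- function(aa1) {
  code <- Biostrings::AMINO_ACID_CODE
  ifelse(aa1 == "*", "*", unname(code[aa1]))
}

aa_one_letter <- function(aa) {
  if (all(nchar(aa) == 1L)) return(aa)
  code <- Biostrings::AMINO_ACID_CODE
  inv <- stats::setNames(names(code), unname(code))
  ifelse(aa == "*", "*", unname(inv[aa]))
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# translate codons; init = TRUE forces Met for an alternative start
translate_codons <- function(codons, init = TRUE) {
  aa <- unname(genetic_code_table()[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  if (init && length(aa) && codons[1L] %in% START_CODONS) aa[1L] <- "M"
  aa
}

#' Translate a CDS and describe its open reading frame
#'
#' Translates to the first in-frame stop.  The expected full length is
#' `floor(len/3) - 1` residues (the final codon being the terminator);
#' an internal stop is one that truncates the product short of that.
#' A trailing partial codon (CDS length not divisible by 3, as in a
#' frame-disrupted gene) is ignored.
#'
#' @param seq CDS nucleotide string, 5' to 3' (already strand-resolved).
#' @return A list: `protein` (string up to the first stop), `length`
#'   (residues), `expected_length`, `internal_stop` (logical),
#'   `terminated` (logical; a stop codon was reached), `aa_full`
#'   (per-codon translation including stops).
#' @export
translate_cds <- function(seq) {
  seq <- as_seq_string(seq)
  codons <- split_codons(seq)
  aa <- translate_codons(codons)
  stop_at <- which(aa == "*")[1L]
  expected <- max(length(codons) - 1L, 0L)
  prot_len <- if (!is.na(stop_at)) stop_at - 1L else length(aa)
  list(protein = paste(aa[seq_len(prot_len)], collapse = ""),
       length = prot_len,
       expected_length = expected,
       internal_stop = !is.na(stop_at) && (stop_at - 1L) < expected,
       terminated = !is.na(stop_at),
       aa_full = aa)
}

# all codons encoding a one-letter amino acid
codons_for_aa <- function(aa1) {
  gc <- genetic_code_table()
  names(gc)[gc == aa1]
}

# deterministic codon pair (differing at exactly one position) turning
# aa_from into aa_to with a single nucleotide change; errors if the
# substitution is not single-nucleotide reachable
codon_pair_for_change <- function(aa_from, aa_to) {
  f1 <- aa_one_letter(aa_from); t1 <- aa_one_letter(aa_to)
  from <- sort(codons_for_aa(f1)); to <- sort(codons_for_aa(t1))
  for (cf in from) {
    for (ct in to) {
      d <- which(strsplit(cf, "")[[1]] != strsplit(ct, "")[[1]])
      if (length(d) == 1L)
        return(list(from = cf, to = ct, offset = d - 1L))
    }
  }
  stop("no single-nucleotide codon change from ", aa_from, " to ", aa_to)
}

# extract the strand-resolved CDS string of one feature
cds_sequence <- function(genome, feature) {
  s <- substr(as_seq_string(genome), feature$start, feature$end)
  if (feature$strand == "-") revcomp(s) else s
}

# map a genome position inside a CDS feature to its codon
codon_at <- function(genome, feature, pos) {
  off <- if (feature$strand == "+") pos - feature$start else feature$end - pos
  idx <- off %/% 3L + 1L
  within <- off %% 3L
  cds <- cds_sequence(genome, feature)
  list(index = idx, within = within,
       codon = substr(cds, 3L * idx - 2L, 3L * idx))
}
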