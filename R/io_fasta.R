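#' Read a FASTA file
#'
#' Sequences are upper-cased, `U` is mapped to `T`, and characters
#' outside `A/C/G/T/N` are rejected.  Record ids (the first whitespace
#' token of each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical flag applied to every returned record.
#' @return A list of [genome_seq()] objects (empty for an empty file).
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf(
      "FASTA format error at line %d: expected a '>' header before sequence data",
      nonblank[1L]))
  hdr_lines <- which(startsWith(trimws(lines), ">"))
  hdr_names <- trimws(sub("^\\s*>", "", lines[hdr_lines]))
  empty_hdr <- which(!nzchar(hdr_names))
  if (length(empty_hdr))
    stop(sprintf("FASTA format error at line %d: empty header",
                 hdr_lines[empty_hdr[1L]]))
  # sequence content parsed by Biostrings; BStringSet so that the package's
  # stricter alphabet rule (not the IUPAC set) is enforced afterwards
  set <- Biostrings::readBStringSet(path)
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                 hdr_lines[which(widths == 0L)[1L]],
                 hdr_names[which(widths == 0L)[1L]]))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate record id '",
         ids[duplicated(ids)][1L], "'")
  seqs <- unname(as.character(set))
  lapply(seq_along(seqs), function(i) genome_seq(ids[i], seqs[i], circular))
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs A [genome_seq()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome_seq")) seqs <- list(seqs)
  ids <- vapply(seqs, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("write_fasta: duplicate sequence ids")
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, ""))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
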